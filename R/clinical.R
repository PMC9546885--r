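#' Monte-Carlo permutation test of a Pearson correlation
#'
#' Envelope-correlation values are bounded and typically non-normal, so the
#' Pearson coefficient is tested by permutation rather than the t
#' approximation: `y` is randomly permuted `n_perm` times and the
#' two-tailed p is `(1 + #(|r*| >= |r|)) / (1 + n_perm)` (add-one
#' estimator; the smallest attainable p is `1/(1 + n_perm)`). FDR across a
#' set of covariates is applied by the caller via [bh_fdr()].
#'
#' @param x,y Equal-length numeric vectors (n >= 4), finite, non-constant.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return An `oaec_perm_test` list: `statistic` (r), `p_value`, `n_perm`.
#' @examples
#' perm_pearson(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9), n_perm = 999, seed = 1)
#' @export
perm_pearson <- function(x, y, n_perm = 10000, seed = NULL) {
  if (length(x) != length(y) || length(x) < 4) {
    abort("`x` and `y` must be equal-length vectors with n >= 4.")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("Inputs must be finite.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance in `x` or `y`.")
  r <- cor(x, y)
  xc <- (x - mean(x)) / sd(x)
  yc <- (y - mean(y)) / sd(y)
  n <- length(x)
  r_null <- with_seed(seed, {
    idx <- replicate(n_perm, sample.int(n))
    colSums(xc * matrix(yc[idx], n)) / (n - 1)
  })
  p <- (1 + sum(abs(r_null) >= abs(r))) / (1 + n_perm)
  structure(list(statistic = r, p_value = p, n_perm = n_perm,
                 method = "permutation Pearson r"),
            class = "oaec_perm_test")
}

#' Overall F of a linear model (covariate-adjusted association)
#'
#' Ordinary least squares of `y` on an intercept plus every column of `X`
#' (factors and characters expanded to indicator columns), reporting the
#' overall F statistic `F = (R^2/df1) / ((1 - R^2)/df2)` with
#' `df1 = n predictor columns`, `df2 = n - df1 - 1`. Used as the
#' ANCOVA-style check that an AEC-covariate association survives
#' adjustment for demographics and symptom severity.
#'
#' @param y Numeric response.
#' @param X Data frame of predictors (numeric, factor or character).
#' @return List `F`, `df1`, `df2`, `r_squared`, `p_value`, `overflow`
#'   (`TRUE` when the fit is exact and F is unbounded).
#' @examples
#' linear_model_f(rnorm(20), data.frame(a = rnorm(20), g = rep(c("u", "v"), 10)))
#' @export
linear_model_f <- function(y, X) {
  X <- as.data.frame(X)
  if (nrow(X) != length(y)) abort("`y` and `X` must have matching rows.")
  mm <- stats::model.matrix(~ ., data = X)
  df1 <- ncol(mm) - 1
  n <- length(y)
  if (n <= df1 + 1) abort("Need n > predictors + 1.")
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    bad <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    abort(paste0("Rank-deficient design; offending column(s): ",
                 paste(bad, collapse = ", ")))
  }
  fit <- qr.fitted(qrm, y)
  ss_res <- sum((y - fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) abort("Response has zero variance.")
  r2 <- 1 - ss_res / ss_tot
  df2 <- n - df1 - 1
  overflow <- ss_res <= 1e-12 * ss_tot
  Fstat <- if (overflow) Inf else (r2 / df1) / ((1 - r2) / df2)
  p <- if (overflow) 0 else stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  list(F = Fstat, df1 = df1, df2 = df2, r_squared = r2, p_value = p,
       overflow = overflow)
}

#' Welch t-test from summary statistics
#'
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with the Welch-Satterthwaite
#' degrees of freedom. Lets published group means and SDs (e.g. a cohort
#' demographics table) be re-checked without subject-level data.
#'
#' @param m1,s1,n1 Mean, SD, size of group 1.
#' @param m2,s2,n2 Mean, SD, size of group 2.
#' @return List `t`, `df`, `p_value` (two-tailed).
#' @examples
#' welch_t_summary(41.25, 14.6, 20, 36.6, 13.1, 20)
#' @export
welch_t_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (s1 < 0 || s2 < 0) abort("SDs must be non-negative.")
  if (n1 < 2 || n2 < 2) abort("Group sizes must be >= 2.")
  if (s1 == 0 && s2 == 0) abort("Both variances are zero.")
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Chi-square test of independence on a contingency table
#'
#' Pearson chi-square, with Yates' continuity correction available for
#' 2 x 2 tables (the correction subtracts min(0.5, |O - E|) from each
#' deviation). Thin wrapper over [stats::chisq.test()] returning the bare
#' statistic and df.
#'
#' @param counts Matrix of non-negative integer counts, at least 2 x 2.
#' @param yates Apply the continuity correction (2 x 2 tables only;
#'   default `TRUE`).
#' @return List `chi2`, `df`, `p_value`.
#' @examples
#' chisq_independence(matrix(c(15, 5, 13, 7), 2), yates = TRUE)
#' @export
chisq_independence <- function(counts, yates = TRUE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be non-negative integers.")
  }
  if (nrow(counts) < 2 || ncol(counts) < 2) abort("Need at least a 2 x 2 table.")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("Zero marginal in the contingency table.")
  }
  correct <- yates && nrow(counts) == 2 && ncol(counts) == 2
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Demographic and clinical group comparison table
#'
#' Reproduces the usual cohort-characteristics table from a cohort tibble:
#' Welch t-tests for numeric variables, chi-square tests (Yates-corrected
#' for 2 x 2) for categorical ones.
#'
#' @param cohort Tibble with a `group` column plus the variables to test.
#' @param numeric_vars,categorical_vars Character vectors of column names.
#' @return Tibble: `variable`, `test`, `statistic`, `df`, `p_value`.
#' @export
cohort_comparison <- function(cohort,
                              numeric_vars = c("age", "severity"),
                              categorical_vars = c("sex", "education")) {
  lv <- unique(cohort$group)
  if (length(lv) != 2) abort("Exactly two groups required.")
  na_row <- function(v, test) {
    tibble::tibble(variable = v, test = test, statistic = NA_real_,
                   df = NA_real_, p_value = NA_real_)
  }
  num <- purrr::map_dfr(numeric_vars, function(v) {
    a <- cohort[[v]][cohort$group == lv[1]]
    b <- cohort[[v]][cohort$group == lv[2]]
    tryCatch({
      w <- welch_t_summary(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
      tibble::tibble(variable = v, test = "welch_t", statistic = w$t,
                     df = w$df, p_value = w$p_value)
    }, error = function(e) na_row(v, "welch_t"))
  })
  cat_ <- purrr::map_dfr(categorical_vars, function(v) {
    tryCatch({
      tab <- table(cohort[[v]], cohort$group)
      cs <- chisq_independence(as.matrix(tab))
      tibble::tibble(variable = v, test = "chisq", statistic = cs$chi2,
                     df = as.numeric(cs$df), p_value = cs$p_value)
    }, error = function(e) na_row(v, "chisq"))
  })
  dplyr::bind_rows(num, cat_)
}

#' Correlate a connectivity cell with clinical covariates
#'
#' Extracts one (pair, band) cell of the connectivity tensor for the chosen
#' subjects and runs [perm_pearson()] against each covariate, then BH-FDR
#' across the covariate family.
#'
#' @param conn Long connectivity tibble.
#' @param cohort Cohort tibble (`subject_id` plus covariates).
#' @param pair,band The tensor cell to extract (e.g. `"DLPFC_R-sgACC_L"`,
#'   `"beta1"`).
#' @param covariates Character vector of cohort columns to test.
#' @param subjects Optional subject-id subset (e.g. patients only).
#' @param n_perm,seed Passed to [perm_pearson()].
#' @param q FDR level across the covariate family.
#' @return Tibble: `covariate`, `r`, `p`, `fdr_reject`.
#' @export
correlate_covariates <- function(conn, cohort, pair, band,
                                 covariates = "episodes", subjects = NULL,
                                 n_perm = 10000, seed = NULL, q = 0.05) {
  cell <- conn[conn$pair == pair & conn$band == band, ]
  if (nrow(cell) == 0) abort("No connectivity rows match that pair/band.")
  if (!is.null(subjects)) cell <- cell[cell$subject_id %in% subjects, ]
  covs <- cohort[match(cell$subject_id, cohort$subject_id), , drop = FALSE]
  res <- purrr::map_dfr(seq_along(covariates), function(i) {
    v <- covariates[i]
    pt <- perm_pearson(cell$aec, as.numeric(covs[[v]]), n_perm = n_perm,
                       seed = if (is.null(seed)) NULL else derive_seed(seed, i))
    tibble::tibble(covariate = v, r = pt$statistic, p = pt$p_value)
  })
  res$fdr_reject <- bh_fdr(res$p, q = q)$reject
  res
}
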