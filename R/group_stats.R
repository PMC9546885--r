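# Welch t statistic, vectorized over columns of b-group assignment matrices
welch_t <- function(a, b) {
  va <- var(a); vb <- var(b)
  (mean(a) - mean(b)) / sqrt(va / length(a) + vb / length(b))
}

#' Two-tailed non-parametric permutation t-test
#'
#' Observed statistic is the Welch t of `a` vs `b`; the null distribution
#' is built by re-splitting the pooled values into groups of the original
#' sizes `n_perm` times. The two-tailed Monte-Carlo p uses the add-one
#' estimator `p = (1 + #(|t*| >= |t_obs|)) / (1 + n_perm)`, which is a
#' valid p-value (never exactly 0) for any `n_perm`.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @param n_perm Number of random re-splits (default 10000).
#' @param seed Integer seed.
#' @return An `oaec_perm_test` list: `statistic` (Welch t), `p_value`,
#'   `n_perm`, `method`. `statistic > 0` means `mean(a) > mean(b)`.
#' @examples
#' permutation_t_test(rnorm(10), rnorm(10, 2), n_perm = 999, seed = 1)
#' @export
permutation_t_test <- function(a, b, n_perm = 10000, seed = NULL) {
  if (length(a) < 2 || length(b) < 2) abort("Each group needs >= 2 values.")
  if (n_perm < 100) abort("`n_perm` must be at least 100.")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    warn("All pooled values identical; permutation test degenerate, p = 1.")
    return(structure(list(statistic = 0, p_value = 1, n_perm = n_perm,
                          method = "permutation Welch t"),
                     class = "oaec_perm_test"))
  }
  na <- length(a); nb <- length(b); n <- length(pooled)
  t_obs <- welch_t(a, b)
  tot <- sum(pooled); tot2 <- sum(pooled^2)
  t_null <- with_seed(seed, {
    idx <- replicate(n_perm, sample.int(n, na))        # na x n_perm
    xa <- matrix(pooled[idx], na)
    sa <- colSums(xa); sa2 <- colSums(xa^2)
    ma <- sa / na; mb <- (tot - sa) / nb
    va <- (sa2 - na * ma^2) / (na - 1)
    vb <- (tot2 - sa2 - nb * mb^2) / (nb - 1)
    (ma - mb) / sqrt(va / na + vb / nb)
  })
  p <- (1 + sum(abs(t_null) >= abs(t_obs))) / (1 + n_perm)
  structure(list(statistic = t_obs, p_value = p, n_perm = n_perm,
                 method = "permutation Welch t"),
            class = "oaec_perm_test")
}

#' @export
print.oaec_perm_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g (%d permutations)\n",
              x$method, x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Sorts the p-values ascending, finds the largest rank `k` with
#' `p(k) <= k * q / m`, and rejects every hypothesis with `p <= p(k)`. The
#' reported `threshold` is `k * q / m` (0 when nothing is rejected): the
#' adjusted significance level the family was thresholded at.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q Target false-discovery rate in `(0, 1)` (default 0.05).
#' @return List with `reject` (logical, input order), `threshold`,
#'   `n_reject`, `m`, `q`.
#' @examples
#' bh_fdr(c(0.001, 0.004, 0.03, 0.8), q = 0.05)
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0) abort("Empty p-value vector.")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  check_number(q, "q", 0, 1, strict = TRUE)
  m <- length(p)
  reject <- stats::p.adjust(p, method = "BH") <= q
  k <- sum(reject)                     # rejection count equals the step-up rank
  list(reject = reject, threshold = k * q / m, n_reject = k, m = m, q = q)
}

#' Group contrast of connectivity tensors
#'
#' One two-tailed permutation Welch t-test per (ROI pair, band) cell of the
#' connectivity tensor, BH-FDR across the whole family of cells (6 pairs x
#' 6 bands = 36 with the defaults), plus the uncorrected `p < 0.01` mask.
#' Positive t means the first group (controls, by convention) has the
#' higher envelope correlation.
#'
#' @param conn Long connectivity tibble from [cohort_connectivity()] (or
#'   [read_connectivity()]).
#' @param groups Named character vector or tibble (`subject_id`, `group`)
#'   mapping subjects to the two group labels.
#' @param control Label of the reference group (default `"control"`); the
#'   t sign is `control - other`.
#' @param q FDR level (default 0.05).
#' @param n_perm Permutations per cell.
#' @param seed Integer seed (each cell derives its own stream).
#' @return An `oaec_statmap`: a tibble with one row per cell — `roi_a`,
#'   `roi_b`, `pair`, `band`, `t`, `p`, `p_unc_lt_01`, `fdr_reject` — with
#'   family metadata (`m`, `q`, `threshold`, `n_perm`, `seed`) attached as
#'   attributes.
#' @export
group_contrast <- function(conn, groups, control = "control", q = 0.05,
                           n_perm = 10000, seed = NULL) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$group, groups$subject_id)
  }
  conn$group <- unname(groups[conn$subject_id])
  if (any(is.na(conn$group))) abort("Some subjects have no group label.")
  lv <- unique(conn$group)
  if (length(lv) != 2) abort("Exactly two groups are required.")
  if (!control %in% lv) abort(sprintf("No group labelled '%s'.", control))
  other <- setdiff(lv, control)

  cells <- dplyr::distinct(conn, roi_a, roi_b, pair, band)
  cells <- dplyr::arrange(cells, band, pair)
  res <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    cell <- conn[conn$pair == cells$pair[i] & conn$band == cells$band[i], ]
    a <- cell$aec[cell$group == control]
    b <- cell$aec[cell$group == other]
    pt <- permutation_t_test(a, b, n_perm = n_perm,
                             seed = if (is.null(seed)) NULL else derive_seed(seed, i))
    tibble::tibble(roi_a = cells$roi_a[i], roi_b = cells$roi_b[i],
                   pair = cells$pair[i], band = cells$band[i],
                   t = pt$statistic, p = pt$p_value)
  })
  fdr <- bh_fdr(res$p, q = q)
  res$p_unc_lt_01 <- res$p < 0.01
  res$fdr_reject <- fdr$reject
  structure(res, class = c("oaec_statmap", class(res)),
            m = fdr$m, q = q, threshold = fdr$threshold, n_perm = n_perm,
            seed = seed, control = control)
}

#' @export
print.oaec_statmap <- function(x, ...) {
  cat(sprintf("<oaec_statmap> %d cells, FDR q = %g, step-up threshold = %.4g, %d rejected\n",
              attr(x, "m"), attr(x, "q"), attr(x, "threshold"),
              sum(x$fdr_reject)))
  NextMethod()
}

#' Write a statistical map as TSV (+ JSON summary)
#'
#' @param statmap An `oaec_statmap` from [group_contrast()].
#' @param path Output TSV path; the JSON summary goes to `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_statmap <- function(statmap, path) {
  utils::write.table(
    statmap[, c("pair", "band", "t", "p", "p_unc_lt_01", "fdr_reject")],
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(m = attr(statmap, "m"), q = attr(statmap, "q"),
         threshold = attr(statmap, "threshold"),
         n_perm = attr(statmap, "n_perm"), seed = attr(statmap, "seed"),
         control = attr(statmap, "control")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
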