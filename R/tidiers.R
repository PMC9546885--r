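#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a permutation test result
#'
#' @param x An `oaec_perm_test` from [permutation_t_test()] or
#'   [perm_pearson()].
#' @param ... Unused.
#' @return One-row tibble: `estimate`, `p.value`, `method`, `n.perm`.
#' @export
tidy.oaec_perm_test <- function(x, ...) {
  tibble::tibble(estimate = x$statistic, p.value = x$p_value,
                 method = x$method, n.perm = x$n_perm)
}

#' Tidy / summarize a group-contrast statistical map
#'
#' `tidy()` returns the per-cell table with broom-style column names;
#' `glance()` the one-row family summary (cells tested, FDR level,
#' step-up threshold, rejection counts).
#'
#' @param x An `oaec_statmap` from [group_contrast()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.oaec_statmap <- function(x, ...) {
  tibble::tibble(pair = x$pair, band = x$band, statistic = x$t,
                 p.value = x$p, fdr.reject = x$fdr_reject,
                 p.unc.lt.01 = x$p_unc_lt_01)
}

#' @rdname tidy.oaec_statmap
#' @export
glance.oaec_statmap <- function(x, ...) {
  tibble::tibble(m = attr(x, "m"), q = attr(x, "q"),
                 threshold = attr(x, "threshold"),
                 n.reject = sum(x$fdr_reject),
                 n.unc.lt.01 = sum(x$p_unc_lt_01),
                 n.perm = attr(x, "n_perm"))
}

#' Tidy / summarize leave-one-out SVM results
#'
#' `tidy()` gives per-subject predictions; `glance()` the
#' sensitivity/specificity/accuracy summary (patients positive).
#'
#' @param x An `oaec_loocv` from [loocv_svm()].
#' @param positive_class Label treated as positive in `glance()`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.oaec_loocv <- function(x, ...) {
  tibble::tibble(truth = as.character(x$truth),
                 predicted = as.character(x$predicted),
                 correct = x$truth == x$predicted)
}

#' @rdname tidy.oaec_loocv
#' @export
glance.oaec_loocv <- function(x, positive_class = "patient", ...) {
  classification_metrics(x, positive_class = positive_class)
}
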