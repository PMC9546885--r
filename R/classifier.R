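#' Leave-one-out cross-validated RBF-SVM predictions
#'
#' For each subject, trains a soft-margin support vector machine with a
#' Gaussian kernel `k(u, v) = exp(-||u - v||^2 / (2 * kernel_scale^2))` and
#' box constraint `C = box_constraint` on all remaining subjects, then
#' predicts the held-out one. The solver is `e1071::svm` (libsvm's SMO-type
#' optimizer, tolerance 1e-6), which is deterministic for fixed inputs;
#' predictions are therefore invariant to subject ordering. Ties at the
#' decision boundary resolve toward the negative (control) class.
#'
#' @param features Numeric matrix or data frame, subjects x features (the
#'   canonical use: the four sgACC-DLPFC envelope correlations).
#' @param labels Binary labels, one per subject (factor or character).
#' @param box_constraint Soft-margin cost `C` (default 3).
#' @param kernel_scale Gaussian kernel scale (default 1).
#' @param standardize Standardize features inside each training fold
#'   (default `FALSE`).
#' @return An `oaec_loocv` list: `predicted` (factor), `truth` (factor),
#'   `config`.
#' @examples
#' X <- rbind(matrix(rnorm(20, 0, .1), 5), matrix(rnorm(20, 1, .1), 5))
#' loocv_svm(X, rep(c("control", "patient"), each = 5))
#' @export
loocv_svm <- function(features, labels, box_constraint = 3, kernel_scale = 1,
                      standardize = FALSE) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) abort("Features must be finite (no missing values).")
  labels <- factor(labels)
  if (nlevels(labels) != 2) abort("Exactly two classes are required.")
  if (any(table(labels) < 2)) abort("Need >= 2 subjects per class.")
  if (nrow(features) != length(labels)) abort("One label per subject required.")
  check_number(box_constraint, "box_constraint", 0, Inf, strict = TRUE)
  check_number(kernel_scale, "kernel_scale", 0, Inf, strict = TRUE)
  gamma <- 1 / (2 * kernel_scale^2)
  n <- nrow(features)
  pred <- vapply(seq_len(n), function(i) {
    tr_y <- labels[-i]
    if (nlevels(droplevels(tr_y)) < 2) {
      abort(sprintf("Training fold %d contains a single class.", i))
    }
    fit <- e1071::svm(features[-i, , drop = FALSE], tr_y, kernel = "radial",
                      cost = box_constraint, gamma = gamma,
                      scale = standardize, tolerance = 1e-6)
    as.character(predict(fit, features[i, , drop = FALSE]))
  }, character(1))
  structure(
    list(predicted = factor(pred, levels = levels(labels)), truth = labels,
         config = list(box_constraint = box_constraint,
                       kernel_scale = kernel_scale,
                       standardize = standardize)),
    class = "oaec_loocv"
  )
}

#' @export
print.oaec_loocv <- function(x, ...) {
  acc <- mean(x$predicted == x$truth)
  cat(sprintf("<oaec_loocv> %d subjects, accuracy %.1f%% (C = %g, kernel scale = %g)\n",
              length(x$truth), 100 * acc, x$config$box_constraint,
              x$config$kernel_scale))
  invisible(x)
}

#' Sensitivity, specificity and accuracy of binary predictions
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / n`, with the positive class named explicitly
#' (patients, in the diagnostic-marker use).
#'
#' @param predicted,truth Equal-length label vectors (or an `oaec_loocv`
#'   as the first argument).
#' @param positive_class The label counted as positive.
#' @return Tibble: `sensitivity`, `specificity`, `accuracy`, `tp`, `fn`,
#'   `tn`, `fp`, `n`.
#' @examples
#' classification_metrics(rep(c("patient", "control"), c(16, 4)),
#'                        rep("patient", 20), positive_class = "patient")
#' @export
classification_metrics <- function(predicted, truth = NULL,
                                   positive_class = "patient") {
  if (inherits(predicted, "oaec_loocv")) {
    truth <- predicted$truth
    predicted <- predicted$predicted
  }
  if (length(predicted) == 0 || length(predicted) != length(truth)) {
    abort("`predicted` and `truth` must be equal-length and non-empty.")
  }
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (!positive_class %in% truth) abort("`positive_class` absent from `truth`.")
  tp <- sum(predicted == positive_class & truth == positive_class)
  fn <- sum(predicted != positive_class & truth == positive_class)
  tn <- sum(predicted != positive_class & truth != positive_class)
  fp <- sum(predicted == positive_class & truth != positive_class)
  tibble::tibble(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(truth),
    tp = tp, fn = fn, tn = tn, fp = fp, n = length(truth)
  )
}

#' Extract an SVM feature matrix from a connectivity tensor
#'
#' Pulls the four sgACC-DLPFC envelope correlations (or any requested
#' pairs) for one band into a subjects x pairs matrix suitable for
#' [loocv_svm()].
#'
#' @param conn Long connectivity tibble.
#' @param band Band name (default `"beta1"`).
#' @param pairs Pair labels; default all four sgACC-DLPFC combinations.
#' @return Tibble with `subject_id` and one column per pair.
#' @export
connectivity_features <- function(conn, band = "beta1",
                                  pairs = c("DLPFC_L-sgACC_L", "DLPFC_L-sgACC_R",
                                            "DLPFC_R-sgACC_L", "DLPFC_R-sgACC_R")) {
  sub <- conn[conn$band == band & conn$pair %in% pairs, ]
  if (nrow(sub) == 0) abort("No connectivity rows match the requested band/pairs.")
  wide <- tidyr::pivot_wider(sub[, c("subject_id", "pair", "aec")],
                             names_from = "pair", values_from = "aec")
  if (anyNA(wide)) abort("Missing feature values for some subjects.")
  wide[, c("subject_id", intersect(pairs, names(wide)))]
}
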