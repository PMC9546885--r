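#' Diagonal noise covariance from a recording
#'
#' Per-channel sample variances, the diagonal noise model used to whiten
#' sensors before the minimum-norm inverse. Channels with zero variance
#' (flat lines) are replaced by the smallest positive variance found and a
#' warning is raised so degenerate channels cannot silently dominate the
#' whitener.
#'
#' @param recording A [sensor_recording()].
#' @return An `oaec_noise_model`: list with `variances` (named numeric) and
#'   `replaced` (indices of patched channels).
#' @export
estimate_noise_covariance <- function(recording) {
  stopifnot(inherits(recording, "sensor_recording"))
  if (ncol(recording$data) < 2) abort("Need at least 2 samples per channel.")
  v <- apply(recording$data, 1, var)
  names(v) <- recording$labels
  zero <- unname(which(v <= 0))
  if (length(zero) == length(v)) abort("All channels are constant; no noise model.")
  if (length(zero) > 0) {
    v[zero] <- min(v[v > 0])
    warn(paste0("Constant channel(s) ", paste(zero, collapse = ", "),
                ": variance replaced by the smallest positive channel variance."))
  }
  structure(list(variances = v, replaced = zero), class = "oaec_noise_model")
}

#' Minimum-norm inverse operator
#'
#' Tikhonov-regularized minimum-norm solution with a diagonal noise
#' covariance: with whitener `W = C^(-1/2)` and whitened lead field
#' `G = W L`, the operator is `K = t(G) (G t(G) + lambda2 I)^(-1) W`. No
#' depth weighting and an identity source covariance are assumed. The
#' default `lambda2 = 1/9` follows the usual SNR = 3 convention
#' (`lambda2 = 1/SNR^2`).
#'
#' @param leadfield Sensors x source-components matrix.
#' @param noise An `oaec_noise_model` (or `NULL` for identity noise).
#' @param lambda2 Regularization, > 0.
#' @return An `oaec_inverse`: list with `K`, `lambda2`, labels.
#' @export
compute_inverse_operator <- function(leadfield, noise = NULL, lambda2 = 1 / 9) {
  check_number(lambda2, "lambda2", 0, Inf, strict = TRUE)
  L <- unclass(leadfield)
  n_sens <- nrow(L)
  if (is.null(noise)) {
    w <- rep(1, n_sens)
  } else {
    stopifnot(inherits(noise, "oaec_noise_model"))
    if (length(noise$variances) != n_sens) {
      abort("Noise model and lead field disagree on channel count.")
    }
    w <- 1 / sqrt(noise$variances)
  }
  G <- w * L                                  # row-scaled: W %*% L
  gram <- G %*% t(G) + lambda2 * diag(n_sens)
  K <- t(G) %*% solve(gram) %*% (w * diag(n_sens))
  structure(
    list(K = K, lambda2 = lambda2,
         sensor_labels = attr(leadfield, "sensor_labels"),
         source_labels = attr(leadfield, "source_labels")),
    class = "oaec_inverse"
  )
}

#' Apply an inverse operator to a recording
#'
#' `S = K X`: projects sensor data into source space.
#'
#' @param inv An `oaec_inverse`.
#' @param recording A [sensor_recording()] (or bare channels x samples
#'   matrix).
#' @return Source-components x samples matrix with attributes `fs` and
#'   `lambda2`.
#' @export
apply_inverse <- function(inv, recording) {
  stopifnot(inherits(inv, "oaec_inverse"))
  if (inherits(recording, "sensor_recording")) {
    X <- recording$data
    fs <- recording$fs
  } else {
    X <- recording
    fs <- attr(recording, "fs")
  }
  if (ncol(inv$K) != nrow(X)) {
    abort(sprintf("Operator expects %d channels, recording has %d.",
                  ncol(inv$K), nrow(X)))
  }
  S <- inv$K %*% X
  rownames(S) <- inv$source_labels
  attr(S, "fs") <- fs
  attr(S, "lambda2") <- inv$lambda2
  S
}

# First principal component of a components x samples block, sign-fixed so
# it correlates positively with the largest-variance component.
collapse_pca <- function(block) {
  if (nrow(block) == 1) return(block[1, ])
  ctr <- block - rowMeans(block)
  sv <- svd(ctr, nu = 1, nv = 0)
  pc <- as.numeric(t(sv$u[, 1, drop = FALSE]) %*% block)
  ref <- block[which.max(apply(block, 1, var)), ]
  if (stats::cor(pc, ref) < 0) pc <- -pc
  pc
}

#' Extract one timeseries per ROI from a source estimate
#'
#' Sources with 3 unconstrained orientation components are collapsed to one
#' sequence via the first principal component of the 3 x samples block
#' (sign fixed against the largest-variance component, so the result keeps
#' a well-defined phase for the Hilbert stage). Within an ROI, member
#' source sequences are sign-aligned to the ROI's first principal
#' component and averaged, preventing cancellation between anatomically
#' opposite dipole orientations.
#'
#' @param S Source matrix from [apply_inverse()].
#' @param roi_map Named list: ROI name -> source indices (source numbering,
#'   not component numbering, when `components_per_source = 3`).
#' @param fs Sampling rate (taken from `S`'s attribute if present).
#' @param components_per_source 1 or 3.
#' @return A [roi_timeseries()] with ROIs in the order given.
#' @export
extract_roi_timeseries <- function(S, roi_map, fs = NULL,
                                   components_per_source = 1) {
  fs <- fs %||% attr(S, "fs")
  if (is.null(fs)) abort("`fs` is required (not found on `S`).")
  if (!components_per_source %in% c(1, 3)) {
    abort("`components_per_source` must be 1 or 3.")
  }
  if (length(roi_map) == 0) abort("`roi_map` is empty.")
  n_sources <- nrow(S) / components_per_source
  if (n_sources != round(n_sources)) {
    abort("Row count of `S` is not a multiple of `components_per_source`.")
  }
  rows <- purrr::imap(roi_map, function(idx, name) {
    if (length(idx) == 0) abort(sprintf("ROI '%s' has no sources.", name))
    if (any(idx < 1 | idx > n_sources)) {
      abort(sprintf("ROI '%s' references sources out of range.", name))
    }
    member <- vapply(idx, function(j) {
      block <- S[((j - 1) * components_per_source + 1):(j * components_per_source),
                 , drop = FALSE]
      collapse_pca(block)
    }, numeric(ncol(S)))                       # samples x members
    if (ncol(member) == 1) return(member[, 1])
    ref <- collapse_pca(t(member))             # ROI-level first PC
    signs <- vapply(seq_len(ncol(member)),
                    function(k) sign(stats::cor(member[, k], ref)), numeric(1))
    signs[signs == 0] <- 1
    rowMeans(sweep(member, 2, signs, "*"))
  })
  roi_timeseries(do.call(rbind, rows), fs, names(roi_map))
}
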