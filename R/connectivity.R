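#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), so the net response is zero-phase and envelope
#' timing is preserved. Output length equals input length.
#'
#' @param x Numeric vector.
#' @param low_hz,high_hz Band edges in Hz (`0 < low < high < fs/2`).
#' @param fs Sampling rate in Hz.
#' @return Filtered numeric vector of the same length.
#' @examples
#' t <- seq(0, 2, by = 1 / 256)
#' y <- bandpass(sin(2 * pi * 15 * t), 13, 17, fs = 256)
#' @export
bandpass <- function(x, low_hz, high_hz, fs) {
  check_number(low_hz, "low_hz", 0, Inf, strict = TRUE)
  if (high_hz <= low_hz) abort("`high_hz` must exceed `low_hz`.")
  if (high_hz >= fs / 2) abort("Band edge at or above Nyquist frequency.")
  if (length(x) < 3 * 9) abort("Input too short for a 4th-order band-pass.")
  bf <- butter_cached(low_hz, high_hz, fs)
  filtfilt_fast(bf$b, bf$a, x)
}

.butter_cache <- new.env(parent = emptyenv())

butter_cached <- function(low_hz, high_hz, fs) {
  key <- paste(low_hz, high_hz, fs, sep = "|")
  bf <- .butter_cache[[key]]
  if (is.null(bf)) {
    bf <- signal::butter(4, c(low_hz, high_hz) / (fs / 2), type = "pass")
    .butter_cache[[key]] <- bf
  }
  bf
}

# forward-backward (zero-phase) application with the same trailing-zero
# padding as signal::filtfilt; the single-pass IIR runs in compiled code
filtfilt_fast <- function(b, a, x) {
  n <- length(x)
  y <- cpp_filter_iir(b, a, c(x, numeric(2 * max(length(a), length(b)))))
  rev(cpp_filter_iir(b, a, rev(y)))[seq_len(n)]
}

# Analytic signal via the FFT half-spectrum construction: positive
# frequencies doubled, negative zeroed, DC and Nyquist kept.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Amplitude envelope via the Hilbert transform
#'
#' Magnitude of the analytic signal `x + i H(x)`. For a band-limited
#' oscillation this is the instantaneous amplitude; correlating these
#' envelopes across regions is the AEC connectivity measure.
#'
#' @param x Finite numeric vector.
#' @return Non-negative numeric vector, same length as `x`.
#' @examples
#' t <- seq(0, 1, by = 1 / 256)
#' env <- amplitude_envelope(sin(2 * pi * 20 * t))
#' @export
amplitude_envelope <- function(x) {
  if (!all(is.finite(x))) abort("`x` must be finite.")
  Mod(analytic_signal(x))
}

#' Symmetric (multivariate) orthogonalization
#'
#' Replaces a set of signals by the *closest* (Frobenius norm) set of
#' mutually orthogonal signals, removing all shared zero-lag components at
#' once. This is the leakage correction step: linear source mixing puts the
#' same instantaneous signal into several reconstructed ROIs, and any
#' connectivity computed on the raw reconstructions is inflated by it.
#' Unlike pairwise regression, the symmetric procedure treats all ROIs
#' jointly and does not depend on their order.
#'
#' The solution is found by alternating (a) the orthonormal polar factor of
#' the magnitude-scaled matrix with (b) per-row rescaling to best fit the
#' original rows, iterated to a relative Frobenius change below `tol`.
#'
#' Rank-deficient inputs are resolved by how the optimum behaves: exactly
#' duplicated rows (same direction and magnitude) leave the optimum
#' non-unique and raise an error naming the rows, while a dominated
#' dependent row (e.g. an exact scaled copy of another row) has a unique
#' optimum that sends it to zero -- such a row is entirely shared signal,
#' and nothing of it survives leakage correction.
#'
#' @param M Numeric matrix, one signal per row.
#' @param tol Convergence tolerance on the relative change (default 1e-9).
#' @param max_iter Iteration cap (default 200).
#' @return Matrix of the same shape with pairwise-orthogonal rows.
#' @export
symmetric_orthogonalize <- function(M, tol = 1e-9, max_iter = 200) {
  if (!is.matrix(M) || nrow(M) < 2) abort("`M` must be a matrix with >= 2 rows.")
  if (ncol(M) < nrow(M)) abort("Need at least as many samples as signals.")
  # Work in the k-dimensional row space: M = A %*% B with B orthonormal
  # (k x T), so every polar-factor iteration runs on k x k matrices. The
  # basis comes from the eigen-decomposition of the small Gram matrix.
  k <- nrow(M)
  gram <- tcrossprod(M)
  ev <- eigen(gram, symmetric = TRUE)
  s <- sqrt(pmax(ev$values, 0))
  if (s[k] < 1e-8 * s[1]) {
    # Duplicated rows (same direction and same magnitude) make the optimum
    # non-unique: error naming them. A *dominated* dependent row (e.g. an
    # exact scaled copy) has a unique optimum that sends it to zero -- the
    # row is entirely shared signal, so nothing survives leakage correction.
    nrm <- sqrt(diag(gram))
    cc <- gram / tcrossprod(nrm)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (abs(abs(cc[i, j]) - 1) < 1e-12 &&
            abs(nrm[i] - nrm[j]) < 1e-10 * max(nrm[i], nrm[j])) {
          abort(sprintf(paste0("Rank-deficient input: rows %d and %d are ",
                               "duplicates; the closest orthogonal set is ",
                               "not unique."), i, j))
        }
      }
    }
    r <- sum(s > 1e-12 * s[1])
    B1 <- (1 / s[seq_len(r)]) *
      (t(ev$vectors[, seq_len(r), drop = FALSE]) %*% M)
    B <- rbind(B1, complete_basis(B1, k - r))
    A <- M %*% t(B)
  } else {
    B <- (1 / s) * (t(ev$vectors) %*% M)              # k x T, orthonormal rows
    A <- ev$vectors %*% diag(s, k)                    # k x k, M = A B
  }
  d <- sqrt(rowSums(M^2))
  Qs <- diag(k)
  prev <- Inf
  for (iter in seq_len(max_iter)) {
    sv <- svd(diag(d, k) %*% A)                 # scaled target, polar factor
    Qs <- sv$u %*% t(sv$v)                      # orthonormal factor in row space
    d <- rowSums(A * Qs)                        # best per-row magnitudes
    err <- norm(A - diag(d, k) %*% Qs, "F")
    if (is.finite(prev) && abs(prev - err) <= tol * max(err, 1e-300)) break
    prev <- err
  }
  O <- diag(d, k) %*% Qs %*% B
  dimnames(O) <- dimnames(M)
  O
}

# deterministic orthonormal completion of a row basis: canonical unit
# vectors Gram-Schmidt-orthogonalized against B1 until `n_extra` found
complete_basis <- function(B1, n_extra) {
  extra <- matrix(0, n_extra, ncol(B1))
  got <- 0
  j <- 1
  while (got < n_extra && j <= ncol(B1)) {
    v <- numeric(ncol(B1))
    v[j] <- 1
    v <- v - as.numeric(t(B1) %*% (B1 %*% v))
    if (got > 0) {
      E <- extra[seq_len(got), , drop = FALSE]
      v <- v - as.numeric(t(E) %*% (E %*% v))
    }
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) {
      got <- got + 1
      extra[got, ] <- v / nv
    }
    j <- j + 1
  }
  if (got < n_extra) abort("Could not complete an orthonormal basis.")
  extra
}

#' Amplitude-envelope correlation between ROI timeseries
#'
#' Per frequency band: band-pass every ROI signal, optionally apply
#' [symmetric_orthogonalize()] to strip shared zero-lag components, take
#' Hilbert envelopes, drop 1 s from each end (filter/Hilbert edge
#' artifacts), and Pearson-correlate envelopes for every ROI pair. With
#' `window_s` set, envelopes are split into non-overlapping windows,
#' correlated per window, and the per-window correlations averaged.
#'
#' @param roi_ts A [roi_timeseries()] (or bare ROIs x samples matrix with
#'   `fs` and `rois` supplied).
#' @param bands Band tibble (see [default_bands()]).
#' @param orthogonalize Apply leakage correction before the envelopes
#'   (default `TRUE`).
#' @param window_s Optional window length in seconds; `NULL` (default)
#'   correlates over the full record.
#' @param fs,rois Only used when `roi_ts` is a bare matrix.
#' @return A tibble with columns `roi_a`, `roi_b`, `pair`, `band`, `aec`,
#'   pairs ordered lexicographically.
#' @examples
#' cfg <- simulation_config(n_per_group = 2, fs = 256, duration = 20,
#'                          n_sensors = 8, seed = 7)
#' co <- simulate_cohort(cfg)
#' aec(co$sources[[1]], bands = default_bands("beta1"))
#' @export
aec <- function(roi_ts, bands = default_bands(), orthogonalize = TRUE,
                window_s = NULL, fs = NULL, rois = NULL) {
  if (inherits(roi_ts, "roi_timeseries")) {
    fs <- roi_ts$fs
    rois <- roi_ts$rois
    M <- roi_ts$data
  } else {
    M <- roi_ts
    if (is.null(fs)) abort("`fs` is required for a bare matrix.")
    rois <- rois %||% rownames(M) %||% sprintf("ROI%d", seq_len(nrow(M)))
  }
  check_bands(bands, fs)
  n <- ncol(M)
  min_len <- max(if (!is.null(window_s)) 4 * window_s * fs else 0,
                 10 / min(bands$low_hz) * fs, 3 * fs)
  if (n < min_len) abort("Recording too short for the requested bands/window.")
  ord <- order(rois)
  M <- M[ord, , drop = FALSE]
  rois <- rois[ord]
  pairs <- roi_pairs(rois)
  trim <- seq.int(round(fs) + 1, n - round(fs))

  purrr::map_dfr(seq_len(nrow(bands)), function(bi) {
    band <- bands[bi, ]
    Fb <- t(apply(M, 1, bandpass, low_hz = band$low_hz,
                  high_hz = band$high_hz, fs = fs))
    if (orthogonalize) Fb <- orthogonalize_rows(Fb)
    env <- t(apply(Fb, 1, amplitude_envelope))[, trim, drop = FALSE]
    cc <- pairwise_env_cor(env, fs, window_s)
    ia <- match(pairs$roi_a, rois)
    ib <- match(pairs$roi_b, rois)
    tibble::tibble(roi_a = pairs$roi_a, roi_b = pairs$roi_b, pair = pairs$pair,
                   band = band$band, aec = cc[cbind(ia, ib)])
  })
}

# Leakage correction as applied inside aec(): rows are first scaled to unit
# RMS (the closest-orthogonal objective weights rows by magnitude, and
# reconstruction gain should not influence the correction -- this makes AEC
# exactly invariant to per-ROI rescaling). A row that is an exact scalar
# copy of an earlier row is pure shared signal: it is zeroed outright, and
# the remaining rows are orthogonalized jointly.
orthogonalize_rows <- function(Fb) {
  rms <- sqrt(rowMeans(Fb^2))
  dup <- rms == 0
  Fn <- Fb / ifelse(rms == 0, 1, rms)
  k <- nrow(Fb)
  cc <- suppressWarnings(stats::cor(t(Fn)))
  for (j in seq_len(k)[-1]) {
    if (!dup[j] && any(abs(cc[j, seq_len(j - 1)][!dup[seq_len(j - 1)]]) >
                         1 - 1e-12)) {
      dup[j] <- TRUE
    }
  }
  keep <- which(!dup)
  O <- matrix(0, k, ncol(Fb))
  if (length(keep) >= 2) {
    O[keep, ] <- symmetric_orthogonalize(Fn[keep, , drop = FALSE])
  } else if (length(keep) == 1) {
    O[keep, ] <- Fn[keep, , drop = FALSE]
  }
  dimnames(O) <- dimnames(Fb)
  O
}

# full-record or windowed-average Pearson correlation matrix of envelopes;
# a zero-variance envelope (a row fully removed as shared leakage) carries
# no measurable coupling and correlates 0 with everything by convention
pairwise_env_cor <- function(env, fs, window_s) {
  safe_cor <- function(m) {
    cc <- suppressWarnings(stats::cor(t(m)))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    cc
  }
  if (is.null(window_s)) {
    return(safe_cor(env))
  }
  w <- round(window_s * fs)
  n_win <- floor(ncol(env) / w)
  if (n_win < 1) abort("`window_s` longer than the trimmed record.")
  mats <- lapply(seq_len(n_win), function(k) {
    safe_cor(env[, ((k - 1) * w + 1):(k * w), drop = FALSE])
  })
  Reduce(`+`, mats) / n_win
}

#' Cohort-level connectivity tensor
#'
#' Runs the full per-subject source-space chain — noise-covariance
#' estimation, minimum-norm inverse, ROI extraction, band-limited
#' orthogonalized envelope correlation — over a set of recordings and
#' stacks the results into one long tibble (the subjects x pairs x bands
#' tensor in tidy form).
#'
#' @param recordings Named list of [sensor_recording()] objects (names are
#'   subject ids), or an `oaec_cohort`.
#' @param leadfield Sensors x sources matrix (ignored for a cohort, which
#'   carries its own).
#' @param roi_map Named list mapping ROI name to lead-field column indices
#'   (ignored for a cohort).
#' @param bands Band tibble.
#' @param lambda2 Minimum-norm regularization (see
#'   [compute_inverse_operator()]).
#' @param orthogonalize,window_s Passed to [aec()].
#' @param components_per_source 1 or 3 lead-field columns per source.
#' @return Tibble: `subject_id`, `roi_a`, `roi_b`, `pair`, `band`, `aec`.
#' @export
cohort_connectivity <- function(recordings, leadfield = NULL, roi_map = NULL,
                                bands = default_bands(), lambda2 = 1 / 9,
                                orthogonalize = TRUE, window_s = NULL,
                                components_per_source = 1) {
  if (inherits(recordings, "oaec_cohort")) {
    leadfield <- recordings$leadfield
    roi_map <- recordings$roi_map
    bands <- bands
    recordings <- recordings$recordings
  }
  if (is.null(leadfield) || is.null(roi_map)) {
    abort("`leadfield` and `roi_map` are required.")
  }
  ids <- names(recordings) %||% sprintf("S%03d", seq_along(recordings))
  purrr::map_dfr(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    res <- tryCatch({
      noise <- estimate_noise_covariance(rec)
      inv <- compute_inverse_operator(leadfield, noise, lambda2 = lambda2)
      S <- apply_inverse(inv, rec)
      ts <- extract_roi_timeseries(S, roi_map, fs = rec$fs,
                                   components_per_source = components_per_source)
      aec(ts, bands = bands, orthogonalize = orthogonalize, window_s = window_s)
    }, error = function(e) {
      abort(sprintf("Connectivity failed for subject %s: %s", ids[i],
                    conditionMessage(e)))
    })
    dplyr::mutate(res, subject_id = ids[i], .before = 1)
  })
}

#' Write / read a connectivity tensor as TSV
#'
#' Long-format TSV (`subject_id`, `roi_a`, `roi_b`, `band`, `aec`) with an
#' optional JSON sidecar holding the configuration hash and seed.
#'
#' @param conn Connectivity tibble from [cohort_connectivity()].
#' @param path Output TSV path.
#' @param meta Optional list written as `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_connectivity <- function(conn, path, meta = NULL) {
  utils::write.table(conn[, c("subject_id", "roi_a", "roi_b", "band", "aec")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  out <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  dplyr::mutate(out, pair = paste(roi_a, roi_b, sep = "-"),
                .after = "roi_b")
}
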