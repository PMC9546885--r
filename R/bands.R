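#' Canonical EEG frequency bands
#'
#' The six band-limited ranges the connectivity analysis runs over: theta
#' (4-8 Hz), alpha (8-12 Hz), beta-1 (13-17 Hz), beta-2 (18-24 Hz), beta-3
#' (25-30 Hz) and gamma (30-100 Hz). Beta-1 is where the sgACC-DLPFC group
#' difference this package is designed to detect is expected to live.
#'
#' @param names Optional character vector selecting a subset by name.
#' @return A tibble with columns `band`, `low_hz`, `high_hz`.
#' @examples
#' default_bands()
#' default_bands("beta1")
#' @export
default_bands <- function(names = NULL) {
  bands <- tibble::tibble(
    band    = c("theta", "alpha", "beta1", "beta2", "beta3", "gamma"),
    low_hz  = c(4, 8, 13, 18, 25, 30),
    high_hz = c(8, 12, 17, 24, 30, 100)
  )
  if (!is.null(names)) {
    missing <- setdiff(names, bands$band)
    if (length(missing) > 0) {
      abort(paste0("Unknown band(s): ", paste(missing, collapse = ", ")))
    }
    bands <- bands[match(names, bands$band), ]
  }
  bands
}

# validate a one-row band (or band tibble) against a sampling rate
check_bands <- function(bands, fs) {
  stopifnot(is.data.frame(bands), all(c("band", "low_hz", "high_hz") %in% names(bands)))
  bad <- bands$low_hz <= 0 | bands$high_hz <= bands$low_hz
  if (any(bad)) {
    abort(paste0("Invalid band edges for: ", paste(bands$band[bad], collapse = ", ")))
  }
  over <- bands$high_hz >= fs / 2
  if (any(over)) {
    abort(paste0("Band edge at or above Nyquist (", fs / 2, " Hz) for: ",
                 paste(bands$band[over], collapse = ", ")))
  }
  invisible(bands)
}

#' Region-of-interest labels and pair ordering
#'
#' The four regions the analysis targets: left/right subgenual anterior
#' cingulate (sgACC) and left/right dorsolateral prefrontal cortex (DLPFC).
#' Pairs are the six unordered combinations, ordered lexicographically over
#' the ROI names so that every tensor, table and test in the package agrees
#' on pair identity.
#'
#' @param rois Character vector of ROI names (default the four canonical ones).
#' @return A tibble with columns `roi_a`, `roi_b`, `pair` (`"a-b"` label).
#' @examples
#' roi_pairs()
#' @export
roi_pairs <- function(rois = c("DLPFC_L", "DLPFC_R", "sgACC_L", "sgACC_R")) {
  rois <- sort(unique(rois))
  if (length(rois) < 2) abort("Need at least two ROIs to form pairs.")
  idx <- utils::combn(length(rois), 2)
  tibble::tibble(
    roi_a = rois[idx[1, ]],
    roi_b = rois[idx[2, ]],
    pair  = paste(rois[idx[1, ]], rois[idx[2, ]], sep = "-")
  )
}
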