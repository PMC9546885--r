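#' Construct a sensor recording
#'
#' Light container for a continuous multi-channel recording: a channels x
#' samples matrix plus its sampling rate and channel labels.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz.
#' @param labels Optional character vector of channel labels.
#' @param meta Optional named list of provenance metadata (seed, snr, ...).
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(data, fs, labels = NULL, meta = list()) {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric matrix (channels x samples).")
  }
  if (!all(is.finite(data))) abort("`data` contains non-finite values.")
  check_number(fs, "fs", lower = 0, strict = TRUE)
  labels <- labels %||% sprintf("CH%03d", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) {
    abort("`labels` length must equal the number of channels.")
  }
  structure(
    list(data = data, fs = fs, labels = as.character(labels), meta = meta),
    class = "sensor_recording"
  )
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' @export
dim.sensor_recording <- function(x) dim(x$data)

#' Construct an ROI timeseries set
#'
#' One real-valued sequence per region of interest, the unit the envelope
#' connectivity stage operates on.
#'
#' @param data Numeric matrix, one ROI per row.
#' @param fs Sampling rate in Hz.
#' @param rois Character vector of ROI names, one per row.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, fs, rois) {
  if (!is.matrix(data) || !all(is.finite(data))) {
    abort("`data` must be a finite numeric matrix (ROIs x samples).")
  }
  if (length(rois) != nrow(data)) abort("`rois` must name every row.")
  check_number(fs, "fs", lower = 0, strict = TRUE)
  structure(list(data = data, fs = fs, rois = as.character(rois)),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %d ROIs x %d samples @ %g Hz: %s\n",
              nrow(x$data), ncol(x$data), x$fs, paste(x$rois, collapse = ", ")))
  invisible(x)
}
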