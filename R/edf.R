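# Minimal continuous-EDF writer/reader: 16-bit samples, one data record per
# second, one physical range per channel. Covers the subset of the format
# this pipeline emits and consumes; not a general EDF+ implementation.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width) {
  s <- formatC(x, width = 1, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(formatC(x, format = "f", digits = width), 1, width)
  edf_pad(s, width)
}

#' Write a recording as EDF
#'
#' European Data Format, continuous, 16-bit, one data record per second
#' (requires an integer sampling rate). Trailing samples that do not fill a
#' whole record are dropped with a warning. Each channel is scaled to its
#' own physical min/max, so round-tripping is exact up to 16-bit
#' quantization of the per-channel range.
#'
#' @param recording A [sensor_recording()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "sensor_recording"))
  fs <- recording$fs
  if (fs != round(fs)) abort("EDF writer requires an integer sampling rate.")
  X <- recording$data
  ns <- nrow(X)
  n_rec <- floor(ncol(X) / fs)
  if (n_rec < 1) abort("Recording shorter than one 1-s data record.")
  if (n_rec * fs < ncol(X)) {
    warn(sprintf("Dropping %d trailing samples (partial EDF record).",
                 ncol(X) - n_rec * fs))
    X <- X[, seq_len(n_rec * fs), drop = FALSE]
  }
  pmin <- apply(X, 1, min)
  pmax <- apply(X, 1, max)
  flat <- pmax - pmin <= 0
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767

  header <- paste0(
    edf_pad("0", 8), edf_pad("synthetic", 80), edf_pad("oaec cohort", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4),
    paste(vapply(recording$labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  scale <- (dmax - dmin) / (pmax - pmin)
  dig <- round((X - pmin) * scale + dmin)     # channels x samples, per-row range
  dig <- pmin(pmax(dig, dmin), dmax)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  for (r in seq_len(n_rec)) {
    block <- dig[, ((r - 1) * fs + 1):(r * fs), drop = FALSE]
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Parses the continuous 16-bit EDF subset written by [write_edf()] (and
#' standard continuous EDF files with a uniform sampling rate across
#' channels). Optionally applies the basic preprocessing the analysis
#' expects: a 1 Hz zero-phase high-pass and a line-noise notch.
#'
#' @param path EDF file path.
#' @param highpass_hz Optional high-pass cutoff in Hz (e.g. 1); `NULL`
#'   disables.
#' @param notch_hz Optional line-noise frequency in Hz (e.g. 50); a
#'   zero-phase band-stop of +/- 2 Hz around it is applied; `NULL`
#'   disables.
#' @return A [sensor_recording()].
#' @export
read_edf <- function(path, highpass_hz = NULL, notch_hz = NULL) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readChar(con, 256, useBytes = TRUE)
  if (nchar(fixed, type = "bytes") < 256) abort("Truncated EDF header.")
  get <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  n_rec <- as.integer(get(fixed, 237, 8))
  rec_dur <- as.numeric(get(fixed, 245, 8))
  ns <- as.integer(get(fixed, 253, 4))
  if (is.na(ns) || ns < 1 || is.na(n_rec)) abort("Malformed EDF header.")
  sig <- readChar(con, 256 * ns, useBytes = TRUE)
  labels <- vapply(seq_len(ns), function(i) {
    trimws(substr(sig, (i - 1) * 16 + 1, i * 16))
  }, "")
  pos <- 16 * ns
  read_field <- function(width) {
    out <- vapply(seq_len(ns), function(i) {
      trimws(substr(sig, pos + (i - 1) * width + 1, pos + i * width))
    }, "")
    pos <<- pos + width * ns
    out
  }
  read_field(80)                       # transducer
  read_field(8)                        # physical dimension
  pmin <- as.numeric(read_field(8))
  pmax <- as.numeric(read_field(8))
  dmin <- as.numeric(read_field(8))
  dmax <- as.numeric(read_field(8))
  read_field(80)                       # prefiltering
  spr <- as.integer(read_field(8))     # samples per record per signal
  if (length(unique(spr)) != 1) {
    abort("Channels have different sampling rates; not supported.")
  }
  fs <- spr[1] / rec_dur
  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2,
                 endian = "little")
  if (length(raw) < n_rec * sum(spr)) abort("Truncated EDF data section.")
  X <- matrix(0, ns, n_rec * spr[1])
  arr <- array(raw, dim = c(spr[1], ns, n_rec))
  for (i in seq_len(ns)) X[i, ] <- as.numeric(arr[, i, ])
  gain <- (pmax - pmin) / (dmax - dmin)
  X <- X * gain + (pmin - dmin * gain)

  if (!is.null(highpass_hz)) {
    hp <- signal::butter(4, highpass_hz / (fs / 2), type = "high")
    X <- t(apply(X, 1, function(r) signal::filtfilt(hp, r)))
  }
  if (!is.null(notch_hz)) {
    bs <- signal::butter(2, c(notch_hz - 2, notch_hz + 2) / (fs / 2),
                         type = "stop")
    X <- t(apply(X, 1, function(r) signal::filtfilt(bs, r)))
  }
  sensor_recording(X, fs, labels = labels, meta = list(path = path))
}

#' @rdname read_edf
#' @param ... Passed to [read_edf()].
#' @export
read_recording <- function(path, ...) read_edf(path, ...)
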