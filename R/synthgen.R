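#' Simulate band-limited sources with planted envelope coupling
#'
#' Generates `n_rois` amplitude-modulated signals whose *envelopes* are
#' correlated by construction while their carrier phases stay independent.
#' Each signal is `x_i(t) = (1 + depth * e_i(t)) * c_i(t)` where the `c_i`
#' are independent band-limited Gaussian carriers and the `e_i` are slow,
#' standardized modulators sharing a common component:
#' `e_i = sqrt(rho) * g0 + sqrt(1 - rho) * g_i`. The planted quantity is the
#' modulator correlation `rho`; the resulting envelope correlation is close
#' to, but not identical to, `rho` (carrier envelope fluctuations dilute it),
#' which is why ground truth is always *measured* on the generated signals
#' rather than assumed.
#'
#' @param band One-row data frame with `low_hz`, `high_hz` (see
#'   [default_bands()]).
#' @param rho Planted modulator correlation in `[0, 1]`, shared by all pairs.
#' @param duration Length in seconds.
#' @param fs Sampling rate in Hz.
#' @param depth Modulation depth in `(0, 1)`.
#' @param n_rois Number of signals.
#' @param modulator_cutoff Low-pass cutoff of the modulators in Hz.
#' @param seed Integer seed; same seed, same output.
#' @return A numeric matrix (`n_rois` x samples) with attribute
#'   `"modulators"` carrying the slow envelopes used.
#' @examples
#' b1 <- default_bands("beta1")
#' s <- simulate_coupled_sources(b1, rho = 0.6, duration = 10, fs = 256, seed = 1)
#' dim(s)
#' @export
simulate_coupled_sources <- function(band, rho, duration, fs, depth = 0.5,
                                     n_rois = 4, modulator_cutoff = 1,
                                     seed = NULL) {
  check_number(rho, "rho", 0, 1)
  check_number(depth, "depth", 0, 1)
  check_bands(band, fs)
  n <- round(duration * fs)
  if (n < 2^12) abort("duration * fs must give at least 4096 samples.")
  rho_mat <- matrix(rho, n_rois, n_rois)
  diag(rho_mat) <- 1
  with_seed(seed, {
    e <- make_modulators(rho_mat, n, fs, modulator_cutoff, depth)
    carriers <- replicate(n_rois,
                          fft_butter(rnorm(n), band$low_hz, band$high_hz, fs))
    out <- t((1 + depth * t(e)) * carriers)
  })
  attr(out, "modulators") <- e
  out
}

# Zero-phase Butterworth filtering in the frequency domain: multiplies the
# spectrum by |H(w)|^2 (the forward-backward magnitude response of the
# 4th-order design), which for the generator's Gaussian-noise inputs is the
# same operation as bidirectional time-domain filtering but much cheaper.
.fft_butter_cache <- new.env(parent = emptyenv())

fft_butter <- function(x, low_hz, high_hz, fs, type = "pass") {
  n <- length(x)
  key <- paste(n, low_hz, high_hz, fs, type, sep = "|")
  H2 <- .fft_butter_cache[[key]]
  if (is.null(H2)) {
    bf <- if (type == "low") {
      signal::butter(4, high_hz / (fs / 2), type = "low")
    } else {
      signal::butter(4, c(low_hz, high_hz) / (fs / 2), type = "pass")
    }
    z <- exp(-2i * pi * seq.int(0, n - 1) / n)
    H <- (outer(z, seq_along(bf$b) - 1, `^`) %*% bf$b) /
      (outer(z, seq_along(bf$a) - 1, `^`) %*% bf$a)
    H2 <- as.numeric(Mod(H)^2)
    .fft_butter_cache[[key]] <- H2
  }
  Re(fft(fft(x) * H2, inverse = TRUE)) / n
}

# Slow modulators with a target correlation matrix: low-passed white noise,
# standardized, mixed by the symmetric square root of `rho_mat`, then
# clipped so 1 + depth * e stays >= 0.05 (avoids carrier sign inversion).
make_modulators <- function(rho_mat, n, fs, cutoff, depth) {
  k <- nrow(rho_mat)
  g <- replicate(k, {
    z <- fft_butter(rnorm(n), 0, cutoff, fs, type = "low")
    (z - mean(z)) / sd(z)
  })
  ev <- eigen(rho_mat, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    abort("Planted coupling matrix is not positive semi-definite; lower the rhos.")
  }
  root <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  e <- g %*% root                     # n x k, columns have cor ~ rho_mat
  if (depth > 0) e <- pmax(e, (0.05 - 1) / depth)
  t(e)                                # k x n
}

#' Toy lead field for pipeline tests
#'
#' A full-column-rank sensor-by-source mixing matrix standing in for a
#' head-model forward solution: each source projects a smooth spatial
#' profile (a Gaussian bump across the sensor array) so neighbouring
#' sensors see correlated mixtures, the signature of volume conduction.
#' Columns are unit-normalized and the matrix is conditioned (condition
#' number < 100) so the minimum-norm inverse is well posed.
#'
#' @param n_sensors Number of sensors (rows).
#' @param n_sources Number of source components (columns); must not exceed
#'   `n_sensors`.
#' @param smoothness Spatial spread of each source's sensor footprint as a
#'   fraction of the array, in `(0, 1)`.
#' @param seed Integer seed.
#' @param identity If `TRUE`, return the `n_sensors` x `n_sensors` identity
#'   (for pipeline self-tests); other arguments are ignored except
#'   `n_sensors`.
#' @return Matrix with attributes `sensor_labels` and `source_labels`.
#' @export
make_toy_leadfield <- function(n_sensors, n_sources, smoothness = 0.25,
                               seed = NULL, identity = FALSE) {
  if (identity) {
    L <- diag(n_sensors)
  } else {
    if (n_sensors < n_sources) {
      abort("Cannot build a full-column-rank lead field: n_sensors < n_sources.")
    }
    check_number(smoothness, "smoothness", 0, 1, strict = TRUE)
    centers <- (seq_len(n_sources) - 0.5) / n_sources * n_sensors
    width <- max(1, smoothness * n_sensors / 2)
    pos <- seq_len(n_sensors)
    L <- with_seed(seed, {
      base <- vapply(centers, function(c0) exp(-0.5 * ((pos - c0) / width)^2),
                     numeric(n_sensors))
      base + matrix(rnorm(n_sensors * n_sources, sd = 0.05), n_sensors)
    })
    # guarantee conditioning by blending toward the orthonormal polar factor
    for (i in 1:50) {
      sv <- svd(L)
      if (sv$d[1] / sv$d[length(sv$d)] < 100) break
      Q <- sv$u %*% t(sv$v)
      L <- 0.9 * L + 0.1 * Q
    }
    L <- sweep(L, 2, sqrt(colSums(L^2)), "/")
  }
  attr(L, "sensor_labels") <- sprintf("CH%03d", seq_len(nrow(L)))
  attr(L, "source_labels") <- sprintf("SRC%02d", seq_len(ncol(L)))
  L
}

#' Project sources to sensors with additive noise
#'
#' `X = L S + N` with white Gaussian `N` scaled so that
#' `power(L S) / power(N) = snr`. This is the volume-conduction step: even
#' envelope-uncoupled sources become instantaneously correlated at the
#' sensors, which is exactly the artifact the orthogonalization stage must
#' remove downstream.
#'
#' @param sources Source matrix (`n_sources` x samples) or `roi_timeseries`.
#' @param leadfield Mixing matrix from [make_toy_leadfield()] (or any
#'   sensors x sources matrix).
#' @param snr Signal-to-noise power ratio; `Inf` disables noise.
#' @param fs Sampling rate in Hz (taken from `sources` if a
#'   `roi_timeseries`).
#' @param seed Integer seed for the noise.
#' @return A [sensor_recording()].
#' @export
mix_to_sensors <- function(sources, leadfield, snr, fs = NULL, seed = NULL) {
  if (inherits(sources, "roi_timeseries")) {
    fs <- fs %||% sources$fs
    sources <- sources$data
  }
  if (is.null(fs)) abort("`fs` is required when `sources` is a bare matrix.")
  if (!is.numeric(snr) || snr <= 0) abort("`snr` must be positive (use Inf for noiseless).")
  if (ncol(leadfield) != nrow(sources)) {
    abort(sprintf("Lead field has %d source columns but %d source rows supplied.",
                  ncol(leadfield), nrow(sources)))
  }
  clean <- leadfield %*% sources
  if (is.finite(snr)) {
    noise_sd <- sqrt(mean(clean^2) / snr)
    noise <- with_seed(seed, matrix(rnorm(length(clean), sd = noise_sd), nrow(clean)))
    x <- clean + noise
  } else {
    x <- clean
  }
  sensor_recording(x, fs, labels = attr(leadfield, "sensor_labels"),
                   meta = list(snr = snr, seed = seed))
}

#' Default planted coupling specification
#'
#' One tibble row per (ROI pair, band) cell with a planted modulator
#' correlation per group. The default plants a single deficit mirroring the
#' effect the analysis is built to detect: strong beta-1 coupling between
#' the left sgACC and right DLPFC in controls (`rho = 0.7`), weakened in
#' patients (`rho = 0.2`). All other cells are uncoupled in both groups.
#'
#' @param rho_control,rho_patient Modulator correlations for the planted cell.
#' @param pair_roi_a,pair_roi_b,band The planted cell.
#' @return Tibble with columns `roi_a`, `roi_b`, `band`, `rho_control`,
#'   `rho_patient`.
#' @export
default_coupling <- function(rho_control = 0.7, rho_patient = 0.2,
                             pair_roi_a = "DLPFC_R", pair_roi_b = "sgACC_L",
                             band = "beta1") {
  tibble::tibble(
    roi_a = pair_roi_a, roi_b = pair_roi_b, band = band,
    rho_control = rho_control, rho_patient = rho_patient
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic study. Defaults mirror the target
#' study design: two cohorts of 20 subjects, 128-channel recordings sampled
#' at 512 Hz, 6-minute eyes-closed segments, four ROIs, six bands, and a
#' planted beta-1 sgACC-DLPFC coupling deficit in the patient group. The
#' covariate model ties a patient's lifetime episode count negatively to
#' their realized coupling strength.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param fs Sampling rate in Hz.
#' @param duration Recording length in seconds.
#' @param n_sensors Number of sensors.
#' @param rois ROI names (one simulated source per ROI).
#' @param bands Band tibble (see [default_bands()]).
#' @param coupling Coupling tibble (see [default_coupling()]).
#' @param modulator_cutoff Modulator low-pass cutoff in Hz.
#' @param modulation_depth Modulation depth in `(0, 1)`.
#' @param sensor_snr Sensor-level signal-to-noise power ratio.
#' @param covariate_intercept,covariate_slope,covariate_noise_sd Episode-count
#'   model: `episodes = round(max(1, a + b * AEC + noise))` evaluated on the
#'   planted cell's realized envelope correlation; the default slope is
#'   negative (fewer episodes when coupling is stronger).
#' @param truth_bands `"coupling"` (default) measures ground-truth envelope
#'   correlations only for bands appearing in the coupling table;
#'   `"all"` measures every band (slower, used when the uncoupled bands'
#'   truth is itself of interest).
#' @param seed Master seed; every subject stream derives from it.
#' @return An `oaec_sim_config` list.
#' @export
simulation_config <- function(n_per_group = 20, fs = 512, duration = 360,
                              n_sensors = 128,
                              rois = c("DLPFC_L", "DLPFC_R", "sgACC_L", "sgACC_R"),
                              bands = default_bands(),
                              coupling = default_coupling(),
                              modulator_cutoff = 1, modulation_depth = 0.5,
                              sensor_snr = 4,
                              covariate_intercept = 18, covariate_slope = -60,
                              covariate_noise_sd = 3,
                              truth_bands = c("coupling", "all"),
                              seed = 1L) {
  truth_bands <- match.arg(truth_bands)
  if (n_per_group < 2) abort("Need at least 2 subjects per group.")
  check_bands(bands, fs)
  if (fs <= 2 * max(bands$high_hz)) {
    abort("fs must exceed twice the highest band edge in use.")
  }
  if (round(duration * fs) < 2^12) abort("duration * fs must be >= 4096 samples.")
  if (n_sensors < length(rois)) abort("Need at least as many sensors as ROIs.")
  bad <- !(coupling$roi_a %in% rois) | !(coupling$roi_b %in% rois) |
    !(coupling$band %in% bands$band) |
    coupling$rho_control < 0 | coupling$rho_control > 1 |
    coupling$rho_patient < 0 | coupling$rho_patient > 1
  if (any(bad)) abort("Invalid coupling specification row(s).")
  structure(
    list(n_per_group = n_per_group, fs = fs, duration = duration,
         n_sensors = n_sensors, rois = sort(rois), bands = bands,
         coupling = coupling, modulator_cutoff = modulator_cutoff,
         modulation_depth = modulation_depth, sensor_snr = sensor_snr,
         covariate_intercept = covariate_intercept,
         covariate_slope = covariate_slope,
         covariate_noise_sd = covariate_noise_sd,
         truth_bands = truth_bands,
         seed = as.integer(seed)),
    class = "oaec_sim_config"
  )
}

# per-band ROI correlation matrix for one group from the coupling tibble
coupling_matrix <- function(config, band_name, group) {
  rois <- config$rois
  R <- diag(length(rois))
  dimnames(R) <- list(rois, rois)
  rows <- config$coupling[config$coupling$band == band_name, ]
  col <- if (group == "control") "rho_control" else "rho_patient"
  for (i in seq_len(nrow(rows))) {
    a <- rows$roi_a[i]; b <- rows$roi_b[i]
    R[a, b] <- R[b, a] <- rows[[col]][i]
  }
  R
}

#' Simulate a full synthetic cohort
#'
#' Generates, per subject, noiseless ROI source signals (the sum over bands
#' of amplitude-modulated carriers whose modulator correlations follow the
#' group's coupling spec), mixes them through a shared toy lead field with
#' sensor noise, measures ground-truth envelope correlations on the
#' noiseless sources, and draws demographics plus an episode count tied to
#' the planted cell's realized coupling. Controls are listed first. The two
#' groups differ only through the coupling specification.
#'
#' @param config An [simulation_config()] object.
#' @return An `oaec_cohort` list with elements `config`, `leadfield`,
#'   `roi_map`, `recordings` (list of [sensor_recording()]), `sources`
#'   (list of noiseless [roi_timeseries()]), `true_aec` (long tibble:
#'   subject_id, roi_a, roi_b, band, aec), and `cohort` (tibble of labels
#'   and covariates).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "oaec_sim_config"))
  rois <- config$rois
  n_rois <- length(rois)
  n <- round(config$duration * config$fs)
  fs <- config$fs
  groups <- rep(c("control", "patient"), each = config$n_per_group)
  ids <- sprintf("S%03d", seq_along(groups))

  leadfield <- make_toy_leadfield(config$n_sensors, n_rois,
                                  seed = derive_seed(config$seed, 0L))
  attr(leadfield, "source_labels") <- rois
  roi_map <- stats::setNames(as.list(seq_len(n_rois)), rois)
  pairs <- roi_pairs(rois)

  per_subject <- purrr::map2(seq_along(ids), groups, function(i, grp) {
    sseed <- derive_seed(config$seed, i)
    comps <- vector("list", nrow(config$bands))
    src <- matrix(0, n_rois, n)
    with_seed(sseed, {
      for (bi in seq_len(nrow(config$bands))) {
        band <- config$bands[bi, ]
        R <- coupling_matrix(config, band$band, grp)
        e <- make_modulators(R, n, fs, config$modulator_cutoff,
                             config$modulation_depth)
        carriers <- replicate(n_rois,
                              fft_butter(rnorm(n), band$low_hz, band$high_hz, fs))
        comp <- t((1 + config$modulation_depth * t(e)) * carriers)
        comps[[bi]] <- comp
        src <- src + comp
      }
    })
    # ground truth AEC: envelope correlation of the isolated band components
    trim <- seq.int(fs + 1, n - fs)
    tb <- if (identical(config$truth_bands %||% "all", "coupling")) {
      which(config$bands$band %in% unique(config$coupling$band))
    } else {
      seq_len(nrow(config$bands))
    }
    truth <- purrr::map_dfr(tb, function(bi) {
      env <- t(apply(comps[[bi]], 1, amplitude_envelope))
      cc <- stats::cor(t(env[, trim, drop = FALSE]))
      tibble::tibble(
        subject_id = ids[i],
        roi_a = pairs$roi_a, roi_b = pairs$roi_b,
        band = config$bands$band[bi],
        aec = cc[cbind(match(pairs$roi_a, rois), match(pairs$roi_b, rois))]
      )
    })
    rec <- mix_to_sensors(src, leadfield, config$sensor_snr, fs = fs,
                          seed = derive_seed(sseed, 1L))
    rec$meta$subject_id <- ids[i]
    list(source = roi_timeseries(src, fs, rois), recording = rec, truth = truth)
  })

  true_aec <- purrr::map_dfr(per_subject, "truth")
  cohort <- draw_covariates(ids, groups, true_aec, config)

  structure(
    list(config = config, leadfield = leadfield, roi_map = roi_map,
         recordings = stats::setNames(purrr::map(per_subject, "recording"), ids),
         sources = stats::setNames(purrr::map(per_subject, "source"), ids),
         true_aec = true_aec, cohort = cohort),
    class = "oaec_cohort"
  )
}

# Demographics emulate the target study's Table-1 marginals; the episodes
# count is the only covariate tied to connectivity (negatively, through the
# planted cell's realized AEC).
draw_covariates <- function(ids, groups, true_aec, config) {
  target <- config$coupling[which.max(abs(config$coupling$rho_control -
                                            config$coupling$rho_patient)), ]
  aec_target <- true_aec[true_aec$roi_a == target$roi_a &
                           true_aec$roi_b == target$roi_b &
                           true_aec$band == target$band, ]
  aec_target <- aec_target$aec[match(ids, aec_target$subject_id)]
  with_seed(derive_seed(config$seed, 999983L), {
    n <- length(ids)
    is_pat <- groups == "patient"
    age <- round(ifelse(is_pat, rnorm(n, 36.6, 13.1), rnorm(n, 41.25, 14.6)))
    age <- pmin(pmax(age, 18), 70)
    sex <- ifelse(runif(n) < ifelse(is_pat, 0.65, 0.75), "F", "M")
    edu_p <- ifelse(is_pat, list(c(.40, .45, .15)), list(c(.20, .45, .35)))
    education <- vapply(edu_p, function(p) sample(c("HS", "BA", "MA"), 1, prob = p), "")
    severity <- ifelse(is_pat, rnorm(n, 33.45, 11.41), pmax(rnorm(n, 1.45, 3.71), 0))
    severity <- round(pmax(severity, 0), 1)
    episodes <- round(pmax(1, config$covariate_intercept +
                             config$covariate_slope * aec_target +
                             rnorm(n, 0, config$covariate_noise_sd)))
    episodes[!is_pat] <- 0L
    tibble::tibble(
      subject_id = ids, group = groups, age = age, sex = sex,
      education = education, severity = severity,
      episodes = as.integer(episodes)
    )
  })
}

#' @export
print.oaec_cohort <- function(x, ...) {
  cat(sprintf("<oaec_cohort> %d subjects (%d control / %d patient), %d sensors, %g Hz, %g s\n",
              length(x$recordings), sum(x$cohort$group == "control"),
              sum(x$cohort$group == "patient"), x$config$n_sensors,
              x$config$fs, x$config$duration))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One EDF file per subject plus `cohort.csv` (labels and covariates) and
#' `ground_truth.json` (coupling spec, master seed, measured true envelope
#' correlations).
#'
#' @param cohort An `oaec_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "oaec_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edf_files <- purrr::imap_chr(cohort$recordings, function(rec, id) {
    path <- file.path(dir, paste0(id, ".edf"))
    write_edf(rec, path)
    path
  })
  csv <- file.path(dir, "cohort.csv")
  utils::write.csv(cohort$cohort, csv, row.names = FALSE)
  gt <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(seed = cohort$config$seed,
         coupling = cohort$config$coupling,
         true_aec = cohort$true_aec),
    gt, auto_unbox = TRUE, digits = NA
  )
  invisible(c(edf_files, csv, gt))
}
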