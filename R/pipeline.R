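#' Lead-field and ROI-definition containers
#'
#' The forward model and ROI membership travel as small JSON documents:
#' the lead field as `{sensor_labels, source_labels, matrix}` (row-major
#' list of rows), ROI definitions as a named map from ROI name to source
#' indices.
#'
#' @param leadfield Sensors x sources matrix.
#' @param path File path.
#' @return `read_leadfield()` returns the matrix with label attributes;
#'   `read_roi_map()` a named list of integer vectors; writers return the
#'   path invisibly.
#' @export
write_leadfield <- function(leadfield, path) {
  jsonlite::write_json(
    list(sensor_labels = attr(leadfield, "sensor_labels"),
         source_labels = attr(leadfield, "source_labels"),
         matrix = lapply(seq_len(nrow(leadfield)),
                         function(i) unname(unclass(leadfield)[i, ]))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_leadfield
#' @export
read_leadfield <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- if (is.matrix(obj$matrix)) {
    obj$matrix
  } else {
    do.call(rbind, lapply(obj$matrix, as.numeric))
  }
  attr(L, "sensor_labels") <- obj$sensor_labels
  attr(L, "source_labels") <- obj$source_labels
  L
}

#' @rdname write_leadfield
#' @param roi_map Named list: ROI name -> source indices.
#' @export
write_roi_map <- function(roi_map, path) {
  jsonlite::write_json(roi_map, path, digits = NA)
  invisible(path)
}

#' @rdname write_leadfield
#' @export
read_roi_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(obj, as.integer)
}

#' Pipeline run configuration
#'
#' Everything one end-to-end analysis needs. Either `simulate` is a
#' [simulation_config()] (synthetic study) or the four input paths point at
#' recordings (one EDF per subject), a lead-field JSON, an ROI JSON and a
#' cohort CSV. Every stochastic stage derives its stream from `seed`.
#'
#' @param output_dir Directory for all outputs (created if needed).
#' @param seed Master integer seed.
#' @param simulate Optional [simulation_config()].
#' @param recordings_dir,leadfield_file,roi_file,cohort_file Real-data
#'   entry points (ignored when `simulate` is given).
#' @param bands Band tibble.
#' @param orthogonalize,window_s,lambda2 Connectivity options (see [aec()]
#'   and [compute_inverse_operator()]).
#' @param n_perm,q Permutation count and FDR level for the statistics.
#' @param covariates Cohort columns to correlate with the strongest cell.
#' @param classifier_band Band whose sgACC-DLPFC features feed the SVM.
#' @param box_constraint,kernel_scale,standardize SVM settings (see
#'   [loocv_svm()]).
#' @param highpass_hz,notch_hz Preprocessing applied when reading EDFs.
#' @return An `oaec_run_config` list.
#' @export
run_config <- function(output_dir, seed = 1L, simulate = NULL,
                       recordings_dir = NULL, leadfield_file = NULL,
                       roi_file = NULL, cohort_file = NULL,
                       bands = default_bands(), orthogonalize = TRUE,
                       window_s = NULL, lambda2 = 1 / 9,
                       n_perm = 10000, q = 0.05,
                       covariates = "episodes", classifier_band = "beta1",
                       box_constraint = 3, kernel_scale = 1,
                       standardize = FALSE,
                       highpass_hz = NULL, notch_hz = NULL) {
  if (is.null(simulate)) {
    for (p in c(recordings_dir, leadfield_file, roi_file, cohort_file)) {
      if (is.null(p) || !file.exists(p)) {
        abort("Without `simulate`, all four input paths must exist.")
      }
    }
  }
  structure(
    list(output_dir = output_dir, seed = as.integer(seed), simulate = simulate,
         recordings_dir = recordings_dir, leadfield_file = leadfield_file,
         roi_file = roi_file, cohort_file = cohort_file, bands = bands,
         orthogonalize = orthogonalize, window_s = window_s, lambda2 = lambda2,
         n_perm = n_perm, q = q, covariates = covariates,
         classifier_band = classifier_band, box_constraint = box_constraint,
         kernel_scale = kernel_scale, standardize = standardize,
         highpass_hz = highpass_hz, notch_hz = notch_hz),
    class = "oaec_run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [run_config()] arguments; a `simulate:` block mirrors
#' [simulation_config()] arguments, with `bands:` given as a list of
#' `{band, low_hz, high_hz}` and `coupling:` as rows of
#' `{roi_a, roi_b, band, rho_control, rho_patient}`.
#'
#' @param path YAML file path.
#' @return An `oaec_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  to_tbl <- function(rows) dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  if (!is.null(y$bands)) y$bands <- to_tbl(y$bands)
  if (!is.null(y$simulate)) {
    sim <- y$simulate
    if (!is.null(sim$bands)) sim$bands <- to_tbl(sim$bands)
    if (!is.null(sim$coupling)) sim$coupling <- to_tbl(sim$coupling)
    y$simulate <- do.call(simulation_config, sim)
  }
  do.call(run_config, y)
}

# temp-then-rename so no partial output file ever appears
write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writer(tmp)
  # sidecar JSON written by stage writers alongside the TSV
  side <- paste0(tmp, ".json")
  ok <- file.rename(tmp, path)
  if (file.exists(side)) file.rename(side, paste0(path, ".json"))
  if (!ok) abort(paste0("Could not write ", path))
  invisible(path)
}

#' Run the end-to-end analysis
#'
#' Executes the full chain: obtain the cohort (simulate or load), compute
#' per-subject orthogonalized envelope connectivity through the
#' minimum-norm inverse, contrast the groups with permutation t-tests and
#' BH-FDR, correlate the strongest cell with clinical covariates in the
#' patient group, and evaluate the band's sgACC-DLPFC features with a
#' leave-one-out RBF-SVM. All tables are written as TSV and all summaries
#' as JSON under `output_dir`, each stamped with the configuration hash;
#' files appear atomically (temp-then-rename), and a rerun with the same
#' configuration reproduces every numeric output exactly.
#'
#' @param cfg An [run_config()] object.
#' @return Invisibly, a list with the in-memory results: `connectivity`,
#'   `statmap`, `comparison`, `covariate_assoc`, `loocv`, `metrics`,
#'   `top_cell`, `hash`, `files`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "oaec_run_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(unclass(cfg))
  message("run_pipeline: config hash ", hash)

  if (!is.null(cfg$simulate)) {
    cohort_obj <- simulate_cohort(cfg$simulate)
    recordings <- cohort_obj$recordings
    leadfield <- cohort_obj$leadfield
    roi_map <- cohort_obj$roi_map
    cohort <- cohort_obj$cohort
  } else {
    files <- sort(list.files(cfg$recordings_dir, pattern = "\\.edf$",
                             full.names = TRUE))
    if (length(files) == 0) abort("No EDF files in `recordings_dir`.")
    recordings <- lapply(files, read_edf, highpass_hz = cfg$highpass_hz,
                         notch_hz = cfg$notch_hz)
    names(recordings) <- sub("\\.edf$", "", basename(files))
    leadfield <- read_leadfield(cfg$leadfield_file)
    roi_map <- read_roi_map(cfg$roi_file)
    cohort <- tibble::as_tibble(utils::read.csv(cfg$cohort_file,
                                                stringsAsFactors = FALSE))
  }

  conn <- cohort_connectivity(recordings, leadfield, roi_map,
                              bands = cfg$bands, lambda2 = cfg$lambda2,
                              orthogonalize = cfg$orthogonalize,
                              window_s = cfg$window_s)
  conn_path <- file.path(cfg$output_dir, "connectivity.tsv")
  write_atomic(conn_path, function(p) {
    write_connectivity(conn, p, meta = list(hash = hash, seed = cfg$seed))
  })

  statmap <- group_contrast(conn, cohort[, c("subject_id", "group")],
                            q = cfg$q, n_perm = cfg$n_perm,
                            seed = derive_seed(cfg$seed, 1L))
  stat_path <- file.path(cfg$output_dir, "statmap.tsv")
  write_atomic(stat_path, function(p) write_statmap(statmap, p))

  comparison <- cohort_comparison(cohort)
  comp_path <- file.path(cfg$output_dir, "cohort_comparison.tsv")
  write_atomic(comp_path, function(p) {
    utils::write.table(comparison, p, sep = "\t", row.names = FALSE, quote = FALSE)
  })

  top <- statmap[which.max(abs(statmap$t)), ]
  patients <- cohort$subject_id[cohort$group != attr(statmap, "control")]
  assoc <- correlate_covariates(conn, cohort, pair = top$pair, band = top$band,
                                covariates = cfg$covariates,
                                subjects = patients, n_perm = cfg$n_perm,
                                seed = derive_seed(cfg$seed, 2L), q = cfg$q)
  assoc_path <- file.path(cfg$output_dir, "covariate_assoc.tsv")
  write_atomic(assoc_path, function(p) {
    utils::write.table(cbind(pair = top$pair, band = top$band, assoc), p,
                       sep = "\t", row.names = FALSE, quote = FALSE)
  })

  feats <- connectivity_features(conn, band = cfg$classifier_band)
  labels <- cohort$group[match(feats$subject_id, cohort$subject_id)]
  loocv <- loocv_svm(as.matrix(feats[, -1]), labels,
                     box_constraint = cfg$box_constraint,
                     kernel_scale = cfg$kernel_scale,
                     standardize = cfg$standardize)
  metrics <- classification_metrics(loocv,
                                    positive_class = setdiff(unique(labels),
                                                             "control")[1])
  metrics_path <- file.path(cfg$output_dir, "classifier_metrics.json")
  write_atomic(metrics_path, function(p) {
    jsonlite::write_json(c(as.list(metrics),
                           list(hash = hash, band = cfg$classifier_band)),
                         p, auto_unbox = TRUE, digits = NA)
  })

  log_path <- file.path(cfg$output_dir, "run_log.json")
  write_atomic(log_path, function(p) {
    jsonlite::write_json(
      list(hash = hash, seed = cfg$seed,
           package_version = as.character(utils::packageVersion("oaec")),
           n_subjects = length(recordings),
           top_cell = list(pair = top$pair, band = top$band, t = top$t),
           outputs = basename(c(conn_path, stat_path, comp_path, assoc_path,
                                metrics_path))),
      p, auto_unbox = TRUE, digits = NA)
  })

  invisible(list(connectivity = conn, statmap = statmap,
                 comparison = comparison, covariate_assoc = assoc,
                 loocv = loocv, metrics = metrics, top_cell = top,
                 hash = hash,
                 files = c(conn_path, stat_path, comp_path, assoc_path,
                           metrics_path, log_path)))
}
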