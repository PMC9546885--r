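b1 <- default_bands("beta1")

test_that("coupled sources are deterministic and shaped correctly", {
  s1 <- simulate_coupled_sources(b1, rho = 0.5, duration = 16, fs = 256,
                                 n_rois = 3, seed = 42)
  s2 <- simulate_coupled_sources(b1, rho = 0.5, duration = 16, fs = 256,
                                 n_rois = 3, seed = 42)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(3, 16 * 256))
  expect_error(simulate_coupled_sources(b1, rho = 1.2, 16, 256, seed = 1),
               "rho")
  expect_error(
    simulate_coupled_sources(tibble::tibble(band = "bad", low_hz = 100,
                                            high_hz = 140),
                             rho = 0.5, 16, 256, seed = 1),
    "Nyquist")
})

test_that("envelope correlation is near zero at rho = 0 and monotone in rho", {
  fs <- 256
  rhos <- c(0, 0.25, 0.5, 0.75, 1)
  # average over a few seeds so monotonicity is tested on the expectation
  mean_cor <- vapply(rhos, function(rho) {
    mean(vapply(1:4, function(sd) {
      s <- simulate_coupled_sources(b1, rho, duration = 60, fs = fs,
                                    n_rois = 2, seed = 100 + sd)
      oracle_envelope_cor(s, fs)[1, 2]
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean_cor[1]), 3 / sqrt(60))
  expect_true(all(diff(mean_cor) > 0))
})

test_that("toy lead field meets its rank, conditioning and determinism contract", {
  L <- make_toy_leadfield(8, 4, seed = 7)
  expect_equal(dim(L), c(8, 4))
  expect_equal(qr(L)$rank, 4)
  expect_lt(kappa(L, exact = TRUE), 100)
  expect_equal(colSums(L^2), rep(1, 4), tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(L, make_toy_leadfield(8, 4, seed = 7))
  expect_false(identical(L, make_toy_leadfield(8, 4, seed = 8)))
  expect_equal(unclass(make_toy_leadfield(5, 5, identity = TRUE))[, ],
               diag(5), ignore_attr = TRUE)
  expect_error(make_toy_leadfield(3, 4, seed = 1), "full-column-rank")
})

test_that("sensor mixing respects the requested SNR and identity limit", {
  fs <- 256
  src <- simulate_coupled_sources(b1, 0.3, duration = 300, fs = fs,
                                  n_rois = 4, seed = 3)
  Lid <- make_toy_leadfield(4, 4, identity = TRUE)
  rec0 <- mix_to_sensors(src, Lid, snr = Inf, fs = fs)
  expect_equal(rec0$data, src, ignore_attr = TRUE)

  L <- make_toy_leadfield(8, 4, seed = 5)
  rec <- mix_to_sensors(src, L, snr = 4, fs = fs, seed = 9)
  clean <- L %*% src
  noise <- rec$data - clean
  ratio <- mean(clean^2) / mean(noise^2)
  expect_lt(abs(ratio - 4), 0.4)

  # volume conduction: uncoupled sources become correlated at the sensors
  src0 <- simulate_coupled_sources(b1, 0, duration = 30, fs = fs,
                                   n_rois = 2, seed = 4)
  recm <- mix_to_sensors(src0, make_toy_leadfield(4, 2, seed = 2), snr = Inf,
                         fs = fs)
  cc <- cor(t(recm$data))
  expect_gt(max(abs(cc[upper.tri(cc)])), 0.2)

  expect_error(mix_to_sensors(src, L, snr = -1, fs = fs), "positive")
  expect_error(mix_to_sensors(src[1:2, ], L, snr = 4, fs = fs), "source")
})

test_that("simulated cohorts are consistent, reproducible and carry the planted structure", {
  cfg <- tiny_cohort_config(seed = 21, n_per_group = 3, truth_bands = "all")
  co <- simulate_cohort(cfg)
  expect_s3_class(co, "oaec_cohort")
  expect_length(co$recordings, 6)
  expect_length(co$sources, 6)
  expect_equal(nrow(co$cohort), 6)
  expect_equal(co$cohort$group, rep(c("control", "patient"), each = 3))
  expect_true(all(co$true_aec$aec >= -1 & co$true_aec$aec <= 1))
  expect_equal(nrow(co$true_aec), 6 * 6 * 6)  # subjects x pairs x bands
  expect_true(all(co$cohort$episodes[co$cohort$group == "patient"] >= 1))

  co2 <- simulate_cohort(tiny_cohort_config(seed = 21, n_per_group = 3,
                                            truth_bands = "all"))
  expect_identical(co$recordings[[1]]$data, co2$recordings[[1]]$data)
  expect_identical(co$true_aec, co2$true_aec)
  expect_identical(co$cohort, co2$cohort)
})

test_that("planted group difference and covariate coupling point the right way", {
  cfg <- simulation_config(n_per_group = 8, fs = 256, duration = 30,
                           n_sensors = 8, seed = 33)
  co <- simulate_cohort(cfg)
  cell <- dplyr::filter(co$true_aec, roi_a == "DLPFC_R", roi_b == "sgACC_L",
                        band == "beta1")
  grp <- co$cohort$group[match(cell$subject_id, co$cohort$subject_id)]
  expect_gt(mean(cell$aec[grp == "control"]), mean(cell$aec[grp == "patient"]))

  pats <- co$cohort$group == "patient"
  aec_p <- cell$aec[match(co$cohort$subject_id[pats], cell$subject_id)]
  expect_lt(cor(co$cohort$episodes[pats], aec_p), 0)
})

test_that("cohorts round-trip to disk as EDF + CSV + JSON", {
  cfg <- tiny_cohort_config(seed = 5, duration = 16)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  files <- write_cohort(co, dir)
  expect_true(all(file.exists(files)))
  back <- read_edf(file.path(dir, "S001.edf"))
  expect_equal(back$fs, 256)
  tol <- max(apply(co$recordings[[1]]$data, 1, function(r) diff(range(r)))) / 65535
  expect_lt(max(abs(back$data - co$recordings[[1]]$data)), 2 * tol)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$seed, 5)
})
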