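test_that("band-pass filter has unit passband gain, strong stopband rejection, near-idempotence", {
  fs <- 512
  t <- seq(0, 10, by = 1 / fs)
  inside <- (fs + 1):(length(t) - fs)   # away from 1-s edges

  tone <- sin(2 * pi * 15 * t)
  y <- bandpass(tone, 13, 17, fs)
  gain <- sqrt(mean(y[inside]^2)) / sqrt(mean(tone[inside]^2))
  expect_gte(gain, 0.95)
  expect_lte(gain, 1.0)

  slow <- sin(2 * pi * 2 * t)
  y2 <- bandpass(slow, 13, 17, fs)
  expect_lt(sqrt(mean(y2[inside]^2)) / sqrt(mean(slow[inside]^2)), 0.05)

  expect_length(y, length(tone))

  set.seed(10)
  w <- rnorm(fs * 10)
  once <- bandpass(w, 13, 17, fs)
  twice <- bandpass(once, 13, 17, fs)
  first_change <- sqrt(mean((once - w)^2))
  second_change <- sqrt(mean((twice - once)^2))
  expect_lt(second_change, 0.05 * first_change)

  expect_error(bandpass(w, 13, 300, fs), "Nyquist")
  expect_error(bandpass(w[1:10], 13, 17, fs), "short")
})

test_that("amplitude envelope recovers tone amplitude and the analytic AM envelope", {
  fs <- 512
  t <- seq(0, 10, by = 1 / fs)
  inside <- (fs / 2):(length(t) - fs / 2)

  env <- amplitude_envelope(2.5 * sin(2 * pi * 15 * t))
  expect_lt(abs(mean(env[inside]) - 2.5) / 2.5, 0.02)
  expect_true(all(env >= 0))

  am <- (1 + 0.5 * cos(2 * pi * 1 * t)) * sin(2 * pi * 15 * t)
  env2 <- amplitude_envelope(am)
  truth <- 1 + 0.5 * cos(2 * pi * 1 * t)
  expect_lt(max(abs(env2[inside] - truth[inside])), 0.05)

  expect_equal(amplitude_envelope(rep(0, 100)), rep(0, 100))
  expect_error(amplitude_envelope(c(1, NA)), "finite")
})

test_that("symmetric orthogonalization: fixed point, rank errors, optimality vs weaker oracles", {
  # already-orthogonal rows are (numerically) a fixed point
  set.seed(3)
  M0 <- t(qr.Q(qr(matrix(rnorm(3 * 500), 500, 3)))) * c(2, 3, 0.5)
  O0 <- symmetric_orthogonalize(M0)
  expect_lt(norm(M0 - O0, "F") / norm(M0, "F"), 1e-8)

  x <- rnorm(256)
  expect_error(symmetric_orthogonalize(rbind(x, x)), "Rank-deficient")

  set.seed(4)
  M <- matrix(rnorm(3 * 2048), 3)
  O <- symmetric_orthogonalize(M)
  G <- O %*% t(O)
  ndot <- abs(G[upper.tri(G)]) / (sqrt(diag(G)[1]) * sqrt(diag(G)[2]))
  expect_true(all(ndot < 1e-6))
  # no worse than the one-shot polar factor with matched row norms
  sv <- svd(M)
  polar <- diag(sqrt(rowSums(M^2))) %*% (sv$u %*% t(sv$v[, 1:3]))
  expect_lte(norm(M - O, "F"), norm(M - polar, "F") + 1e-10)

  # 2-row case: beats a dense grid search over row-space rotations
  set.seed(5)
  M2 <- matrix(rnorm(2 * 64), 2)
  O2 <- symmetric_orthogonalize(M2)
  B <- t(svd(M2)$v[, 1:2])
  grid_best <- min(vapply(seq(0, pi, length.out = 3601), function(th) {
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
    Q2 <- R %*% B
    d <- rowSums(M2 * Q2)          # optimal per-row magnitudes for this Q2
    norm(M2 - d * Q2, "F")
  }, numeric(1)))
  expect_lte(norm(M2 - O2, "F"), grid_best + 1e-6)
})

test_that("aec nulls exact leakage copies, is symmetric, bounded, and scale invariant", {
  fs <- 256
  x <- make_band_noise(fs * 40, 13, 17, fs, seed = 6)
  ts2 <- roi_timeseries(rbind(A = x, B = 0.5 * x), fs, c("A", "B"))
  b1 <- default_bands("beta1")

  raw <- aec(ts2, b1, orthogonalize = FALSE)
  expect_gt(raw$aec, 0.95)
  # an exact scaled copy is pure leakage: orthogonalization removes it all
  ort <- aec(ts2, b1, orthogonalize = TRUE)
  expect_lt(abs(ort$aec), 0.05)
  # near-copy with a little independent signal: still strongly suppressed
  y <- make_band_noise(fs * 40, 13, 17, fs, seed = 7)
  ts2b <- roi_timeseries(rbind(A = x, B = 0.5 * x + 0.05 * y), fs, c("A", "B"))
  expect_lt(abs(aec(ts2b, b1, orthogonalize = TRUE)$aec), 0.1)
  expect_gt(aec(ts2b, b1, orthogonalize = FALSE)$aec, 0.95)

  src <- simulate_coupled_sources(b1, 0.5, duration = 40, fs = fs,
                                  n_rois = 4, seed = 8)
  ts4 <- roi_timeseries(src, fs, c("sgACC_L", "DLPFC_R", "sgACC_R", "DLPFC_L"))
  out <- aec(ts4, default_bands(c("alpha", "beta1")))
  expect_true(all(out$aec >= -1 & out$aec <= 1))
  expect_equal(nrow(out), 12)              # 6 pairs x 2 bands
  expect_true(all(out$roi_a < out$roi_b))  # fixed lexicographic ordering

  scaled <- ts4
  scaled$data[2, ] <- 7 * scaled$data[2, ]
  out2 <- aec(scaled, default_bands(c("alpha", "beta1")))
  expect_equal(out$aec, out2$aec, tolerance = 1e-6)
})

test_that("windowed aec averages per-window correlations", {
  fs <- 256
  b1 <- default_bands("beta1")
  src <- simulate_coupled_sources(b1, 0.8, duration = 60, fs = fs,
                                  n_rois = 2, seed = 12)
  ts <- roi_timeseries(src, fs, c("A", "B"))
  full <- aec(ts, b1, orthogonalize = FALSE)
  win <- aec(ts, b1, orthogonalize = FALSE, window_s = 10)
  expect_true(abs(win$aec - full$aec) < 0.25)
  expect_true(win$aec > 0.1)
  expect_error(aec(ts, b1, window_s = 30), "short")
})

test_that("coupling planted in beta-1 does not bleed into other bands", {
  fs <- 256
  # run the generator with coupling only in beta1, compare other bands to a
  # fully uncoupled baseline of the same size
  coupled <- simulation_config(n_per_group = 6, fs = fs, duration = 30,
                               n_sensors = 8, seed = 51, truth_bands = "all")
  nullcfg <- simulation_config(n_per_group = 6, fs = fs, duration = 30,
                               n_sensors = 8, seed = 52, truth_bands = "all",
                               coupling = default_coupling(0, 0))
  aec_c <- simulate_cohort(coupled)$true_aec
  aec_0 <- simulate_cohort(nullcfg)$true_aec
  for (bd in setdiff(unique(aec_c$band), "beta1")) {
    a <- aec_c$aec[aec_c$band == bd]
    b <- aec_0$aec[aec_0$band == bd]
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    expect_lt(abs(mean(a) - mean(b)), 2.5 * se)
  }
})

test_that("cohort connectivity is deterministic, complete, and tracks planted coupling", {
  cfg <- tiny_cohort_config(seed = 61, n_per_group = 2, duration = 20)
  co <- simulate_cohort(cfg)
  conn <- cohort_connectivity(co)
  expect_equal(nrow(conn), 4 * 6 * 6)      # subjects x pairs x bands
  expect_equal(length(unique(conn$pair)), 6)

  # two subjects given identical recordings produce identical slices
  recs <- co$recordings[c(1, 1)]
  names(recs) <- c("A", "B")
  dup <- cohort_connectivity(recs, co$leadfield, co$roi_map,
                             bands = default_bands("beta1"))
  expect_equal(dup$aec[dup$subject_id == "A"], dup$aec[dup$subject_id == "B"])

  cfg2 <- simulation_config(n_per_group = 6, fs = 256, duration = 30,
                            n_sensors = 8, seed = 62)
  co2 <- simulate_cohort(cfg2)
  conn2 <- cohort_connectivity(co2)
  cell <- dplyr::filter(conn2, pair == "DLPFC_R-sgACC_L", band == "beta1")
  grp <- co2$cohort$group[match(cell$subject_id, co2$cohort$subject_id)]
  expect_gt(mean(cell$aec[grp == "control"]), mean(cell$aec[grp == "patient"]))
})
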