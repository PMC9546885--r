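test_that("noise covariance is the per-channel variance with degenerate channels patched", {
  set.seed(1)
  big <- sensor_recording(matrix(rnorm(8 * 1e5), 8), fs = 100)
  nm <- estimate_noise_covariance(big)
  expect_true(all(abs(nm$variances - 1) < 0.05))

  alt <- sensor_recording(rbind(rep(c(1, -1), 50), rep(c(2, -2), 50)), fs = 10)
  nm2 <- estimate_noise_covariance(alt)
  expect_equal(unname(nm2$variances[2] / nm2$variances[1]), 4)

  flat <- sensor_recording(rbind(rnorm(100), rep(1, 100)), fs = 10)
  expect_warning(nm3 <- estimate_noise_covariance(flat), "Constant channel")
  expect_equal(unname(nm3$variances[2]), unname(nm3$variances[1]))
  expect_equal(nm3$replaced, 2L)

  expect_error(
    estimate_noise_covariance(sensor_recording(matrix(0, 2, 10), fs = 10)),
    "constant")
})

test_that("minimum-norm operator matches its closed forms and the SVD oracle", {
  Lid <- make_toy_leadfield(4, 4, identity = TRUE)
  # identity limit: lambda2 -> 0 gives the identity operator
  inv0 <- compute_inverse_operator(Lid, noise = NULL, lambda2 = 1e-12)
  expect_equal(inv0$K, diag(4), tolerance = 1e-9, ignore_attr = TRUE)
  # closed form at lambda2 = 1: K = I/2
  inv1 <- compute_inverse_operator(Lid, noise = NULL, lambda2 = 1)
  expect_equal(inv1$K, diag(4) / 2, tolerance = 1e-12, ignore_attr = TRUE)

  set.seed(8)
  L <- matrix(rnorm(60), 10, 6)
  vars <- runif(10, 0.5, 2)
  rec <- sensor_recording(matrix(rnorm(10 * 50), 10), fs = 100)
  noise <- structure(list(variances = vars, replaced = integer(0)),
                     class = "oaec_noise_model")
  inv <- compute_inverse_operator(L, noise, lambda2 = 1 / 9)
  expect_equal(inv$K, oracle_mne_operator(L, vars, 1 / 9), tolerance = 1e-8)
  expect_error(compute_inverse_operator(L, noise, lambda2 = -1), "lambda2")
})

test_that("applying the inverse is linear and shrinks with regularization", {
  set.seed(9)
  L <- make_toy_leadfield(8, 4, seed = 2)
  inv <- compute_inverse_operator(L, noise = NULL, lambda2 = 1 / 9)
  X <- matrix(rnorm(8 * 200), 8)
  Y <- matrix(rnorm(8 * 200), 8)
  recX <- sensor_recording(X, fs = 100)

  expect_equal(apply_inverse(inv, sensor_recording(matrix(0, 8, 50), fs = 100)),
               matrix(0, 4, 50), ignore_attr = TRUE)
  SX <- apply_inverse(inv, recX)
  lin <- apply_inverse(inv, sensor_recording(2 * X + 3 * Y, fs = 100))
  expect_equal(lin, 2 * SX + 3 * apply_inverse(inv, sensor_recording(Y, fs = 100)),
               tolerance = 1e-10, ignore_attr = TRUE)

  norms <- vapply(c(0.01, 0.1, 1, 10), function(l2) {
    norm(apply_inverse(compute_inverse_operator(L, NULL, l2), recX), "F")
  }, numeric(1))
  expect_true(all(diff(norms) < 0))

  idinv <- compute_inverse_operator(make_toy_leadfield(8, 8, identity = TRUE),
                                    NULL, lambda2 = 1e-12)
  expect_equal(apply_inverse(idinv, recX), X, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(apply_inverse(inv, sensor_recording(matrix(0, 5, 10), fs = 1)),
               "channels")
})

test_that("reconstructed ROI sources track the ground truth on a toy cohort", {
  cfg <- simulation_config(n_per_group = 2, fs = 256, duration = 30,
                           n_sensors = 16, sensor_snr = 10, seed = 14)
  co <- simulate_cohort(cfg)
  noise <- estimate_noise_covariance(co$recordings[[1]])
  inv <- compute_inverse_operator(co$leadfield, noise)
  S <- apply_inverse(inv, co$recordings[[1]])
  ts <- extract_roi_timeseries(S, co$roi_map, fs = 256)
  for (i in seq_along(co$roi_map)) {
    expect_gt(cor(ts$data[i, ], co$sources[[1]]$data[i, ]), 0.8)
  }
})

test_that("ROI extraction collapses components and aligns signs without cancellation", {
  x <- make_band_noise(2000, 8, 12, 100, seed = 3)
  S1 <- rbind(x)
  one <- extract_roi_timeseries(S1, list(A = 1), fs = 100)
  expect_equal(one$data[1, ], x, ignore_attr = TRUE)

  two <- extract_roi_timeseries(rbind(x, x), list(A = c(1, 2)), fs = 100)
  expect_equal(two$data[1, ], x, ignore_attr = TRUE)

  flip <- extract_roi_timeseries(rbind(x, -x), list(A = c(1, 2)), fs = 100)
  expect_gt(abs(cor(flip$data[1, ], x)), 0.999)
  expect_gt(sd(flip$data[1, ]), 0.5 * sd(x))

  # 3-component dipole: PCA collapse recovers the dominant orientation
  y <- make_band_noise(2000, 8, 12, 100, seed = 4)
  block <- rbind(2 * x, x + 0.1 * y, 0.2 * y)
  pc <- extract_roi_timeseries(block, list(A = 1), fs = 100,
                               components_per_source = 3)
  expect_gt(cor(pc$data[1, ], x), 0.95)

  expect_error(extract_roi_timeseries(S1, list(A = integer(0)), fs = 100),
               "no sources")
  expect_error(extract_roi_timeseries(S1, list(A = 5), fs = 100),
               "out of range")
})
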