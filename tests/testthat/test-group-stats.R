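test_that("permutation t-test: identical groups, exhaustive oracle, planted effect", {
  a <- c(1, 2, 3, 4)
  tie <- permutation_t_test(a, a, n_perm = 500, seed = 1)
  expect_equal(tie$statistic, 0)
  expect_equal(tie$p_value, 1)

  expect_warning(deg <- permutation_t_test(rep(2, 5), rep(2, 5), n_perm = 200),
                 "identical")
  expect_equal(deg$p_value, 1)

  # 3 vs 3: Monte-Carlo p within 3 binomial SE of the exact enumeration
  x <- c(0.3, 1.2, 2.1)
  y <- c(1.8, 2.6, 3.4)
  p_exact <- oracle_exact_perm_p(x, y)
  mc <- permutation_t_test(x, y, n_perm = 4000, seed = 2)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(mc$p_value - p_exact), 3 * se + 1 / 4000)

  set.seed(3)
  big <- permutation_t_test(rnorm(20), rnorm(20, 3), n_perm = 10000, seed = 4)
  expect_lte(big$p_value, 0.001)
})

test_that("permutation t-test is reproducible under a fixed seed", {
  a <- rnorm(8)
  b <- rnorm(8, 1)
  r1 <- permutation_t_test(a, b, n_perm = 500, seed = 99)
  r2 <- permutation_t_test(a, b, n_perm = 500, seed = 99)
  expect_identical(r1, r2)
})

test_that("BH step-up matches the independent oracle and the printed-threshold arithmetic", {
  expect_equal(bh_fdr(rep(1, 10), q = 0.1)$n_reject, 0)
  expect_equal(bh_fdr(rep(1, 10), q = 0.1)$threshold, 0)

  # m = 36 with a maximal step-up rank of 4 at q = 0.05
  p <- c(0.0005, 0.001, 0.003, 0.0055, rep(0.5, 32))
  out <- bh_fdr(p, q = 0.05)
  expect_equal(out$n_reject, 4)
  expect_equal(out$threshold, 4 * 0.05 / 36)
  expect_equal(round(out$threshold, 4), 0.0056)

  set.seed(11)
  for (i in 1:250) {
    pv <- runif(100)^sample(c(1, 3), 1)    # mix of null-ish and signal-ish
    mine <- bh_fdr(pv, q = 0.2)
    orac <- oracle_bh(pv, 0.2)
    expect_identical(mine$reject, as.logical(orac))
    expect_equal(mine$threshold, attr(orac, "threshold"))
  }
})

test_that("BH rejections are monotone in q", {
  set.seed(12)
  pv <- runif(40)^2
  qs <- c(0.01, 0.05, 0.1, 0.2, 0.4)
  rej <- lapply(qs, function(q) which(bh_fdr(pv, q)$reject))
  for (i in seq_len(length(qs) - 1)) {
    expect_true(all(rej[[i]] %in% rej[[i + 1]]))
  }
  thr <- vapply(qs, function(q) bh_fdr(pv, q)$threshold, numeric(1))
  expect_true(all(diff(thr) >= 0))
})

test_that("group contrast: null tensors stay null, sign convention holds", {
  set.seed(13)
  pairs <- roi_pairs()
  bands <- default_bands()$band
  grid <- expand.grid(pair_i = seq_len(6), band = bands,
                      stringsAsFactors = FALSE)
  make_tensor <- function(ids, shift = 0) {
    purrr::map_dfr(ids, function(id) {
      tibble::tibble(subject_id = id, roi_a = pairs$roi_a[grid$pair_i],
                     roi_b = pairs$roi_b[grid$pair_i],
                     pair = pairs$pair[grid$pair_i], band = grid$band,
                     aec = rnorm(nrow(grid), 0.2 + shift, 0.05))
    })
  }
  conn <- dplyr::bind_rows(make_tensor(sprintf("C%02d", 1:8)),
                           make_tensor(sprintf("P%02d", 1:8)))
  groups <- tibble::tibble(subject_id = unique(conn$subject_id),
                           group = rep(c("control", "patient"), each = 8))
  sm <- group_contrast(conn, groups, n_perm = 499, seed = 14)
  expect_s3_class(sm, "oaec_statmap")
  expect_equal(attr(sm, "m"), 36)
  expect_equal(sum(sm$fdr_reject), 0)

  # identical tensors: every cell ties
  half <- make_tensor(sprintf("S%02d", 1:5))
  conn_same <- dplyr::bind_rows(dplyr::mutate(half, subject_id = paste0("A", subject_id)),
                                dplyr::mutate(half, subject_id = paste0("B", subject_id)))
  g2 <- tibble::tibble(subject_id = unique(conn_same$subject_id),
                       group = rep(c("control", "patient"), each = 5))
  sm2 <- group_contrast(conn_same, g2, n_perm = 199, seed = 15)
  expect_true(all(sm2$t == 0))
  expect_true(all(!sm2$fdr_reject))

  # control > patient in one cell gives positive t there
  connA <- make_tensor(sprintf("C%02d", 1:8), shift = 0)
  connA$aec[connA$pair == "DLPFC_R-sgACC_L" & connA$band == "beta1"] <-
    connA$aec[connA$pair == "DLPFC_R-sgACC_L" & connA$band == "beta1"] + 0.3
  conn3 <- dplyr::bind_rows(connA, make_tensor(sprintf("P%02d", 1:8)))
  sm3 <- group_contrast(conn3, groups, n_perm = 499, seed = 16)
  top <- sm3[which.max(abs(sm3$t)), ]
  expect_equal(top$pair, "DLPFC_R-sgACC_L")
  expect_equal(top$band, "beta1")
  expect_gt(top$t, 0)
  expect_true(top$p_unc_lt_01)
})

test_that("statmap tidiers and writer expose the family metadata", {
  set.seed(17)
  pairs <- roi_pairs()
  conn <- purrr::map_dfr(sprintf("S%02d", 1:10), function(id) {
    tibble::tibble(subject_id = id, roi_a = pairs$roi_a, roi_b = pairs$roi_b,
                   pair = pairs$pair, band = "beta1",
                   aec = rnorm(6, 0.2, 0.05))
  })
  groups <- tibble::tibble(subject_id = sprintf("S%02d", 1:10),
                           group = rep(c("control", "patient"), 5))
  sm <- group_contrast(conn, groups, n_perm = 199, seed = 18)
  td <- generics::tidy(sm)
  expect_named(td, c("pair", "band", "statistic", "p.value", "fdr.reject",
                     "p.unc.lt.01"))
  gl <- generics::glance(sm)
  expect_equal(gl$m, 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_statmap(sm, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".json")))
  js <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(js$m, 6)
})
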