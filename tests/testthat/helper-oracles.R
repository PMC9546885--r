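# Independent reference implementations used as oracles. Each is written as
# a direct transcription of the defining formula, separate from the package's
# code paths.

# envelope correlation computed directly: analytic-signal magnitude per row
# (explicit half-spectrum construction), 1 s trimmed per side, full-record
# Pearson correlation
oracle_envelope_cor <- function(M, fs) {
  env <- t(apply(M, 1, function(x) {
    n <- length(x)
    X <- stats::fft(x)
    mult <- rep(0, n)
    mult[1] <- 1
    if (n %% 2 == 0) {
      mult[n / 2 + 1] <- 1
      mult[2:(n / 2)] <- 2
    } else {
      mult[2:((n + 1) / 2)] <- 2
    }
    Mod(stats::fft(X * mult, inverse = TRUE) / n)
  }))
  keep <- (round(fs) + 1):(ncol(M) - round(fs))
  stats::cor(t(env[, keep, drop = FALSE]))
}

# BH step-up transcribed from the definition: sort, largest k with
# p_(k) <= k q / m, reject everything at or below p_(k)
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * q / m)
  reject <- rep(FALSE, m)
  if (length(ok) > 0) {
    k <- max(ok)
    reject[o[seq_len(k)]] <- TRUE
    attr(reject, "threshold") <- k * q / m
  } else {
    attr(reject, "threshold") <- 0
  }
  reject
}

# Welch t statistic from first principles
oracle_welch_t <- function(a, b) {
  (mean(a) - mean(b)) /
    sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
}

# exact permutation p for small groups: every split enumerated
oracle_exact_perm_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  splits <- utils::combn(length(pooled), na)
  t_obs <- oracle_welch_t(a, b)
  t_all <- apply(splits, 2, function(idx) {
    oracle_welch_t(pooled[idx], pooled[-idx])
  })
  mean(abs(t_all) >= abs(t_obs) - 1e-12)
}

# minimum-norm operator through the SVD closed form of the regularized
# pseudo-inverse: K = V diag(d / (d^2 + lambda2)) t(U) W
oracle_mne_operator <- function(L, noise_var, lambda2) {
  w <- 1 / sqrt(noise_var)
  G <- diag(w) %*% L
  sv <- svd(G)
  sv$v %*% diag(sv$d / (sv$d^2 + lambda2)) %*% t(sv$u) %*% diag(w)
}

# overall F through the explicit hat-matrix projection
oracle_ols_f <- function(y, mm) {
  H <- mm %*% solve(crossprod(mm)) %*% t(mm)
  fit <- H %*% y
  ss_res <- sum((y - fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  df1 <- ncol(mm) - 1
  df2 <- length(y) - ncol(mm)
  (r2 / df1) / ((1 - r2) / df2)
}

# small band-limited test signal
make_band_noise <- function(n, low, high, fs, seed) {
  withr::with_seed(seed, bandpass(rnorm(n), low, high, fs))
}

tiny_cohort_config <- function(seed = 11, n_per_group = 2, duration = 20,
                               fs = 256, n_sensors = 8, ...) {
  simulation_config(n_per_group = n_per_group, fs = fs, duration = duration,
                    n_sensors = n_sensors, seed = seed, ...)
}
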