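test_that("r2_from_pair implements the pair-ratio formula", {
  expect_equal(r2_from_pair(5, 5, n = 3, delta_TE = 1.3), 0)
  expect_equal(r2_from_pair(2, 1, n = 10, delta_TE = 1.3), log(2) / 0.026)
  expect_equal(r2_from_pair(2, 1, n = 10, delta_TE = 1.3), 26.66,
               tolerance = 1e-3)
  expect_error(r2_from_pair(0, 1, 1, 1.3), "positive")
  expect_error(r2_from_pair(1, -1, 1, 1.3), "positive")
})

test_that("noiseless forward-simulation inverts exactly for every pair index", {
  spec <- default_spec
  ts <- tissue_params(1000, 25, 5)
  s <- simulate_se_signal(ts, spec = spec)
  for (n in spec$pair_ns) {
    te <- pair_te(spec, n)
    sm <- s$values[which(abs(s$echo_TEs - te[1]) < 1e-9)]
    sp <- s$values[which(abs(s$echo_TEs - te[2]) < 1e-9)]
    expect_equal(r2_from_pair(sm, sp, n, spec$delta_TE), 25, tolerance = 1e-9)
  }
})

test_that("pair estimator is invariant to scaling and to R2prime", {
  set.seed(21)
  spec <- default_spec
  for (rep in 1:20) {
    r2 <- runif(1, 5, 50)
    n <- sample(spec$pair_ns, 1)
    te <- pair_te(spec, n)
    base <- simulate_se_signal(tissue_params(1000, r2, runif(1, 0, 25)),
                               TEs = te, spec = spec)
    scaled <- runif(1, 0.1, 10) * base$values
    expect_equal(r2_from_pair(scaled[1], scaled[2], n, spec$delta_TE), r2,
                 tolerance = 1e-9)
  }
})

make_stack <- function(tissues, spec, sections = c("rephase", "dephase")) {
  te <- echo_times(spec, sections)
  vals <- t(vapply(tissues, function(ts) {
    simulate_se_signal(ts, TEs = as.numeric(te), spec = spec)$values
  }, numeric(length(te))))
  echo_stack(vals, as.numeric(te), attr(te, "section"))
}

test_that("pair-average map: noiseless consistency, singleton reduction, invalidation", {
  spec <- default_spec
  tissues <- list(tissue_params(1000, 22, 4), tissue_params(800, 28, 9))
  stk <- make_stack(tissues, spec)
  est <- r2_map_pair_average(stk, spec, n_range = 6:11)
  expect_equal(est$R2, c(22, 28), tolerance = 1e-9)
  expect_true(all(est$valid_mask))
  # singleton n-range equals the direct pair formula
  est6 <- r2_map_pair_average(stk, spec, n_range = 6)
  te <- pair_te(spec, 6)
  direct <- r2_from_pair(stk$values[, abs(stk$echo_TEs - te[1]) < 1e-9],
                         stk$values[, abs(stk$echo_TEs - te[2]) < 1e-9],
                         6, spec$delta_TE)
  expect_equal(est6$R2, as.numeric(direct), tolerance = 1e-12)
  # a non-positive magnitude invalidates the voxel, no exception
  bad <- stk
  bad$values[2, 5] <- 0
  estb <- r2_map_pair_average(bad, spec, n_range = 6:11)
  expect_false(estb$valid_mask[2])
  expect_true(is.na(estb$R2[2]))
  expect_true(estb$valid_mask[1])
  expect_error(r2_map_pair_average(stk, spec, n_range = integer(0)), "non-empty")
  expect_error(r2_map_pair_average(stk, spec, n_range = 40), "available")
})

test_that("pair-average map is unbiased within 1% under Rician noise at SNR 50", {
  spec <- default_spec
  ts <- tissue_params(1000, 25, 5)
  s <- simulate_se_signal(ts, spec = spec)
  nvox <- 1e4
  vals <- matrix(rep(s$values, each = nvox), nvox)
  sigma <- 1000 * exp(-25 * 0.040) / 50          # SNR 50 at the echo top
  set.seed(31)
  noisy <- sqrt((vals + rnorm(length(vals), 0, sigma))^2 +
                  matrix(rnorm(length(vals), 0, sigma), nvox)^2)
  stk <- echo_stack(noisy, s$echo_TEs, s$section)
  est <- r2_map_pair_average(stk, spec, n_range = 6:11)
  expect_equal(mean(est$R2[est$valid_mask]), 25, tolerance = 0.01)
})

test_that("exponential and log-linear fits recover noiseless parameters", {
  spec <- default_spec
  ser <- simulate_se_signal(tissue_params(1000, 25, 5), spec = spec)
  ll <- fit_loglinear(ser, spec)
  ex <- fit_exponential(ser, spec)
  expect_equal(ll$M0, 1000, tolerance = 1e-9)
  expect_equal(ll$R2, 25, tolerance = 1e-9)
  expect_equal(ll$R2prime, 5, tolerance = 1e-9)
  expect_equal(ex$R2, 25, tolerance = 1e-6)
  expect_equal(ex$R2prime, 5, tolerance = 1e-6)
  expect_true(ex$converged)
  # flat series: both rates zero
  flat <- simulate_se_signal(tissue_params(700, 0, 0), spec = spec)
  exf <- fit_exponential(flat, spec)
  expect_equal(c(exf$M0, exf$R2, exf$R2prime), c(700, 0, 0), tolerance = 1e-6)
  # echoes on one side of sTE only: collinear design is flagged
  oneside <- simulate_se_signal(tissue_params(1000, 25, 5),
                                TEs = spec$dephase_TEs, spec = spec)
  expect_error(fit_loglinear(oneside, spec), "collinear")
})

test_that("noisy fits agree with the pair-average estimator within simulation error", {
  spec <- default_spec
  ts <- tissue_params(1000, 25, 5)
  clean <- simulate_se_signal(ts, spec = spec)
  set.seed(41)
  nvox <- 300
  d_pair <- d_exp <- numeric(nvox)
  for (i in seq_len(nvox)) {
    noisy <- add_magnitude_noise(clean, sigma = 3, model = "gaussian")
    stk <- echo_stack(matrix(noisy$values, 1), noisy$echo_TEs, noisy$section)
    d_pair[i] <- r2_map_pair_average(stk, spec)$R2
    d_exp[i]  <- fit_exponential(noisy, spec)$R2
  }
  diff <- d_pair - d_exp
  expect_lt(abs(mean(diff)), 3 * sd(diff) / sqrt(nvox) + 0.05)
  # and both are close to truth on average
  expect_equal(mean(d_pair), 25, tolerance = 0.02)
  expect_equal(mean(d_exp), 25, tolerance = 0.02)
})

test_that("pair-estimator bias vanishes as SNR grows (gaussian noise)", {
  spec <- default_spec
  ts <- tissue_params(1000, 25, 5)
  s <- simulate_se_signal(ts, spec = spec)
  bias <- vapply(c(10, 30, 100), function(snr) {
    sigma <- 1000 * exp(-1) / snr
    set.seed(51)
    nvox <- 4000
    vals <- matrix(rep(s$values, each = nvox), nvox)
    noisy <- pmax(vals + rnorm(length(vals), 0, sigma), 1e-6)
    est <- r2_map_pair_average(echo_stack(noisy, s$echo_TEs, s$section), spec)
    mean(est$R2[est$valid_mask]) - 25
  }, numeric(1))
  expect_true(abs(bias[3]) < abs(bias[1]))
  expect_lt(abs(bias[3]), 0.05)
})

test_that("R2* FID fit: exactness, two-point identity, R2prime combination", {
  ts <- tissue_params(1000, 25, 5)
  fid <- simulate_fid_signal(ts, TEs = default_spec$fid_TEs)
  f <- fit_r2star_fid(fid)
  expect_equal(f$R2star, 30, tolerance = 1e-9)
  expect_equal(f$M0, 1000, tolerance = 1e-6)
  expect_true(f$valid)
  # two echoes reduce to the two-point formula
  two <- echo_series(c(800, 600), c(8, 12), c("fid", "fid"))
  f2 <- fit_r2star_fid(two)
  expect_equal(f2$R2star, log(800 / 600) / 0.004, tolerance = 1e-9)
  # R2prime = R2* - R2 recovers the generating value on noiseless data
  se <- simulate_se_signal(ts, spec = default_spec)
  stk <- echo_stack(matrix(se$values, 1), se$echo_TEs, se$section)
  est <- r2_map_pair_average(stk, default_spec)
  comb <- combine_r2prime(est, f$R2star)
  expect_equal(comb$R2prime, 5, tolerance = 1e-9)
  expect_true(comb$valid_mask)
})

test_that("all three R2 estimators agree to 1e-6 on noiseless phantoms", {
  spec <- default_spec
  set.seed(61)
  for (rep in 1:5) {
    ts <- tissue_params(runif(1, 100, 2000), runif(1, 10, 45), runif(1, 0, 20))
    ser <- simulate_se_signal(ts, spec = spec)
    stk <- echo_stack(matrix(ser$values, 1), ser$echo_TEs, ser$section)
    r2s <- c(r2_map_pair_average(stk, spec)$R2,
             fit_exponential(ser, spec)$R2,
             fit_loglinear(ser, spec)$R2)
    expect_equal(max(r2s) - min(r2s), 0, tolerance = 1e-6)
    expect_equal(r2s[1], ts$R2, tolerance = 1e-6)
  }
})
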