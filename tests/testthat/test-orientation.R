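test_that("compute_alpha handles canonical geometries and symmetries", {
  b0 <- c(0, 0, 1)
  expect_equal(compute_alpha(c(0, 0, 1), b0), 0)
  expect_equal(sin4_alpha(compute_alpha(c(0, 0, 1), b0)), 0)
  expect_equal(compute_alpha(c(1, 0, 0), b0), 90)
  expect_equal(sin4_alpha(compute_alpha(c(1, 0, 0), b0)), 1)
  v45 <- c(1, 0, 1) / sqrt(2)
  expect_equal(compute_alpha(v45, b0), 45)
  expect_equal(sin4_alpha(45), 0.25)
  # PEV sign flip and joint rotation invariance
  set.seed(71)
  for (rep in 1:10) {
    p <- unlist(lapply(1, function(i) rnorm(3))); p <- p / sqrt(sum(p^2))
    expect_equal(compute_alpha(p, b0), compute_alpha(-p, b0))
    Q <- random_rotation()
    expect_equal(compute_alpha(as.numeric(Q %*% p), as.numeric(Q %*% b0)),
                 compute_alpha(p, b0), tolerance = 1e-9)
  }
  expect_error(compute_alpha(c(0, 0, 0), b0), "zero-length")
})

test_that("select_voxels applies strict thresholds and matches a brute-force oracle", {
  tab <- table_from_alpha(rep(30, 4), R2 = 25, FA = c(0.5, 0.4, 0.39, 0.8),
                          prob = c(0.5, 0.5, 0.9, 0.25))
  sel <- select_voxels(tab)
  expect_equal(sel$voxel, 1L)            # FA = 0.4 and prob = 0.25 excluded
  # identity when everything passes
  all_in <- table_from_alpha(rep(10, 5), R2 = 22, FA = 0.5, prob = 0.5)
  expect_equal(nrow(select_voxels(all_in)), 5)
  # randomized composition against an independently coded filter
  set.seed(72)
  n <- 2000
  big <- fiber_voxel_table(data.frame(
    voxel = 1:n, R2 = rnorm(n, 25), FA = runif(n), tract_id = 1L,
    tract_prob = runif(n), pev_x = 0, pev_y = 0, pev_z = 1, d = 4))
  expect_equal(nrow(select_voxels(big)),
               sum(big$FA > 0.4 & big$tract_prob > 0.25))
})

test_that("compute_dbar is the voxel-count-weighted tract mean", {
  one <- table_from_alpha(rep(20, 7), R2 = 25, d = 3.3)
  expect_equal(compute_dbar(one), 3.3)
  two <- rbind(as.data.frame(table_from_alpha(rep(10, 100), 25, tract_id = 1, d = 4)),
               as.data.frame(table_from_alpha(rep(80, 300), 25, tract_id = 2, d = 6)))
  two$voxel <- seq_len(nrow(two))
  expect_equal(compute_dbar(fiber_voxel_table(two)), 5.5)
  shuffled <- two[sample(nrow(two)), ]
  expect_equal(compute_dbar(fiber_voxel_table(shuffled)), 5.5)
})

test_that("bin_by_sin4: membership, boundaries and count conservation", {
  # all voxels in one low bin
  low <- table_from_alpha(rep(28, 50), R2 = 25)   # sin^4(28 deg) ~ 0.049
  obs <- bin_by_sin4(low)
  expect_equal(nrow(obs), 1)
  expect_equal(obs$bin_index, 0L)
  expect_equal(obs$n_members, 50)
  expect_equal(obs$R2_se, 0)
  # sin^4 = 1 lands in the closed top bin 9
  top <- table_from_alpha(c(90, 90), R2 = c(20, 30))
  obs9 <- bin_by_sin4(top)
  expect_equal(obs9$bin_index, 9L)
  expect_equal(obs9$R2_mean, 25)
  expect_equal(obs9$R2_se, sd(c(20, 30)) / sqrt(2))
  # uniform sin^4 on [0, 1]: all 10 bins near 10% occupancy
  set.seed(73)
  nn <- 1e5
  alpha <- asin(runif(nn)^0.25) * 180 / pi
  uni <- table_from_alpha(alpha, R2 = 25)
  obs_u <- bin_by_sin4(uni)
  expect_equal(nrow(obs_u), 10)
  expect_true(all(abs(obs_u$n_members - nn / 10) < 0.03 * nn / 10 * 3))
  expect_equal(sum(obs_u$n_members), nn)
  # bin means sit inside their bins
  expect_true(all(obs_u$bin_sin4_mean >= obs_u$bin_index * 0.1 &
                    obs_u$bin_sin4_mean < (obs_u$bin_index + 1) * 0.1 + 1e-12))
})

test_that("fit_orientation_model recovers exact planes and flags bad designs", {
  # exact (noise-free) observations on the model plane
  tracts <- default_tract_set(n_voxels = 300)
  tab <- generate_voxel_table(coeffs = c(22, -6, 3.5, 0), tracts = tracts,
                              sigma = 0, seed = 74)
  sel <- select_voxels(tab)
  dbar <- compute_dbar(sel)
  obs <- bin_by_sin4(sel)
  fit <- suppressWarnings(                 # "essentially perfect fit"
    fit_orientation_model(obs, dbar, terms = c("a1", "a2")))
  expect_equal(c(fit$a0, fit$a1, fit$a2), c(22, -6, 3.5), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(fit$R2_stat, 1, tolerance = 1e-12)
  expect_true(is.na(fit$a3))
  # with a3 = 0 truth the full-model interaction is within 2 SE of zero
  noisy <- generate_voxel_table(coeffs = c(22.08, -6.06, 3.49, 0),
                                sigma = 1.5, seed = 75)
  seln <- select_voxels(noisy)
  full <- fit_orientation_model(bin_by_sin4(seln), compute_dbar(seln))
  expect_lt(abs(full$a3), 2 * full$se[["a3"]])
  # a single tract cannot identify the diameter terms
  single <- bin_by_sin4(select_voxels(
    generate_voxel_table(coeffs = c(22, 0, 3, 0),
                         tracts = default_tract_set(n_voxels = 500)[3],
                         sigma = 0.5, seed = 76)))
  expect_error(fit_orientation_model(single, d_bar = 4, terms = c("a1", "a2")),
               "rank-deficient")
})

test_that("model_comparison: nesting structure and reduced-truth behaviour", {
  tab <- generate_voxel_table(coeffs = c(22.08, -6.06, 3.49, 0), sigma = 1.5,
                              seed = 77,
                              tracts = default_tract_set(n_voxels = 400))
  sel <- select_voxels(tab)
  cmp <- model_comparison(bin_by_sin4(sel), compute_dbar(sel))
  expect_equal(cmp$fit, 1:4)
  # nested R^2 monotonicity: fit1 <= fit3 <= fit4 and fit2 <= fit3 <= fit4
  expect_true(cmp$R2_stat[1] <= cmp$R2_stat[3] + 1e-12)
  expect_true(cmp$R2_stat[2] <= cmp$R2_stat[3] + 1e-12)
  expect_true(cmp$R2_stat[3] <= cmp$R2_stat[4] + 1e-12)
  # orientation-free truth: adding sin^4 changes R^2 only within noise
  no_ori <- generate_voxel_table(coeffs = c(24.08, -7.33, 0, 0), sigma = 1.5,
                                 seed = 78,
                                 tracts = default_tract_set(n_voxels = 400))
  seln <- select_voxels(no_ori)
  cmp2 <- model_comparison(bin_by_sin4(seln), compute_dbar(seln))
  expect_lt(cmp2$R2_stat[3] - cmp2$R2_stat[2], 0.02)
})

test_that("field-scaling ratios are computed and rounded as reported", {
  fs <- orientation_field_scaling(5.34, 2.2, b_high = 7, b_low = 3)
  expect_identical(fs$amplitude_ratio, 2.43)
  expect_identical(fs$field_ratio, 2.33)
})
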