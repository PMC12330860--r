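test_that("effective_diameter implements the area-weighted mean", {
  expect_equal(effective_diameter(diameter_histogram(2.5, 10)), 2.5)
  h <- diameter_histogram(c(1, 2), c(10, 10))
  expect_equal(effective_diameter(h), 1.8)
  # frequency rescaling invariance, diameter scale equivariance, bounds
  set.seed(81)
  for (rep in 1:10) {
    d <- sort(runif(6, 0.3, 5)); f <- runif(6, 0, 100)
    de <- effective_diameter(diameter_histogram(d, f))
    expect_equal(effective_diameter(diameter_histogram(d, 7.3 * f)), de)
    expect_equal(effective_diameter(diameter_histogram(2 * d, f)), 2 * de)
    expect_true(de >= min(d) && de <= max(d))
  }
  expect_error(diameter_histogram(c(1, 2), c(0, 0)), "positive entry")
  expect_error(diameter_histogram(c(-1, 2), c(1, 1)), "positive")
})

test_that("straight-bar mask sections into four near-equal contiguous pieces", {
  mask <- matrix(FALSE, 44, 10)
  mask[3:42, 3:8] <- TRUE                      # 40 x 6 bar along the AP axis
  sec <- section_callosum(mask)
  expect_equal(sort(unique(sec$section[mask])), 1:4)
  counts <- table(sec$section[mask])
  expect_equal(sum(counts), sum(mask))
  expect_true(all(abs(counts - sum(mask) / 4) <= 0.15 * sum(mask) / 4))
  # anterior-to-posterior ordering along the first axis
  mean_ap <- tapply(row(mask)[mask], sec$section[mask], mean)
  expect_true(all(diff(mean_ap) > 0))
  # arc length ~ bar length between the medial tips (pulled slightly
  # inboard of the bar ends by the interior-tip refinement)
  expect_gt(sec$arc_length, 34)
  expect_lt(sec$arc_length, 40)
  # translation invariance (exact): shifting the mask shifts the sections
  big <- matrix(FALSE, 60, 20)
  big[10 + (3:42), 7 + (3:8)] <- TRUE
  sect <- section_callosum(big)
  expect_equal(sect$section[10 + (3:42), 7 + (3:8)], sec$section[3:42, 3:8])
  # mirrored mask gives the mirrored sectioning, up to tie-breaking of
  # boundary voxels (tip selection among equidistant corners is ordered)
  mirrored <- mask[rev(seq_len(nrow(mask))), ]
  secm <- section_callosum(mirrored)
  flipped <- secm$section[rev(seq_len(nrow(mask))), ]
  expect_gt(mean(flipped[mask] == 5L - sec$section[mask]), 0.95)
})

test_that("C-shaped mask sections at 25/50/75% of medial arc (independent oracle)", {
  # C-shape: annulus segment opening to the right
  n <- 41
  mask <- matrix(FALSE, n, n)
  ctr <- (n + 1) / 2
  for (i in 1:n) for (j in 1:n) {
    r <- sqrt((i - ctr)^2 + (j - ctr)^2)
    ang <- atan2(j - ctr, i - ctr)
    if (r >= 12 && r <= 17 && abs(ang) < 2.3) mask[i, j] <- TRUE
  }
  sec <- section_callosum(mask)
  expect_equal(sort(unique(sec$section[mask])), 1:4)
  # oracle: naive Bellman-Ford geodesic distances from both detected tips
  gA <- brute_geodesic(mask, sec$tips[1, ])
  gB <- brute_geodesic(mask, sec$tips[2, ])
  t_oracle <- gA$dist / (gA$dist + gB$dist)
  sec_oracle <- findInterval(t_oracle, c(0.25, 0.5, 0.75)) + 1L
  got <- sec$section[cbind(gA$coords[, 1], gA$coords[, 2])]
  expect_equal(got, sec_oracle)
  # arc length = oracle geodesic distance between the two tips
  iP <- which(gA$coords[, 1] == sec$tips[2, 1] &
                gA$coords[, 2] == sec$tips[2, 2])
  expect_equal(sec$arc_length, gA$dist[iP], tolerance = 1e-9)
})

test_that("degenerate and disconnected masks are rejected", {
  line <- matrix(FALSE, 20, 5)
  line[2:18, 3] <- TRUE
  expect_error(section_callosum(line), "line-like")
  two <- matrix(FALSE, 20, 20)
  two[2:5, 2:5] <- TRUE; two[12:18, 12:18] <- TRUE
  expect_error(section_callosum(two), "connected")
  expect_error(section_callosum(matrix(FALSE, 5, 5)), "empty")
})

test_that("section_stats summarizes sections and associates with d_eff", {
  mask <- matrix(FALSE, 44, 10); mask[3:42, 3:8] <- TRUE
  sec <- section_callosum(mask)
  # construct R2 strictly decreasing in d_eff
  d_eff <- c(0.7, 0.9, 1.3, 1.0)
  r2 <- matrix(NA_real_, 44, 10)
  vals <- c(28, 26, 22, 25)                  # monotone decreasing in d_eff
  for (s in 1:4) r2[sec$section == s] <- vals[s]
  st <- section_stats(r2, sec, d_eff = d_eff)
  expect_equal(st$stats$mean, vals)
  expect_equal(st$association$spearman, -1)
  expect_true(st$association$defined)
  expect_lt(st$association$pearson, -0.9)
  # constant map: association undefined and flagged
  flat <- matrix(24, 44, 10)
  stf <- section_stats(flat, sec, d_eff = d_eff)
  expect_false(stf$association$defined)
  expect_true(is.na(stf$association$spearman))
  # noisy section means converge to the assigned values
  set.seed(82)
  noisy <- r2 + rnorm(length(r2), 0, 1)
  stn <- section_stats(noisy, sec, d_eff = d_eff)
  se <- stn$stats$sd / sqrt(stn$stats$n)
  expect_true(all(abs(stn$stats$mean - vals) < 3.5 * se))
})

test_that("3-D masks collapse over the slice stack and replicate the sectioning", {
  mask2 <- matrix(FALSE, 30, 8); mask2[2:29, 2:7] <- TRUE
  mask3 <- array(FALSE, c(30, 8, 3))
  for (k in 1:3) mask3[, , k] <- mask2
  s2 <- section_callosum(mask2)
  s3 <- section_callosum(mask3)
  for (k in 1:3) expect_equal(s3$section[, , k], s2$section)
})
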