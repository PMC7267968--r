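test_that("run normalization scales every voxel series to mean 100", {
  x <- rbind(rep(500, 8), c(1, 3, 1, 3, 1, 3, 1, 3))
  out <- normalize_run(x)
  expect_equal(out[1, ], rep(100, 8))
  expect_equal(rowMeans(out), c(100, 100), tolerance = 1e-9)
  expect_equal(normalize_run(matrix(c(1, 3), 1))[1, ], c(50, 150))
  expect_error(normalize_run(rbind(c(1, -1))), "positive mean")
})

test_that("polynomial detrending removes quartic drift and leaves orthogonal residuals", {
  tt <- 1:60
  quartic <- rbind(2 + 0.5 * tt - 0.01 * tt^2 + 1e-4 * tt^3 - 5e-7 * tt^4)
  out <- detrend_polynomial(quartic, 4)
  expect_lt(max(abs(out)), 1e-8)

  set.seed(51)
  noise <- matrix(rnorm(3 * 80), 3, 80)
  res <- detrend_polynomial(noise, 4)
  # matches an explicit per-series least-squares fit
  for (v in 1:3) {
    fit <- stats::lm(noise[v, ] ~ stats::poly(1:80, 4))
    expect_gt(cor(res[v, ], stats::residuals(fit)), 0.999999)
  }
  expect_equal(rowMeans(res), rep(0, 3), tolerance = 1e-10)
  # residuals orthogonal to the polynomial basis
  basis <- stats::poly(1:80, 4)
  expect_lt(max(abs(res %*% basis)), 1e-8)
  expect_error(detrend_polynomial(noise[, 1:5, drop = FALSE], 4), "short")
})

test_that("the HRF kernel has the canonical difference-of-gammas shape", {
  k <- hrf_kernel(2)
  expect_equal(k$values[1], 0)
  # dense grid oracle: peak near 5 s (mode of gamma(6,1)), undershoot late
  grid <- seq(0, 32, by = 0.01)
  dense <- stats::dgamma(grid, 6, scale = 1) -
    stats::dgamma(grid, 16, scale = 1) / 6
  expect_lte(abs(k$times[which.max(k$values)] - grid[which.max(dense)]), 2)
  expect_lt(abs(grid[which.max(dense)] - 5), 0.1)
  expect_lt(k$values[k$times == 16], 0)   # undershoot around 15 s
  k1 <- hrf_kernel(1, 24)
  expect_equal(k1$times, 0:24)
  expect_equal(k1$values[6], dense[grid == 5])
})

test_that("Wiener deconvolution inverts the HRF convolution", {
  k <- hrf_kernel(2)
  # zero input -> zero output
  expect_equal(wiener_deconvolve(matrix(0, 2, 50), k), matrix(0, 2, 50))

  # impulse: convolve with kernel, deconvolve, maximum at the impulse
  act <- rep(0, 60); act[20] <- 1
  conv <- stats::filter(c(act, rep(0, 16)), k$values, method = "convolution",
                        sides = 1)
  y <- rbind(as.numeric(conv)[seq_len(60)])
  y[is.na(y)] <- 0
  dec <- wiener_deconvolve(y, k, 0.1)
  expect_equal(which.max(dec[1, ]), 20)

  # deconvolve-then-reconvolve approximates the input at small phi
  set.seed(52)
  smooth_act <- as.numeric(stats::filter(rnorm(80), rep(1 / 3, 3),
                                         sides = 1))
  smooth_act[is.na(smooth_act)] <- 0
  y2 <- as.numeric(stats::filter(c(smooth_act, rep(0, 16)), k$values,
                                 method = "convolution", sides = 1))
  y2[is.na(y2)] <- 0
  y2 <- rbind(y2[seq_len(80)])
  dec2 <- wiener_deconvolve(y2, k, 0.01)
  rec <- as.numeric(stats::filter(c(dec2[1, ], rep(0, 16)), k$values,
                                  method = "convolution", sides = 1))
  rec[is.na(rec)] <- 0
  expect_gt(cor(rec[seq_len(80)], y2[1, ]), 0.95)

  # a range of plausible regularizers gives similar deconvolved series
  for (phi in c(0.05, 0.2, 0.5))
    expect_gt(cor(wiener_deconvolve(y2, k, phi)[1, ], dec2[1, ]), 0.9)

  expect_error(wiener_deconvolve(y2, rep(0, 5)), "zero")
  expect_error(wiener_deconvolve(matrix(0, 1, 5), k), "shorter")
})

test_that("dimension reduction yields z-scored, decorrelated component scores", {
  set.seed(53)
  # rank-2 structure + small noise spread over 30 voxels
  tscore <- cbind(rnorm(100), rnorm(100))
  loads <- matrix(rnorm(2 * 30), 2, 30)
  x <- tscore %*% loads
  red <- reduce_dimensions(x, 2)
  expect_equal(unname(colMeans(red$scores)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(red$scores, 2, sd)), c(1, 1),
               tolerance = 1e-10)
  expect_lt(abs(cor(red$scores[, 1], red$scores[, 2])), 1e-8)
  expect_gt(sum(red$variance_fractions[1:2]), 0.999)
  # sign convention: largest-magnitude loading entry is positive
  for (j in 1:2) {
    v <- red$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_warning(reduce_dimensions(x, 10), "rank")
  expect_error(reduce_dimensions(x[1:3, ], 10), "time points")
})

test_that("outlier truncation clips into the bound", {
  expect_equal(truncate_outliers(6), 5)
  expect_equal(truncate_outliers(-7), -5)
  expect_equal(truncate_outliers(3), 3)
  m <- matrix(c(-10, 0, 10, 4.9), 2)
  expect_equal(truncate_outliers(m), matrix(c(-5, 0, 5, 4.9), 2))
})

test_that("trials with too many outlying time points are dropped", {
  set.seed(54)
  clean <- matrix(rnorm(10 * 4), 10, 4)
  dirty <- clean
  dirty[c(1, 4, 7), 2] <- 8       # three outlying time points
  borderline <- clean
  borderline[c(2, 5), 3] <- -9    # exactly two: kept
  trials <- hsmm_trials(list(clean, dirty, borderline),
                        c("s1", "s1", "s2"))
  kept <- drop_outlier_trials(trials)
  expect_equal(length(kept), 2)
  expect_equal(attr(kept, "kept"), c(1L, 3L))
})

test_that("back-projection recovers state voxel maps", {
  # two hard-assigned states -> segment means
  vox <- matrix(rnorm(8 * 6), 8, 6)
  occ <- cbind(c(rep(1, 5), rep(0, 3)), c(rep(0, 5), rep(1, 3)))
  maps <- backproject_states(list(occ), list(vox))
  expect_equal(maps[1, ], colMeans(vox[1:5, ]))
  expect_equal(maps[2, ], colMeans(vox[6:8, ]))
  # a single state occupying everything -> grand mean
  maps1 <- backproject_states(list(matrix(1, 8, 1)), list(vox))
  expect_equal(maps1[1, ], colMeans(vox))
  expect_error(backproject_states(list(occ), list(vox[1:3, ])), "lengths")
})

test_that("the preprocessing chain composes and preserves time points", {
  set.seed(55)
  runs <- lapply(1:2, function(r) {
    act <- matrix(rnorm(12 * 40), 12, 40)        # 12 voxels x 40 scans
    drift <- outer(rnorm(12), seq(-1, 1, length.out = 40)^2 * 30)
    1000 + drift + 20 * act
  })
  res <- preprocess_runs(runs, n_components = 5)
  expect_equal(nrow(res$scores), 80)
  expect_equal(ncol(res$scores), 5)
  expect_true(all(abs(res$scores) <= 5))
  expect_equal(res$run_rows[, "start"], c(1, 41), ignore_attr = TRUE)
  # deterministic given input
  res2 <- preprocess_runs(runs, n_components = 5)
  expect_identical(res$scores, res2$scores)
})

test_that("trials are cut from score matrices by a validated manifest", {
  scores <- matrix(rnorm(30 * 4), 30, 4)
  manifest <- data.frame(subject = c("a", "b"), trial = 1:2,
                         condition = "all", onset = c(0, 12),
                         length = c(12, 18))
  trials <- build_trials(scores, manifest)
  expect_equal(trial_lengths(trials), c(12, 18))
  expect_equal(trials$values[[2]][1, ], scores[13, ])
  bad <- manifest; bad$length[2] <- 30
  expect_error(build_trials(scores, bad), "out of bounds: 2")
  expect_error(build_trials(scores, manifest[, -4]), "lacks columns")
})
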