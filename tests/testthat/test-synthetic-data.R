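test_that("sampled ground truths respect the stated supports", {
  set.seed(61)
  designs <- replicate(500, sample_ground_truth(6), simplify = FALSE)
  ms <- unlist(lapply(designs, `[[`, "mean_sojourns"))
  sh <- unlist(lapply(designs, `[[`, "shapes"))
  expect_true(all(ms >= 2 & ms <= 8))
  expect_true(all(sh >= 2 & sh <= 5))
  expect_equal(mean(ms), 5, tolerance = 0.1)
  d <- designs[[1]]
  expect_equal(d$scales, d$mean_sojourns / d$shapes)
  expect_equal(dim(d$signatures), c(6, 20))
})

test_that("subject parameters follow the two-level gamma and offset laws", {
  set.seed(62)
  design <- ground_truth_design(3, c(4, 6, 2), c(3, 4, 2),
                                matrix(rnorm(60), 3, 20))
  sp <- replicate(20000, sample_subject_params(design), simplify = FALSE)
  scales <- t(vapply(sp, `[[`, numeric(3), "scales"))
  # E[b_ij] = b_i
  expect_equal(colMeans(scales), design$scales, tolerance = 0.02)
  # relative SD of subject mean sojourns = 1/sqrt(15)
  rel_sd <- apply(scales, 2, sd) / colMeans(scales)
  expect_equal(rel_sd, rep(1 / sqrt(15), 3), tolerance = 0.02)
  # Var(B_kij - B_ki) = 0.25
  offs <- vapply(sp, function(s)
    (s$signatures - design$signatures)[2, 7], numeric(1))
  expect_equal(var(offs), 0.25, tolerance = 0.02)
})

test_that("trial durations are gamma draws with condition-specific means", {
  set.seed(63)
  design <- ground_truth_design(4, c(3, 4, 4, 5), c(3, 3, 3, 3),
                                matrix(rnorm(80), 4, 20),
                                condition_effects = list(
                                  c1 = c(NA, 0.5, NA, NA),
                                  c2 = c(NA, 2.5, NA, NA),
                                  c3 = c(NA, 4.5, NA, NA),
                                  c4 = c(NA, 6.5, NA, NA)))
  sp <- sample_subject_params(design)
  base <- t(replicate(20000, sample_trial_durations(design, sp)))
  expect_equal(colMeans(base), design$shapes * sp$scales, tolerance = 0.05)
  # state 2 mean tracks the condition effect (.5 / 2.5 / 4.5 / 6.5 scaled
  # by this subject's deviation from the population mean)
  subj_factor <- sp$scales[2] / design$scales[2]
  for (cond in paste0("c", 1:4)) {
    d2 <- replicate(20000,
                    sample_trial_durations(design, sp, cond)[2])
    expect_equal(mean(d2),
                 design$condition_effects[[cond]][2] * subj_factor,
                 tolerance = 0.05)
  }
})

test_that("signal composition converts durations to occupancy-weighted signatures", {
  B <- rbind(c(1, 0, 2), c(-1, 3, 0))
  # one state spanning the whole trial
  cs1 <- compose_signal(c(8, 0.2), B)
  expect_equal(nrow(cs1$signal), 4)
  expect_equal(cs1$signal[2, ], B[1, ])
  expect_equal(rowSums(cs1$weights), rep(1, 4))

  # boundary exactly mid-scan: equal blend
  cs2 <- compose_signal(c(3, 5), B)
  expect_equal(cs2$weights[2, ], c(0.5, 0.5))
  expect_equal(cs2$signal[2, ], colMeans(B))
  expect_equal(cs2$weights[1, ], c(1, 0))
  expect_equal(sum(cs2$durations_effective), 8)

  # whole mode rounds boundaries to scan edges: weights are 0/1
  cs3 <- compose_signal(c(2.6, 3.1), B, occupancy_mode = "whole")
  expect_true(all(cs3$weights %in% c(0, 1)))
  expect_equal(rowSums(cs3$weights), rep(1, nrow(cs3$weights)))
  # a state rounded to zero length is skipped
  cs4 <- compose_signal(c(0.3, 6), B, occupancy_mode = "whole")
  expect_equal(cs4$durations_effective[1], 0)
  expect_error(compose_signal(c(0, 0), B), "positive")
})

test_that("correlated noise has the lag structure of a 4-term running sum", {
  set.seed(64)
  n <- sample_noise(2e5, 1, "correlated")
  ac <- stats::acf(n[, 1], lag.max = 5, plot = FALSE)$acf[2:6]
  expect_equal(ac[1:4], c(0.75, 0.5, 0.25, 0), tolerance = 0.02)
  expect_lt(abs(ac[5]), 0.02)
  # heavy tails: exceedance beyond 4 SD far above the normal rate
  z <- n[, 1] / sd(n[, 1])
  expect_gt(mean(abs(z) > 4), 10 * 2 * stats::pnorm(-4))
  # iid kind is standard normal
  m <- sample_noise(5e4, 2, "iid")
  expect_equal(sd(m), 1, tolerance = 0.02)
  expect_lt(abs(stats::acf(m[, 1], lag.max = 1,
                           plot = FALSE)$acf[2]), 0.02)
})

test_that("SNR mixing realizes the requested signal-to-noise ratio", {
  set.seed(65)
  s <- matrix(rnorm(4000), 1000, 4)
  n <- matrix(rnorm(4000), 1000, 4)
  mx <- mix_snr(s, n, 1, zscore = FALSE)
  expect_equal(mx$a, sqrt(var(as.vector(s)) / var(as.vector(n))),
               tolerance = 1e-12)
  expect_equal(mx$a, 1, tolerance = 0.05)
  mx2 <- mix_snr(s, n, 0.1, zscore = FALSE)
  expect_equal(var(as.vector(s)) / var(as.vector(mx2$a * n)), 0.1,
               tolerance = 1e-10)
  # high snr limit: output approaches the z-scored signal
  mx3 <- mix_snr(s, n, 1e8)
  expect_gt(cor(as.vector(mx3$values), as.vector(scale(s))), 0.9999)
  zs <- mix_snr(s, n, 0.5)
  expect_equal(colMeans(zs$values), rep(0, 4), tolerance = 1e-10)
  expect_true(all(abs(zs$values) <= 5))
  expect_error(mix_snr(matrix(1, 10, 2), matrix(rnorm(20), 10, 2), 0.5),
               "zero variance")
})

test_that("experiment generation is reproducible and correctly sized", {
  design <- ground_truth_design(3, c(4, 5, 3), c(3, 3, 4),
                                matrix(rnorm(30), 3, 10),
                                n_subjects = 4, trials_per_subject = 6)
  synth <- generate_experiment(design, seed = 99)
  expect_equal(length(synth$trials), 24)
  expect_equal(length(unique(synth$trials$subject)), 4)
  expect_equal(n_dimensions(synth$trials), 10)
  # occupancy weights sum to 1 and effective durations to the window
  for (k in c(1, 10, 24)) {
    expect_equal(rowSums(synth$truth$weights[[k]]),
                 rep(1, nrow(synth$truth$weights[[k]])))
    expect_equal(sum(synth$truth$durations_effective[[k]]),
                 2 * nrow(synth$trials$values[[k]]))
  }
  # bit-for-bit reproducibility under the same seed
  synth2 <- generate_experiment(design, seed = 99)
  expect_identical(synth$trials$values, synth2$trials$values)
  expect_identical(synth$truth$durations, synth2$truth$durations)
  # mean trial length tracks total design sojourn / 2 s
  lens <- trial_lengths(synth$trials)
  expect_equal(mean(lens), sum(design$mean_sojourns) / 2, tolerance = 0.15)
})

test_that("the true model maps generating parameters into the fitted space", {
  design <- ground_truth_design(2, c(5, 7), c(3, 4),
                                rbind(rnorm(8), rnorm(8)),
                                n_subjects = 3, trials_per_subject = 5)
  synth <- generate_experiment(design, seed = 7)
  tm <- true_model(synth)
  expect_equal(tm$n_states, 2)
  so <- state_sojourns(tm)
  expect_equal(so$shape * so$scale, c(5, 7))
  mu <- state_means(tm)
  # inverse z-scoring returns the generating signatures
  back <- sweep(sweep(mu, 2, synth$truth$scale, `*`), 2,
                synth$truth$center, `+`)
  expect_equal(back, design$signatures, tolerance = 1e-10,
               ignore_attr = TRUE)
})
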