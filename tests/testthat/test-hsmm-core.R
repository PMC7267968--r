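test_that("discretized gamma sojourn pmf matches closed forms and sums to 1", {
  # gamma(4,1): mass below 1 s is 1 - e^-1 (1 + 1 + 1/2 + 1/6)
  s <- gamma_sojourn(4, 1)
  expect_equal(sojourn_pmf(s, 0), 1 - exp(-1) * (1 + 1 + 1 / 2 + 1 / 6),
               tolerance = 1e-12)
  expect_equal(skip_probability(s), sojourn_pmf(s, 0))

  # bin (2m-1, 2m+1): numerical integration oracle
  s2 <- gamma_sojourn(2, 2)
  oracle <- stats::integrate(function(t) stats::dgamma(t, 2, scale = 2),
                             3, 5)$value
  expect_equal(sojourn_pmf(s2, 2), oracle, tolerance = 1e-8)

  # masses over m = 0, 1, 2, ... partition the positive axis
  for (par in list(c(4, 1), c(2, 2), c(0.7, 5), c(15, 1))) {
    s3 <- gamma_sojourn(par[1], par[2])
    expect_equal(sum(sojourn_pmf(s3, 0:500)), 1, tolerance = 1e-12)
  }

  # skip probability limits
  expect_lt(skip_probability(gamma_sojourn(15, 1)), 1e-10)
  expect_gt(skip_probability(gamma_sojourn(0.2, 0.05)), 0.99)

  # general scan length: bounds scale with timepoint_seconds
  expect_equal(sojourn_pmf(s2, 3, timepoint_seconds = 1),
               stats::pgamma(3.5, 2, scale = 2) -
                 stats::pgamma(2.5, 2, scale = 2))
  expect_error(gamma_sojourn(-1, 1), "positive")
  expect_error(gamma_sojourn(2, 0), "positive")
})

test_that("emission log density is the product of unit normals", {
  # zero deviation in D = 20: -10 log(2 pi)
  mu <- rnorm(20)
  expect_equal(emission_logdensity(mu, mu), -10 * log(2 * pi))
  expect_equal(emission_logdensity(0, 1), -0.5 - 0.5 * log(2 * pi))
  set.seed(7)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(emission_logdensity(a, b),
               log(prod(stats::dnorm(b, a, 1))), tolerance = 1e-10)
  expect_error(emission_logdensity(rnorm(3), rnorm(4)), "dimension")
})

test_that("DP likelihood, occupancy and duration posterior match enumeration", {
  set.seed(11)
  for (rep in 1:6) {
    M <- sample(2:7, 1)
    N <- sample(1:3, 1)
    cs <- random_small_case(M, N)
    oracle <- brute_force_hsmm(cs$X, cs$shapes, cs$scales, cs$means)
    expect_equal(trial_loglikelihood(cs$model, cs$trials), oracle$loglik,
                 tolerance = 1e-8)
    occ <- occupancy(cs$model, cs$trials)
    expect_equal(occ, oracle$occupancy, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(rowSums(occ), rep(1, M), tolerance = 1e-9)
    dp <- duration_posterior(cs$model, cs$trials)
    expect_equal(unname(dp), oracle$durations, tolerance = 1e-8)
    expect_equal(rowSums(dp), rep(1, N), tolerance = 1e-9)
    # posterior-mean durations agree with summed occupancies
    expect_equal(as.numeric(dp %*% (0:M)) * 2, colSums(occ) * 2,
                 tolerance = 1e-6 * M)
  }
})

test_that("single-state model reduces to one partition", {
  set.seed(3)
  cs <- random_small_case(5, 1)
  ll <- trial_loglikelihood(cs$model, cs$trials)
  manual <- log(sojourn_pmf(gamma_sojourn(cs$shapes, cs$scales), 5)) +
    sum(vapply(1:5, function(j)
      emission_logdensity(cs$means[1, ], cs$X[j, ]), numeric(1)))
  expect_equal(ll, manual, tolerance = 1e-10)
  expect_true(all(occupancy(cs$model, cs$trials) == 1))
  dp <- duration_posterior(cs$model, cs$trials)
  expect_equal(unname(dp[1, ]), c(rep(0, 5), 1))
})

test_that("expected sojourns convert occupancy to seconds and sum to trial length", {
  occ <- matrix(1, 10, 1)
  expect_equal(expected_sojourns(occ, 2), 20)
  set.seed(5)
  cs <- random_small_case(6, 3)
  occ <- occupancy(cs$model, cs$trials)
  es <- expected_sojourns(occ, 2)
  expect_length(es, 3)
  expect_equal(sum(es), 12, tolerance = 1e-9)
})

test_that("neutral initialization is deterministic and equalizes state means", {
  set.seed(9)
  values <- lapply(c(14, 15, 13, 14), function(m) matrix(rnorm(m * 4), m, 4))
  trials <- hsmm_trials(values, c("a", "a", "b", "b"))
  m1 <- neutral_initialize(6, trials)
  m2 <- neutral_initialize(6, trials)
  expect_identical(m1, m2)
  so <- state_sojourns(m1)
  expect_equal(so$shape, rep(2, 6))
  expect_equal(so$shape * so$scale, rep(mean(c(14, 15, 13, 14)) * 2 / 6, 6))
  expect_true(all(state_means(m1) == 0))
  m3 <- neutral_initialize(1, trials)
  so3 <- state_sojourns(m3)
  expect_equal(so3$shape * so3$scale, mean(c(14, 15, 13, 14)) * 2)
})

test_that("EM recovers a 2-state model at high SNR and never decreases the likelihood", {
  set.seed(21)
  truth <- hsmm_model(2, list(
    list(shape = 3, scale = 1.5, means = c(1.2, -0.8, 0.5, 0, -1)),
    list(shape = 4, scale = 2, means = c(-1, 0.7, -0.3, 1.1, 0.4))))
  trials <- sample_from_hsmm(truth, 1000, subjects = 5)
  fit <- em_fit(trials, n_states = 2)
  expect_true(all(diff(fit$trace) > -1e-6))
  expect_true(fit$converged)
  mu <- state_means(fit$model)
  expect_lt(max(abs(mu - state_means(truth))), 0.05)
  so <- state_sojourns(fit$model)
  expect_equal(so$shape * so$scale, c(3 * 1.5, 4 * 2), tolerance = 0.25)
})

test_that("fitted states appear in temporal order on every trial", {
  set.seed(22)
  truth <- hsmm_model(3, list(
    list(shape = 3, scale = 1.5, means = c(2, 0, -1, 0.5)),
    list(shape = 3, scale = 1.5, means = c(-1, 2, 0.5, -0.5)),
    list(shape = 3, scale = 1.5, means = c(0, -2, 1, 1))))
  trials <- sample_from_hsmm(truth, 150, subjects = 3)
  fit <- em_fit(trials, n_states = 3)
  occ <- occupancy(fit, trials, simplify = FALSE)
  for (o in occ) {
    tm <- seq_len(nrow(o))
    centers <- colSums(o * tm) / pmax(colSums(o), 1e-12)
    visited <- colSums(o) > 0.2   # states effectively present on the trial
    expect_true(!is.unsorted(centers[visited]))
  }
})

test_that("degenerate trials shorter than the state count are handled by skipping", {
  set.seed(23)
  cs <- random_small_case(2, 3)   # M = 2 < N = 3
  ll <- trial_loglikelihood(cs$model, cs$trials)
  expect_true(is.finite(ll))
  occ <- occupancy(cs$model, cs$trials)
  expect_equal(rowSums(occ), rep(1, 2), tolerance = 1e-9)
})

test_that("model serialization round-trips losslessly", {
  set.seed(31)
  tying <- tying_map(3, c("x", "y"), "state1_separate")
  groups <- lapply(1:4, function(g)
    list(shape = runif(1, 0.5, 6), scale = runif(1, 0.5, 4),
         means = rnorm(7)))
  model <- hsmm_model(3, groups, tying)
  path <- tempfile(fileext = ".json")
  write_hsmm_json(model, path)
  back <- read_hsmm_json(path)
  expect_equal(back$n_states, model$n_states)
  expect_identical(unname(back$tying), unname(model$tying))
  for (g in 1:4) {
    expect_equal(back$groups[[g]]$shape, model$groups[[g]]$shape,
                 tolerance = 1e-12)
    expect_equal(back$groups[[g]]$means, model$groups[[g]]$means,
                 tolerance = 1e-12)
  }
  other <- tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), other)
  expect_error(read_hsmm_json(other), "model")
})

test_that("input validation catches malformed models and trials", {
  expect_error(hsmm_trials(list(), character(0)), "length")
  expect_error(hsmm_trials(list(matrix(NA_real_, 2, 2)), "s"), "missing")
  expect_error(hsmm_trials(list(matrix(0, 2, 2), matrix(0, 2, 3)),
                           c("a", "b")), "same number")
  groups <- list(list(shape = 2, scale = 1, means = c(0, 0)))
  model <- hsmm_model(1, groups)
  tr <- hsmm_trials(list(matrix(0, 3, 5)), "s")
  expect_error(trial_loglikelihood(model, tr), "dimensions differ")
  expect_error(em_fit(tr, n_states = 1, tol = -1), "tol")
})
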