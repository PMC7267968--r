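# Brute-force oracles for the explicit-duration DP: enumerate every
# composition m_1 + ... + m_N = M (m_i >= 0) and sum the partition
# probabilities directly.  Only usable for tiny M and N; the DP under test
# never shares code with this path.

compositions <- function(M, N) {
  if (N == 1) return(matrix(M, 1, 1))
  out <- NULL
  for (m1 in 0:M) {
    rest <- compositions(M - m1, N - 1)
    out <- rbind(out, cbind(m1, rest, deparse.level = 0))
  }
  out
}

# full enumeration of likelihood, occupancy and duration posterior
brute_force_hsmm <- function(X, shapes, scales, means, dt = 2) {
  M <- nrow(X)
  N <- length(shapes)
  comps <- compositions(M, N)
  total <- 0
  occ <- matrix(0, M, N)
  eta <- matrix(0, N, M + 1)
  for (r in seq_len(nrow(comps))) {
    m <- comps[r, ]
    p <- 1
    t0 <- 0
    for (i in seq_len(N)) {
      p <- p * sojourn_pmf(gamma_sojourn(shapes[i], scales[i]), m[i], dt)
      if (m[i] > 0)
        for (j in (t0 + 1):(t0 + m[i]))
          p <- p * exp(emission_logdensity(means[i, ], X[j, ]))
      t0 <- t0 + m[i]
    }
    total <- total + p
    t0 <- 0
    for (i in seq_len(N)) {
      if (m[i] > 0)
        occ[(t0 + 1):(t0 + m[i]), i] <- occ[(t0 + 1):(t0 + m[i]), i] + p
      eta[i, m[i] + 1] <- eta[i, m[i] + 1] + p
      t0 <- t0 + m[i]
    }
  }
  list(loglik = log(total), occupancy = occ / total, durations = eta / total)
}

# random small model + single-trial data for oracle comparisons
random_small_case <- function(M, N, D = 3) {
  X <- matrix(stats::rnorm(M * D), M, D)
  shapes <- stats::runif(N, 1, 5)
  scales <- stats::runif(N, 0.5, 3)
  means <- matrix(stats::rnorm(N * D, sd = 0.7), N, D)
  groups <- lapply(seq_len(N), function(i)
    list(shape = shapes[i], scale = scales[i], means = means[i, ]))
  list(model = hsmm_model(N, groups),
       trials = hsmm_trials(list(X), "s1"),
       X = X, shapes = shapes, scales = scales, means = means)
}

# sample trials directly from an HSMM (discretized gamma durations, unit
# normal emissions) -- generation shares no code with the fitting path
sample_from_hsmm <- function(model, n_trials, subjects = 1,
                             max_resample = 50) {
  so <- state_sojourns(model)
  mu <- state_means(model)
  dt <- model$timepoint_seconds
  values <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    for (try in seq_len(max_resample)) {
      durs <- round(stats::rgamma(model$n_states, shape = so$shape,
                                  scale = so$scale) / dt)
      if (sum(durs) >= 1) break
    }
    if (sum(durs) < 1) durs[1] <- 1
    states <- rep(seq_len(model$n_states), durs)
    values[[k]] <- mu[states, , drop = FALSE] +
      matrix(stats::rnorm(length(states) * ncol(mu)), length(states))
  }
  subj <- rep(sprintf("s%02d", seq_len(subjects)), length.out = n_trials)
  hsmm_trials(values, subj, timepoint_seconds = dt)
}
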