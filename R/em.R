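LOG2PI <- log(2 * pi)

# Pre-stack trials by condition so EM touches each matrix once.
# Returns list per condition: X (T x D), lengths, trial indices, r2.
stack_by_condition <- function(trials, conditions) {
  out <- list()
  for (cond in conditions) {
    idx <- which(trials$condition == cond)
    if (length(idx) == 0) next
    X <- do.call(rbind, trials$values[idx])
    out[[cond]] <- list(X = X, r2 = rowSums(X^2),
                        lengths = trial_lengths(trials)[idx], idx = idx)
  }
  leftover <- setdiff(unique(trials$condition), conditions)
  if (length(leftover) > 0 && length(conditions) > 1)
    stop("trials contain conditions not covered by the model: ",
         paste(leftover, collapse = ", "))
  if (length(conditions) == 1 && !all(trials$condition == conditions)) {
    # single-group models apply to any condition labelling
    X <- do.call(rbind, trials$values)
    out <- list()
    out[[conditions]] <- list(X = X, r2 = rowSums(X^2),
                              lengths = trial_lengths(trials),
                              idx = seq_along(trials$values))
  }
  out
}

# Emission log densities for a stacked batch: T x N matrix with
# logB[t, i] = sum_k log N(x_tk | mu_ik, 1).
emission_log_matrix <- function(X, r2, Mu) {
  d <- ncol(X)
  m2 <- rowSums(Mu^2)
  X %*% t(Mu) - 0.5 * outer(r2, m2, `+`) - d / 2 * LOG2PI
}

# One E pass over all trials.  mode "loglik" runs the forward recursion
# only; mode "estep" also returns occupancies and pooled duration counts.
estep_all <- function(model, stacked, mode = c("estep", "loglik")) {
  mode <- match.arg(mode)
  dt <- model$timepoint_seconds
  n <- model$n_states
  res <- list(loglik = NULL, batches = list())
  total_ll <- numeric(0)
  for (cond in names(stacked)) {
    b <- stacked[[cond]]
    Mu <- state_means(model, cond)
    so <- state_sojourns(model, cond)
    dmax <- max(b$lengths)
    logG <- sojourn_log_pmf_matrix(so$shape, so$scale, dmax, dt)
    # prune durations far beyond each state's gamma support; the DP falls
    # back to the full range for any trial this would make infeasible
    dcap <- pmin(as.integer(ceiling(stats::qgamma(1 - 1e-12, so$shape,
                                                  scale = so$scale) / dt)
                            + 1L), dmax)
    logB <- emission_log_matrix(b$X, b$r2, Mu)
    if (mode == "loglik") {
      ll <- .dp_forward_batch(logB, as.integer(b$lengths), logG, dcap)
      res$batches[[cond]] <- list(loglik = ll, idx = b$idx)
    } else {
      e <- .dp_estep_batch(logB, as.integer(b$lengths), logG, dcap)
      e$idx <- b$idx
      res$batches[[cond]] <- e
    }
  }
  n_trials <- sum(vapply(res$batches, function(b) length(b$loglik),
                         numeric(1)))
  ll_all <- numeric(n_trials)
  for (b in res$batches) ll_all[b$idx] <- b$loglik
  res$loglik <- ll_all
  res
}

#' Neutral model initialization
#'
#' Deterministic starting point for EM: every emission mean is 0 (the data
#' are z-scored, so 0 is the uninformative signature) and every sojourn is a
#' shape-2 gamma whose mean is the mean trial duration divided by the number
#' of states, so that all states begin on an equal temporal footing.
#' Symmetry between states is broken by temporal position alone: sequential
#' states come to occupy different windows of the trial as EM proceeds.
#'
#' @param n_states number of states
#' @param trials an [hsmm_trials] object
#' @param tying tying map from [tying_map()]; defaults to a single shared
#'   group per state over the conditions present in `trials`
#' @return an [hsmm_model]
#' @export
neutral_initialize <- function(n_states, trials, tying = NULL) {
  stopifnot(inherits(trials, "hsmm_trials"), n_states >= 1)
  if (length(trials) == 0) stop("cannot initialize from an empty trial set")
  if (is.null(tying))
    tying <- tying_map(n_states, sort(unique(trials$condition)), "all_shared")
  dt <- trials$timepoint_seconds
  mean_seconds <- mean(trial_lengths(trials)) * dt
  shape0 <- 2
  scale0 <- mean_seconds / n_states / shape0
  d <- n_dimensions(trials)
  n_groups <- max(tying)
  groups <- replicate(n_groups,
                      list(shape = shape0, scale = scale0,
                           means = rep(0, d)),
                      simplify = FALSE)
  hsmm_model(n_states, groups, tying, dt)
}

# Maximum-likelihood gamma parameters for pooled expected duration counts
# w[d+1] = expected number of sojourns of d time points (d = 0..dmax).
# Maximizes sum_d w_d * log pmf(d | shape, scale) for the discretized gamma
# by Nelder-Mead on log(shape), log(scale), moment-matched start, with a
# moment-matching fallback.  Shape is kept in [0.1, 50].
fit_discretized_gamma <- function(w, dt, shape0 = NULL, scale0 = NULL) {
  total <- sum(w)
  if (total <= 0) return(NULL)
  # drop bins whose expected counts are negligible: they cannot move the
  # objective but dominate its cost
  keep <- w > total * 1e-12
  dsel <- (seq_along(w) - 1)[keep]
  wsel <- w[keep]
  # representative continuous duration per bin; the 0 bin sits below dt/2
  mid <- pmax(dsel * dt, dt / 4)
  mu <- sum(wsel * mid) / total
  v <- sum(wsel * (mid - mu)^2) / total
  sh_m <- if (v > 1e-12) min(max(mu^2 / v, 0.1), 50) else 50
  sc_m <- mu / sh_m
  hi_edge <- dsel * dt + dt / 2
  lo_edge <- pmax(dsel * dt - dt / 2, 0)   # the d = 0 bin starts at 0
  nll <- function(par) {
    shape <- min(max(exp(par[1]), 0.1), 50)
    scale <- exp(par[2])
    if (!is.finite(scale) || scale <= 0) return(1e12)
    p <- stats::pgamma(hi_edge, shape, scale = scale) -
      stats::pgamma(lo_edge, shape, scale = scale)
    val <- -sum(wsel * log(pmax(p, 1e-300)))
    if (!is.finite(val)) 1e12 else val
  }
  p0 <- if (!is.null(shape0) && is.finite(shape0) && shape0 > 0)
    c(log(shape0), log(scale0)) else c(log(sh_m), log(sc_m))
  fit <- tryCatch(
    stats::optim(p0, nll, method = "Nelder-Mead",
                 control = list(maxit = 150, reltol = 1e-6)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value) ||
      fit$value > nll(c(log(sh_m), log(sc_m))))
    fit <- tryCatch(
      stats::optim(c(log(sh_m), log(sc_m)), nll, method = "Nelder-Mead",
                   control = list(maxit = 150, reltol = 1e-6)),
      error = function(e) NULL)
  if (is.null(fit))
    return(list(shape = sh_m, scale = sc_m))
  list(shape = min(max(exp(fit$par[1]), 0.1), 50),
       scale = exp(fit$par[2]))
}

#' Fit a sequential HSMM by expectation maximization
#'
#' Starting from a neutral (or user-supplied) model, alternates E-steps
#' (forward-backward over all partitionings of each trial) with M-steps
#' (occupancy-weighted emission means; numerical maximum-likelihood gamma
#' sojourn updates over expected duration counts), pooling sufficient
#' statistics within tying groups, until the summed log likelihood improves
#' by less than `tol` or `max_iter` is reached.
#'
#' @param trials an [hsmm_trials] object
#' @param n_states number of states (ignored when `init` is given)
#' @param init optional [hsmm_model] starting point; default
#'   [neutral_initialize()]
#' @param tying tying map (see [tying_map()]); default one shared group per
#'   state
#' @param tol convergence tolerance on the summed log likelihood (default
#'   1e-3)
#' @param max_iter maximum EM iterations (default 200)
#' @param verbose print per-iteration log likelihoods
#' @return An object of class `hsmm_fit`: a list with the fitted `model`,
#'   the per-iteration log-likelihood `trace`, the final `logLik`,
#'   `converged`, `n_iter`, and `degenerate` (indices of parameter groups
#'   that lost all occupancy and kept their previous parameters).
#' @export
em_fit <- function(trials, n_states = NULL, init = NULL, tying = NULL,
                   tol = 1e-3, max_iter = 200, verbose = FALSE) {
  stopifnot(inherits(trials, "hsmm_trials"))
  if (length(trials) == 0) stop("no trials to fit")
  if (tol <= 0) stop("tol must be positive")
  if (is.null(init)) {
    if (is.null(n_states)) stop("give either n_states or init")
    init <- neutral_initialize(n_states, trials, tying)
  }
  model <- init
  if (length(model$groups[[1]]$means) != n_dimensions(trials))
    stop("model and trial dimensions differ")
  conds <- colnames(model$tying)
  stacked <- stack_by_condition(trials, conds)
  dt <- model$timepoint_seconds
  trace <- numeric(0)
  degenerate <- integer(0)
  prev_ll <- -Inf
  converged <- FALSE
  d <- n_dimensions(trials)
  dmax_all <- max(trial_lengths(trials))
  for (iter in seq_len(max_iter)) {
    e <- estep_all(model, stacked, "estep")
    ll <- sum(e$loglik)
    trace <- c(trace, ll)
    if (verbose)
      message(sprintf("iter %d: logLik %.4f", iter, ll))
    # M-step: pool sufficient statistics within tying groups
    n_groups <- length(model$groups)
    num <- matrix(0, n_groups, d)
    den <- numeric(n_groups)
    wdur <- matrix(0, n_groups, dmax_all + 1)
    for (cond in names(e$batches)) {
      b <- e$batches[[cond]]
      st <- stacked[[cond]]
      ids <- model$tying[, cond]
      cg <- crossprod(b$gamma, st$X)          # N x D occupancy-weighted sums
      csum <- colSums(b$gamma)
      for (i in seq_len(model$n_states)) {
        g <- ids[i]
        num[g, ] <- num[g, ] + cg[i, ]
        den[g] <- den[g] + csum[i]
        wdur[g, seq_len(ncol(b$eta))] <- wdur[g, seq_len(ncol(b$eta))] +
          b$eta[i, ]
      }
    }
    new_groups <- model$groups
    degenerate <- integer(0)
    for (g in seq_len(n_groups)) {
      if (den[g] < 1e-8) {           # state never occupied: keep parameters
        degenerate <- c(degenerate, g)
        next
      }
      new_groups[[g]]$means <- num[g, ] / den[g]
      so <- fit_discretized_gamma(wdur[g, ], dt,
                                  model$groups[[g]]$shape,
                                  model$groups[[g]]$scale)
      if (!is.null(so)) {
        new_groups[[g]]$shape <- so$shape
        new_groups[[g]]$scale <- so$scale
      }
    }
    model <- hsmm_model(model$n_states, new_groups, model$tying, dt)
    if (is.finite(prev_ll) && ll - prev_ll < tol) {
      converged <- TRUE
      break
    }
    prev_ll <- ll
  }
  structure(list(model = model, trace = trace, logLik = trace[length(trace)],
                 converged = converged, n_iter = length(trace),
                 degenerate = degenerate),
            class = "hsmm_fit")
}

#' @export
print.hsmm_fit <- function(x, ...) {
  cat(sprintf("<hsmm_fit> logLik %.3f after %d EM iterations (%s)\n",
              x$logLik, x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  print(x$model)
  invisible(x)
}

as_hsmm_model <- function(x) {
  if (inherits(x, "hsmm_fit")) x$model
  else if (inherits(x, "hsmm_model")) x
  else stop("expected an hsmm_model or hsmm_fit")
}

#' Per-trial log likelihood
#'
#' Log of the summed probability over all partitionings of each trial into
#' the model's sequential states, computed by the explicit-duration forward
#' recursion in log space.
#'
#' @param model an [hsmm_model] or [em_fit()] result
#' @param trials an [hsmm_trials] object
#' @return numeric vector, one log likelihood per trial
#' @export
trial_loglikelihood <- function(model, trials) {
  model <- as_hsmm_model(model)
  stopifnot(inherits(trials, "hsmm_trials"))
  if (length(trials) == 0) stop("no trials given")
  if (length(model$groups[[1]]$means) != n_dimensions(trials))
    stop("model and trial dimensions differ")
  stacked <- stack_by_condition(trials, colnames(model$tying))
  estep_all(model, stacked, "loglik")$loglik
}

#' State occupancies
#'
#' Posterior probability that each time point of each trial belongs to each
#' state, summed over all partitionings (forward-backward).  Rows sum to 1.
#'
#' @inheritParams trial_loglikelihood
#' @return list of M x N occupancy matrices, one per trial (a single matrix
#'   if `simplify` and only one trial is given)
#' @param simplify return the bare matrix when a single trial is supplied
#' @export
occupancy <- function(model, trials, simplify = TRUE) {
  model <- as_hsmm_model(model)
  stopifnot(inherits(trials, "hsmm_trials"))
  stacked <- stack_by_condition(trials, colnames(model$tying))
  e <- estep_all(model, stacked, "estep")
  out <- vector("list", length(trials))
  lens <- trial_lengths(trials)
  for (cond in names(e$batches)) {
    b <- e$batches[[cond]]
    row0 <- 0
    for (j in seq_along(b$idx)) {
      k <- b$idx[j]
      out[[k]] <- b$gamma[row0 + seq_len(lens[k]), , drop = FALSE]
      row0 <- row0 + lens[k]
    }
  }
  if (simplify && length(out) == 1) out[[1]] else out
}

#' Expected state sojourns from occupancies
#'
#' Summing occupancies over time points and multiplying by the scan
#' duration gives each state's expected sojourn on the trial, in seconds.
#' The entries always sum to the trial duration.
#'
#' @param occ an M x N occupancy matrix (or list of them)
#' @param timepoint_seconds scan duration in seconds (default 2)
#' @return numeric N-vector of seconds (or a matrix, trials x states, for a
#'   list input)
#' @export
expected_sojourns <- function(occ, timepoint_seconds = 2) {
  if (is.list(occ))
    return(t(vapply(occ, function(o) colSums(o) * timepoint_seconds,
                    numeric(ncol(occ[[1]])))))
  colSums(occ) * timepoint_seconds
}

#' Posterior duration distribution per state
#'
#' For one trial, the posterior probability that each state occupied
#' exactly d time points, d = 0..M.  Rows (states) sum to 1; the posterior
#' mean duration agrees with [expected_sojourns()].
#'
#' @param model an [hsmm_model] or [em_fit()] result
#' @param trial a single-trial [hsmm_trials] object, or a numeric M x D
#'   matrix
#' @param condition condition label when `trial` is a bare matrix
#' @return N x (M + 1) matrix of probabilities, columns named by duration
#' @export
duration_posterior <- function(model, trial, condition = NULL) {
  model <- as_hsmm_model(model)
  if (inherits(trial, "hsmm_trials")) {
    if (length(trial) != 1)
      stop("duration_posterior works on a single trial")
    condition <- trial$condition[1]
    trial <- trial$values[[1]]
  }
  trial <- as.matrix(trial)
  condition <- resolve_condition(model, condition)
  Mu <- state_means(model, condition)
  so <- state_sojourns(model, condition)
  dt <- model$timepoint_seconds
  logB <- emission_log_matrix(trial, rowSums(trial^2), Mu)
  logG <- sojourn_log_pmf_matrix(so$shape, so$scale, nrow(trial), dt)
  eta <- .dp_trial_durations(logB, logG)
  colnames(eta) <- 0:nrow(trial)
  eta
}
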