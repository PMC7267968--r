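#' Gamma sojourn distribution
#'
#' The dwell time of each state is modelled by a continuous gamma
#' distribution, discretized to whole scans: the probability of spending m
#' time points of length `dt` seconds in a state is the gamma mass on the
#' interval (m*dt - dt/2, m*dt + dt/2).  The m = 0 bin (mass below dt/2)
#' is the probability that the state is skipped entirely.
#'
#' @param shape,scale positive gamma shape and scale; the mean sojourn is
#'   `shape * scale` seconds.
#' @return An object of class `gamma_sojourn`.
#' @export
gamma_sojourn <- function(shape, scale) {
  if (!is.numeric(shape) || length(shape) != 1 || !is.finite(shape) ||
      shape <= 0)
    stop("shape must be a positive number")
  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) ||
      scale <= 0)
    stop("scale must be a positive number")
  structure(list(shape = shape, scale = scale), class = "gamma_sojourn")
}

#' @export
print.gamma_sojourn <- function(x, ...) {
  cat(sprintf("<gamma_sojourn> shape %.3f, scale %.3f (mean %.2f s)\n",
              x$shape, x$scale, x$shape * x$scale))
  invisible(x)
}

#' Discretized sojourn probability mass
#'
#' Probability of occupying a state for exactly `m` time points of
#' `timepoint_seconds` each, under the discretized gamma sojourn law.
#'
#' @param sojourn a [gamma_sojourn]
#' @param m vector of non-negative integer time-point counts
#' @param timepoint_seconds scan duration in seconds (default 2)
#' @return numeric vector of probabilities; the masses over m = 0, 1, 2, ...
#'   partition the positive axis and sum to 1.
#' @export
sojourn_pmf <- function(sojourn, m, timepoint_seconds = 2) {
  stopifnot(inherits(sojourn, "gamma_sojourn"))
  if (any(m < 0) || any(m != floor(m))) stop("m must be non-negative integers")
  dt <- timepoint_seconds
  hi <- stats::pgamma(m * dt + dt / 2, shape = sojourn$shape,
                      scale = sojourn$scale)
  lo <- stats::pgamma(pmax(m * dt - dt / 2, 0), shape = sojourn$shape,
                      scale = sojourn$scale)
  out <- hi - lo
  out[m == 0] <- stats::pgamma(dt / 2, shape = sojourn$shape,
                               scale = sojourn$scale)
  out
}

#' Probability that a state is skipped
#'
#' A state is skipped when its continuous sojourn falls below half a scan,
#' i.e. the duration rounds to zero time points.
#'
#' @inheritParams sojourn_pmf
#' @return probability in [0, 1)
#' @export
skip_probability <- function(sojourn, timepoint_seconds = 2) {
  sojourn_pmf(sojourn, 0L, timepoint_seconds)
}

#' Per-time-point emission log density
#'
#' Component scores at one time point are modelled as independent normals
#' with state-specific means and unit standard deviation (the z-scoring of
#' the reduced data fixes the scale).
#'
#' @param means numeric D-vector of state emission means (the brain
#'   signature in component space)
#' @param observation numeric D-vector of observed component scores
#' @return the log density, a scalar
#' @export
emission_logdensity <- function(means, observation) {
  means <- as.numeric(means)
  observation <- as.numeric(observation)
  if (length(means) != length(observation))
    stop("observation dimension does not match emission means")
  if (!all(is.finite(means)) || !all(is.finite(observation)))
    stop("non-finite values in emission density inputs")
  sum(stats::dnorm(observation, mean = means, sd = 1, log = TRUE))
}

#' Condition-tying map
#'
#' Builds the map from (state, condition) to parameter group used to share
#' or separate parameters across experimental conditions.  Three schemes are
#' supported, mirroring common model specifications:
#' `all_shared` fits one parameter set per state regardless of condition;
#' `state1_separate` frees only the first state to differ across
#' conditions; `all_separate` fits every state separately per condition.
#'
#' @param n_states number of sequential states
#' @param conditions character vector of condition labels
#' @param kind one of `"all_shared"`, `"state1_separate"`, `"all_separate"`
#' @return integer matrix `n_states x length(conditions)` of parameter group
#'   ids (1-based, consecutive), with dimnames.
#' @export
tying_map <- function(n_states, conditions,
                      kind = c("all_shared", "state1_separate",
                               "all_separate")) {
  kind <- match.arg(kind)
  conditions <- as.character(conditions)
  nc <- length(conditions)
  stopifnot(n_states >= 1, nc >= 1)
  tie <- switch(kind,
    all_shared = matrix(seq_len(n_states), n_states, nc),
    all_separate = matrix(seq_len(n_states * nc), n_states, nc),
    state1_separate = {
      m <- matrix(0L, n_states, nc)
      m[1, ] <- seq_len(nc)
      if (n_states > 1)
        m[-1, ] <- nc + seq_len(n_states - 1)
      m
    })
  storage.mode(tie) <- "integer"
  dimnames(tie) <- list(state = NULL, condition = conditions)
  tie
}

#' Sequential hidden semi-Markov model
#'
#' An N-state strictly sequential HSMM: state i + 1 always follows state i
#' (states may be skipped but never reordered or branched).  Each parameter
#' group couples a gamma sojourn law with a D-vector of emission means; the
#' tying map assigns a group to every (state, condition) pair.
#'
#' @param n_states number of states N
#' @param groups list of parameter groups, each a list with elements
#'   `shape`, `scale` (gamma sojourn) and `means` (numeric D-vector)
#' @param tying integer matrix `n_states x n_conditions` of group indices,
#'   as produced by [tying_map()]; column names are the condition labels.
#'   Defaults to a single-condition identity map.
#' @param timepoint_seconds scan duration in seconds (default 2)
#' @return An object of class `hsmm_model`.
#' @export
hsmm_model <- function(n_states, groups, tying = NULL,
                       timepoint_seconds = 2) {
  stopifnot(n_states >= 1)
  if (is.null(tying))
    tying <- tying_map(n_states, "all", "all_shared")
  tying <- as.matrix(tying)
  storage.mode(tying) <- "integer"
  if (nrow(tying) != n_states)
    stop("tying map must have one row per state")
  if (is.null(colnames(tying)))
    stop("tying map must carry condition labels as column names")
  ids <- sort(unique(as.integer(tying)))
  if (!identical(ids, seq_along(groups)))
    stop("tying map group ids must index the groups list exactly")
  d <- unique(vapply(groups, function(g) length(g$means), integer(1)))
  if (length(d) != 1)
    stop("all groups must share the same emission dimension")
  for (g in groups) {
    if (!is.finite(g$shape) || g$shape <= 0 ||
        !is.finite(g$scale) || g$scale <= 0)
      stop("group sojourn parameters must be positive")
    if (!all(is.finite(g$means)))
      stop("group emission means must be finite")
  }
  structure(
    list(n_states = as.integer(n_states), groups = groups, tying = tying,
         timepoint_seconds = timepoint_seconds),
    class = "hsmm_model")
}

#' @export
print.hsmm_model <- function(x, ...) {
  cat(sprintf(
    "<hsmm_model> %d sequential states, %d parameter group(s), D = %d, dt = %g s\n",
    x$n_states, length(x$groups), length(x$groups[[1]]$means),
    x$timepoint_seconds))
  for (cond in colnames(x$tying)) {
    mu <- state_means(x, cond)
    so <- state_sojourns(x, cond)
    cat(sprintf("  condition %s: mean sojourns %s s\n", cond,
                paste(sprintf("%.2f", so$shape * so$scale), collapse = ", ")))
  }
  invisible(x)
}

#' Condition labels covered by a model's tying map
#' @param model an [hsmm_model]
#' @return character vector of condition labels
#' @export
model_conditions <- function(model) colnames(model$tying)

resolve_condition <- function(model, condition) {
  conds <- colnames(model$tying)
  if (is.null(condition)) {
    if (length(conds) == 1) return(conds)
    stop("model has several conditions; specify one")
  }
  if (!condition %in% conds) {
    if (length(conds) == 1) return(conds)  # single-group model fits any label
    stop(sprintf("condition '%s' not covered by the tying map", condition))
  }
  condition
}

#' State emission means for one condition
#' @param model an [hsmm_model]
#' @param condition condition label (may be omitted for single-condition
#'   models)
#' @return N x D matrix of emission means (brain signatures)
#' @export
state_means <- function(model, condition = NULL) {
  condition <- resolve_condition(model, condition)
  ids <- model$tying[, condition]
  t(vapply(model$groups[ids], function(g) g$means,
           numeric(length(model$groups[[1]]$means))))
}

#' State sojourn parameters for one condition
#' @inheritParams state_means
#' @return list with numeric vectors `shape` and `scale`, one entry per state
#' @export
state_sojourns <- function(model, condition = NULL) {
  condition <- resolve_condition(model, condition)
  ids <- model$tying[, condition]
  list(shape = vapply(model$groups[ids], `[[`, numeric(1), "shape"),
       scale = vapply(model$groups[ids], `[[`, numeric(1), "scale"))
}

# N x (dmax+1) matrix of log duration masses for durations 0..dmax.
# Masses are floored at 1e-300 so that a single far-out duration cannot
# annihilate a whole trial's likelihood during EM.
sojourn_log_pmf_matrix <- function(shapes, scales, dmax, dt, floor = 1e-300) {
  m <- outer(seq_along(shapes), 0:dmax, function(i, d) {
    hi <- stats::pgamma(d * dt + dt / 2, shape = shapes[i], scale = scales[i])
    lo <- stats::pgamma(pmax(d * dt - dt / 2, 0), shape = shapes[i],
                        scale = scales[i])
    ifelse(d == 0,
           stats::pgamma(dt / 2, shape = shapes[i], scale = scales[i]),
           hi - lo)
  })
  log(pmax(m, floor))
}

#' Serialize a model to JSON
#'
#' Round-trip lossless representation of an [hsmm_model] (numbers written at
#' full precision).
#'
#' @param model an [hsmm_model]
#' @param path file path to write to
#' @return `path`, invisibly
#' @seealso [read_hsmm_json()]
#' @export
write_hsmm_json <- function(model, path) {
  stopifnot(inherits(model, "hsmm_model"))
  obj <- list(
    schema = "hsmmvpa-model-1",
    n_states = model$n_states,
    timepoint_seconds = model$timepoint_seconds,
    conditions = colnames(model$tying),
    tying = unname(apply(model$tying, 2, as.integer, simplify = FALSE)),
    groups = lapply(model$groups, function(g)
      list(shape = g$shape, scale = g$scale, means = as.numeric(g$means))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model from JSON
#' @param path file written by [write_hsmm_json()]
#' @return an [hsmm_model]
#' @export
read_hsmm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || !identical(obj$schema, "hsmmvpa-model-1"))
    stop("not an hsmmvpa model file: ", path)
  tying <- obj$tying
  tying <- if (is.list(tying)) do.call(cbind, lapply(tying, as.integer))
           else if (is.matrix(tying)) t(tying)     # conditions come first
           else matrix(as.integer(tying), nrow = obj$n_states)
  colnames(tying) <- obj$conditions
  groups <- if (is.data.frame(obj$groups)) {
    lapply(seq_len(nrow(obj$groups)), function(i)
      list(shape = obj$groups$shape[i], scale = obj$groups$scale[i],
           means = as.numeric(obj$groups$means[[i]])))
  } else {
    lapply(obj$groups, function(g)
      list(shape = g$shape, scale = g$scale, means = as.numeric(g$means)))
  }
  hsmm_model(obj$n_states, groups, tying, obj$timepoint_seconds)
}
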