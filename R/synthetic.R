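#' Ground-truth design for synthetic experiments
#'
#' Describes the generative process for a synthetic multi-subject
#' experiment: per-state mean sojourns and gamma shapes, population brain
#' signatures, subject-level variation, signal-to-noise ratio, the noise
#' family, and whether states may partially occupy a scan.
#'
#' Subject variation follows a two-level gamma scheme: state i has
#' population mean sojourn `mean_sojourns[i]` seconds with gamma shape
#' `shapes[i]`, hence population scale `b_i = mean_sojourns[i] / shapes[i]`;
#' subject j draws its own scale `b_ij ~ Gamma(shape = 15, scale = b_i/15)`
#' (so subject mean sojourns scatter around the population mean with
#' relative SD 1/sqrt(15) ~ 0.258), and individual trial durations are
#' `t_ij ~ Gamma(shapes[i], b_ij)`.  Subject signatures add 0.5-weighted
#' standard-normal offsets to the population signature.
#'
#' @param n_states number of sequential states
#' @param mean_sojourns numeric vector of population mean sojourns, seconds
#' @param shapes numeric vector of gamma shapes per state
#' @param signatures `n_states x n_dim` matrix of population signatures
#'   (one row per state)
#' @param snr signal-to-noise ratio used when mixing (default 0.1)
#' @param noise_kind `"correlated"` (running sum of four t(3) draws, giving
#'   lag-k autocorrelation (4-k)/4 and heavy tails) or `"iid"` (standard
#'   normal)
#' @param occupancy_mode `"partial"` (state boundaries fall anywhere inside
#'   a scan) or `"whole"` (boundaries first rounded to scan edges)
#' @param n_subjects,trials_per_subject experiment size (defaults 20 x 100)
#' @param subject_scale_shape gamma shape of the subject-scale hyperprior
#'   (default 15)
#' @param subject_signature_sd SD weight of subject signature offsets
#'   (default 0.5)
#' @param condition_effects optional named list: for each condition label, a
#'   numeric vector of per-state mean sojourns (NA entries inherit the
#'   population mean), letting some states vary across conditions
#' @param timepoint_seconds scan duration, seconds (default 2)
#' @return object of class `ground_truth_design`
#' @export
ground_truth_design <- function(n_states, mean_sojourns, shapes, signatures,
                                snr = 0.1,
                                noise_kind = c("correlated", "iid"),
                                occupancy_mode = c("partial", "whole"),
                                n_subjects = 20, trials_per_subject = 100,
                                subject_scale_shape = 15,
                                subject_signature_sd = 0.5,
                                condition_effects = NULL,
                                timepoint_seconds = 2) {
  noise_kind <- match.arg(noise_kind)
  occupancy_mode <- match.arg(occupancy_mode)
  signatures <- as.matrix(signatures)
  stopifnot(n_states >= 1,
            length(mean_sojourns) == n_states,
            length(shapes) == n_states,
            nrow(signatures) == n_states,
            all(mean_sojourns > 0), all(shapes > 0),
            snr > 0, n_subjects >= 1, trials_per_subject >= 1)
  if (!is.null(condition_effects)) {
    stopifnot(is.list(condition_effects), !is.null(names(condition_effects)))
    for (ce in condition_effects)
      stopifnot(length(ce) == n_states, all(is.na(ce) | ce > 0))
  }
  structure(
    list(n_states = as.integer(n_states),
         mean_sojourns = as.numeric(mean_sojourns),
         shapes = as.numeric(shapes),
         scales = as.numeric(mean_sojourns) / as.numeric(shapes),
         signatures = signatures,
         snr = snr, noise_kind = noise_kind,
         occupancy_mode = occupancy_mode,
         n_subjects = as.integer(n_subjects),
         trials_per_subject = as.integer(trials_per_subject),
         subject_scale_shape = subject_scale_shape,
         subject_signature_sd = subject_signature_sd,
         condition_effects = condition_effects,
         timepoint_seconds = timepoint_seconds),
    class = "ground_truth_design")
}

#' @export
print.ground_truth_design <- function(x, ...) {
  cat(sprintf(
    "<ground_truth_design> %d states, %d x %d trials, SNR %g, %s noise, %s occupancy\n",
    x$n_states, x$n_subjects, x$trials_per_subject, x$snr, x$noise_kind,
    x$occupancy_mode))
  cat("  mean sojourns (s):", paste(sprintf("%.2f", x$mean_sojourns),
                                    collapse = ", "), "\n")
  invisible(x)
}

#' Sample a random ground-truth state structure
#'
#' Draws an arbitrary single-condition state structure: mean sojourns
#' uniform on 2-8 s, gamma shapes uniform on 2-5, and standard-normal
#' population signatures, matching the distributions used for general
#' parameter-recovery studies.  With 6 states the mean total sojourn is
#' 30 s.
#'
#' @param n_states number of states (default 6)
#' @param n_dim signature dimension (default 20)
#' @param sojourn_range range of the uniform law for mean sojourns, seconds
#' @param shape_range range of the uniform law for gamma shapes
#' @param ... further arguments passed to [ground_truth_design()]
#' @return a [ground_truth_design()]; draws come from the current RNG
#'   stream, so wrap in `set.seed()` for reproducibility
#' @export
sample_ground_truth <- function(n_states = 6, n_dim = 20,
                                sojourn_range = c(2, 8),
                                shape_range = c(2, 5), ...) {
  stopifnot(n_states >= 1)
  mean_sojourns <- stats::runif(n_states, sojourn_range[1], sojourn_range[2])
  shapes <- stats::runif(n_states, shape_range[1], shape_range[2])
  signatures <- matrix(stats::rnorm(n_states * n_dim), n_states, n_dim)
  ground_truth_design(n_states, mean_sojourns, shapes, signatures, ...)
}

#' Sample subject-level parameters
#'
#' Draws one subject's sojourn scales `b_ij ~ Gamma(shape = s, scale =
#' b_i/s)` (s = `subject_scale_shape`) and signatures `B_ij = B_i +
#' sd * N(0,1)` from a design.
#'
#' @param design a [ground_truth_design()]
#' @return list with `scales` (numeric per state) and `signatures`
#'   (`n_states x n_dim` matrix)
#' @export
sample_subject_params <- function(design) {
  s <- design$subject_scale_shape
  scales <- stats::rgamma(design$n_states, shape = s,
                          scale = design$scales / s)
  signatures <- design$signatures +
    design$subject_signature_sd *
    matrix(stats::rnorm(length(design$signatures)),
           nrow(design$signatures), ncol(design$signatures))
  list(scales = scales, signatures = signatures)
}

#' Sample one trial's continuous state durations
#'
#' Durations are independent gammas `t_ij ~ Gamma(shapes[i], b_ij)`.  When
#' the design carries condition effects, the affected states' subject
#' scales are rescaled by the ratio of the condition mean to the population
#' mean, so condition effects act multiplicatively on the subject's mean
#' sojourn.
#'
#' @param design a [ground_truth_design()]
#' @param subject_params result of [sample_subject_params()]
#' @param condition condition label (only used with condition effects)
#' @return numeric vector of continuous per-state durations, seconds
#' @export
sample_trial_durations <- function(design, subject_params,
                                   condition = NULL) {
  scales <- subject_params$scales
  if (!is.null(design$condition_effects) && !is.null(condition)) {
    eff <- design$condition_effects[[condition]]
    if (is.null(eff))
      stop(sprintf("condition '%s' not in design", condition))
    adj <- which(!is.na(eff))
    scales[adj] <- scales[adj] * eff[adj] / design$mean_sojourns[adj]
  }
  stats::rgamma(design$n_states, shape = design$shapes, scale = scales)
}

#' Compose the noise-free signal for one trial
#'
#' Converts continuous state durations into per-scan occupancy weights and
#' mixes the state signatures accordingly: the signal at scan t is
#' `sum_i w_i(t) B_i`, with `w_i(t)` the fraction of the scan occupied by
#' state i.  In `"whole"` mode state boundaries are first rounded to scan
#' edges so every weight is 0 or 1 (a state rounded to zero length is
#' skipped).  The trial length is `M = round(total / dt)` scans, at least
#' 1; the final boundary is aligned to the trial window.
#'
#' @param durations continuous per-state durations, seconds
#' @param signatures `n_states x D` signature matrix
#' @param timepoint_seconds scan duration (default 2)
#' @param occupancy_mode `"partial"` or `"whole"`
#' @return list with `signal` (M x D), `weights` (M x n_states, rows sum to
#'   1) and `durations_effective` (per-state seconds inside the trial
#'   window, summing to `M * dt`)
#' @export
compose_signal <- function(durations, signatures, timepoint_seconds = 2,
                           occupancy_mode = c("partial", "whole")) {
  occupancy_mode <- match.arg(occupancy_mode)
  dt <- timepoint_seconds
  total <- sum(durations)
  if (total <= 0) stop("total trial duration must be positive")
  n <- length(durations)
  bounds <- cumsum(c(0, durations))
  if (occupancy_mode == "whole") {
    bounds <- round(bounds / dt) * dt
    bounds <- cummax(bounds)
    if (bounds[n + 1] <= 0) bounds[n + 1] <- dt
    m <- as.integer(round(bounds[n + 1] / dt))
  } else {
    m <- max(as.integer(round(total / dt)), 1L)
    bounds <- pmin(bounds, m * dt)
    bounds[n + 1] <- m * dt
  }
  edges <- seq(0, m * dt, by = dt)
  w <- matrix(0, m, n)
  for (i in seq_len(n)) {
    lo <- pmax(edges[-length(edges)], bounds[i])
    hi <- pmin(edges[-1], bounds[i + 1])
    w[, i] <- pmax(hi - lo, 0) / dt
  }
  list(signal = w %*% signatures, weights = w,
       durations_effective = diff(bounds))
}

#' Sample a noise matrix
#'
#' `"correlated"` noise emulates the temporal and tail structure of
#' z-scored fMRI component scores: each column is a running sum of four
#' consecutive draws from a t distribution with 3 degrees of freedom,
#' `N(t) = T3(t) + T3(t+1) + T3(t+2) + T3(t+3)`, giving lag-k
#' autocorrelation (4-k)/4 for k = 0..4 and far heavier tails than a
#' normal.  `"iid"` noise is standard normal.
#'
#' @param m,d matrix dimensions (time points x components)
#' @param kind `"correlated"` or `"iid"`
#' @return m x d numeric matrix
#' @export
sample_noise <- function(m, d, kind = c("correlated", "iid")) {
  kind <- match.arg(kind)
  stopifnot(m >= 1, d >= 1)
  if (kind == "iid")
    return(matrix(stats::rnorm(m * d), m, d))
  raw <- matrix(stats::rt((m + 3) * d, df = 3), m + 3, d)
  out <- raw[1:m, , drop = FALSE]
  for (k in 1:3) out <- out + raw[(1 + k):(m + k), , drop = FALSE]
  out
}

#' Mix signal and noise at a target SNR
#'
#' Scales the noise so that the realized variance ratio var(S)/var(aN)
#' equals `snr`, adds it to the signal, then (optionally) z-scores each
#' component over the whole data set and truncates extreme values to
#' `[-bound, bound]`, matching how real reduced data are prepared.
#'
#' @param signal,noise matrices of identical shape (all trials stacked)
#' @param snr target signal-to-noise ratio (> 0)
#' @param zscore z-score each column after mixing (default TRUE)
#' @param bound truncation bound after z-scoring (default 5)
#' @return list with `values` (mixed matrix), `a` (noise multiplier),
#'   `center`/`scale` (per-column z-scoring parameters, NULL if `zscore`
#'   is FALSE)
#' @export
mix_snr <- function(signal, noise, snr, zscore = TRUE, bound = 5) {
  stopifnot(identical(dim(signal), dim(noise)), snr > 0)
  vs <- stats::var(as.vector(signal))
  vn <- stats::var(as.vector(noise))
  if (vs <= 0) stop("signal has zero variance")
  a <- sqrt(vs / (vn * snr))
  f <- signal + a * noise
  center <- scale <- NULL
  if (zscore) {
    center <- colMeans(f)
    scale <- apply(f, 2, stats::sd)
    scale[scale == 0] <- 1
    f <- sweep(sweep(f, 2, center), 2, scale, `/`)
    f <- pmin(pmax(f, -bound), bound)
  }
  list(values = f, a = a, center = center, scale = scale)
}

#' Generate a full synthetic experiment
#'
#' Draws subject parameters, trial durations, signals and noise from a
#' design, mixes them at the design SNR (variances pooled over the whole
#' data set), z-scores and truncates, and returns the trials together with
#' the complete ground truth needed to score recovery.
#'
#' @param design a [ground_truth_design()]
#' @param seed optional integer seed (applied with [set.seed()])
#' @return object of class `hsmm_synth`: list with `trials` (an
#'   [hsmm_trials]), and `truth` (design, subject signatures/scales,
#'   per-trial continuous and effective durations, occupancy weights, the
#'   noise multiplier `a`, and the z-scoring map)
#' @export
generate_experiment <- function(design, seed = NULL) {
  stopifnot(inherits(design, "ground_truth_design"))
  if (!is.null(seed)) set.seed(seed)
  dt <- design$timepoint_seconds
  conds <- if (is.null(design$condition_effects)) "all"
           else names(design$condition_effects)
  n_trials <- design$n_subjects * design$trials_per_subject
  subj_lab <- character(n_trials)
  cond_lab <- character(n_trials)
  durations <- vector("list", n_trials)
  durations_eff <- vector("list", n_trials)
  weights <- vector("list", n_trials)
  signals <- vector("list", n_trials)
  subjects <- sprintf("s%02d", seq_len(design$n_subjects))
  subj_params <- vector("list", design$n_subjects)
  k <- 0
  for (j in seq_len(design$n_subjects)) {
    sp <- sample_subject_params(design)
    subj_params[[j]] <- sp
    for (r in seq_len(design$trials_per_subject)) {
      k <- k + 1
      cond <- conds[((r - 1) %% length(conds)) + 1]
      dur <- sample_trial_durations(design, sp, if (length(conds) > 1) cond)
      cs <- compose_signal(dur, sp$signatures, dt, design$occupancy_mode)
      subj_lab[k] <- subjects[j]
      cond_lab[k] <- cond
      durations[[k]] <- dur
      durations_eff[[k]] <- cs$durations_effective
      weights[[k]] <- cs$weights
      signals[[k]] <- cs$signal
    }
  }
  lens <- vapply(signals, nrow, integer(1))
  S <- do.call(rbind, signals)
  noise <- sample_noise(nrow(S), ncol(S), design$noise_kind)
  mixed <- mix_snr(S, noise, design$snr)
  split_idx <- rep(seq_len(n_trials), lens)
  values <- lapply(seq_len(n_trials), function(i)
    mixed$values[split_idx == i, , drop = FALSE])
  trials <- hsmm_trials(values, subj_lab, cond_lab, dt)
  structure(
    list(trials = trials,
         truth = list(design = design,
                      subject_params = subj_params,
                      durations = durations,
                      durations_effective = durations_eff,
                      weights = weights,
                      a = mixed$a,
                      center = mixed$center, scale = mixed$scale,
                      seed = seed)),
    class = "hsmm_synth")
}

#' @export
print.hsmm_synth <- function(x, ...) {
  cat("<hsmm_synth> synthetic experiment\n")
  print(x$truth$design)
  print(x$trials)
  invisible(x)
}

#' Ground-truth model in the fitted (z-scored) data space
#'
#' Builds the generating model as an [hsmm_model] whose emission means are
#' the population signatures mapped through the data set's z-scoring
#' (`(B - center)/scale` per component) and whose sojourns are the
#' population gamma laws.  Useful as an oracle initialization or for
#' likelihood comparisons against fitted models.
#'
#' @param synth an [generate_experiment()] result
#' @return an [hsmm_model]
#' @export
true_model <- function(synth) {
  stopifnot(inherits(synth, "hsmm_synth"))
  design <- synth$truth$design
  B <- design$signatures
  if (!is.null(synth$truth$center))
    B <- sweep(sweep(B, 2, synth$truth$center), 2, synth$truth$scale, `/`)
  groups <- lapply(seq_len(design$n_states), function(i)
    list(shape = design$shapes[i], scale = design$scales[i],
         means = B[i, ]))
  conds <- unique(synth$trials$condition)
  hsmm_model(design$n_states, groups,
             tying_map(design$n_states, sort(conds), "all_shared"),
             design$timepoint_seconds)
}
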