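#' Leave-one-subject-out cross-validation
#'
#' For each subject, fits the model (from neutral initialization) to all
#' other subjects' trials and evaluates the summed trial log likelihood on
#' the held-out subject.  The held-out likelihoods measure how well a
#' specification generalizes across subjects and are the basis for
#' choosing the number of states.
#'
#' @param trials an [hsmm_trials] with at least 2 subjects
#' @param n_states number of states of the candidate specification
#' @param tying_kind `"all_shared"`, `"state1_separate"` or
#'   `"all_separate"` (see [tying_map()])
#' @param tol,max_iter EM settings passed to [em_fit()]
#' @return object of class `loocv_result`: list with `heldout` (named
#'   per-subject held-out log likelihoods), `fits` (per-fold [em_fit()]
#'   results), `n_states`, `tying_kind`
#' @export
loocv <- function(trials, n_states, tying_kind = "all_shared",
                  tol = 1e-3, max_iter = 200) {
  stopifnot(inherits(trials, "hsmm_trials"))
  subjects <- trial_subjects(trials)
  if (length(subjects) < 2) stop("LOOCV needs at least 2 subjects")
  counts <- table(trials$subject)
  if (any(counts == 0)) stop("every subject needs at least one trial")
  tying <- tying_map(n_states, sort(unique(trials$condition)), tying_kind)
  heldout <- numeric(length(subjects))
  names(heldout) <- subjects
  fits <- vector("list", length(subjects))
  names(fits) <- subjects
  for (s in subjects) {
    train <- trials[trials$subject != s]
    test <- trials[trials$subject == s]
    fit <- em_fit(train, n_states = n_states, tying = tying,
                  tol = tol, max_iter = max_iter)
    heldout[s] <- sum(trial_loglikelihood(fit, test))
    fits[[s]] <- fit
  }
  structure(list(heldout = heldout, fits = fits, n_states = n_states,
                 tying_kind = tying_kind),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf(
    "<loocv_result> %d states (%s), %d folds, mean held-out logLik %.3f\n",
    x$n_states, x$tying_kind, length(x$heldout), mean(x$heldout)))
  invisible(x)
}

#' Sign test between two models' held-out likelihoods
#'
#' Counts the subjects predicted better by model B than by model A and
#' returns the one-sided binomial tail probability at chance 1/2.  Exact
#' ties are excluded from the count.
#'
#' @param ll_a,ll_b per-subject held-out log likelihoods (equal subject
#'   sets; named vectors are aligned by name)
#' @return list with `n_better` (subjects where B beats A), `n` (subjects
#'   counted, ties excluded) and `p` (one-sided binomial tail probability)
#' @export
sign_test_compare <- function(ll_a, ll_b) {
  if (!is.null(names(ll_a)) && !is.null(names(ll_b))) {
    if (!setequal(names(ll_a), names(ll_b)))
      stop("subject sets differ")
    ll_b <- ll_b[names(ll_a)]
  } else if (length(ll_a) != length(ll_b)) {
    stop("subject sets differ")
  }
  diff <- ll_b - ll_a
  n <- sum(diff != 0)
  n_better <- sum(diff > 0)
  p <- if (n == 0) 1 else
    stats::pbinom(n_better - 1, n, 0.5, lower.tail = FALSE)
  list(n_better = n_better, n = n, p = p)
}

#' Choose the number of states by LOOCV and sign tests
#'
#' Runs [loocv()] over a contiguous range of state counts and selects the
#' largest N whose held-out likelihoods beat those of every smaller N at
#' the sign-test threshold `alpha`: more states are only justified when
#' they predict significantly more subjects better.
#'
#' @param trials an [hsmm_trials]
#' @param n_range contiguous integer range of candidate state counts,
#'   starting at 1
#' @param tying_kind tying scheme for every candidate (see [tying_map()])
#' @param alpha sign-test significance threshold (default .01)
#' @param tol,max_iter EM settings
#' @return list of class `state_selection`: `selected` (chosen N),
#'   `heldout` (subjects x candidates matrix), `comparisons` (data frame of
#'   all pairwise sign tests: n_states_a, n_states_b, n_better, n, p),
#'   `loocv` (list of [loocv()] results)
#' @export
select_n_states <- function(trials, n_range, tying_kind = "all_shared",
                            alpha = 0.01, tol = 1e-3, max_iter = 200) {
  n_range <- sort(unique(as.integer(n_range)))
  if (n_range[1] != 1 || !all(diff(n_range) == 1))
    stop("n_range must be a contiguous range starting at 1")
  cvs <- lapply(n_range, function(n)
    loocv(trials, n, tying_kind, tol = tol, max_iter = max_iter))
  names(cvs) <- as.character(n_range)
  heldout <- vapply(cvs, `[[`, cvs[[1]]$heldout, "heldout")
  comparisons <- NULL
  if (length(n_range) > 1) {
    pairs <- utils::combn(seq_along(n_range), 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      st <- sign_test_compare(heldout[, i], heldout[, j])
      data.frame(n_states_a = n_range[i], n_states_b = n_range[j],
                 n_better = st$n_better, n = st$n, p = st$p)
    }))
  }
  selected <- n_range[1]
  for (n in n_range[-1]) {
    beats_all <- all(vapply(n_range[n_range < n], function(m) {
      row <- comparisons[comparisons$n_states_a == m &
                           comparisons$n_states_b == n, ]
      row$p < alpha
    }, logical(1)))
    if (beats_all) selected <- n
  }
  structure(list(selected = selected, heldout = heldout,
                 comparisons = comparisons, loocv = cvs, alpha = alpha),
            class = "state_selection")
}

#' @export
print.state_selection <- function(x, ...) {
  cat(sprintf("<state_selection> selected %d states (alpha %g) from %s\n",
              x$selected, x$alpha,
              paste(range(as.integer(colnames(x$heldout))), collapse = "-")))
  invisible(x)
}

#' Correlation between adjacent state signatures
#'
#' Pearson correlation between the emission means of consecutive states.
#' Elevated adjacent correlations are the characteristic symptom of
#' excess-state solutions (splits and bridges), and a reason for caution
#' when cross-validation prefers a high state count.
#'
#' @param model an [hsmm_model] or [em_fit()] result
#' @param condition condition label (optional for single-condition models)
#' @return numeric vector of length N - 1; `NA` where a signature has zero
#'   variance (flagged with a warning)
#' @export
adjacent_state_correlation <- function(model, condition = NULL) {
  model <- as_hsmm_model(model)
  if (model$n_states < 2) stop("need at least 2 states")
  mu <- state_means(model, condition)
  out <- vapply(seq_len(nrow(mu) - 1), function(i) {
    if (stats::sd(mu[i, ]) == 0 || stats::sd(mu[i + 1, ]) == 0) NA_real_
    else stats::cor(mu[i, ], mu[i + 1, ])
  }, numeric(1))
  if (anyNA(out)) warning("constant signature: undefined correlation")
  out
}

#' Classify extra states in an over-sized fit
#'
#' When a fitted model has more states than the generating model, each
#' unmatched fitted state is labelled by its relation to its fitted
#' neighbours: a `"bridge"` is a short state (mean sojourn at most
#' `bridge_max_timepoints` scans) whose signature correlates above
#' `cor_threshold` with both neighbours (it absorbs scans straddling a
#' true state boundary); a `"split"` correlates above threshold with the
#' true state matched to one of its neighbours (two fitted states covering
#' one true state); anything else is `"other"`.
#'
#' @param true_model,fitted_model [hsmm_model]s (or [em_fit()] results);
#'   fitted must have at least as many states as true
#' @param mapping optional matching from [match_states()]; computed if
#'   omitted
#' @param condition condition label for multi-condition models
#' @param cor_threshold signature correlation threshold (default 0.5)
#' @param bridge_max_timepoints maximum mean sojourn, in scans, for a
#'   bridge (default 1.5)
#' @return data frame with one row per extra fitted state: `fitted_state`,
#'   `label`, `cor_prev`, `cor_next`, `mean_timepoints`
#' @export
classify_excess_states <- function(true_model, fitted_model, mapping = NULL,
                                   condition = NULL, cor_threshold = 0.5,
                                   bridge_max_timepoints = 1.5) {
  true_model <- as_hsmm_model(true_model)
  fitted_model <- as_hsmm_model(fitted_model)
  if (fitted_model$n_states < true_model$n_states)
    stop("fitted model has fewer states than the generating model")
  mu_t <- state_means(true_model, condition)
  mu_f <- state_means(fitted_model, condition)
  if (is.null(mapping)) mapping <- match_states(mu_t, mu_f)
  so <- state_sojourns(fitted_model, condition)
  mean_tp <- so$shape * so$scale / fitted_model$timepoint_seconds
  extra <- mapping$extra_fitted
  if (length(extra) == 0)
    return(data.frame(fitted_state = integer(0), label = character(0),
                      cor_prev = numeric(0), cor_next = numeric(0),
                      mean_timepoints = numeric(0)))
  safe_cor <- function(a, b) {
    if (is.null(a) || is.null(b) || stats::sd(a) == 0 || stats::sd(b) == 0)
      return(NA_real_)
    stats::cor(a, b)
  }
  fitted_to_true <- rep(NA_integer_, fitted_model$n_states)
  fitted_to_true[mapping$pairs$fitted] <- mapping$pairs$true
  rows <- lapply(extra, function(i) {
    cp <- if (i > 1) safe_cor(mu_f[i - 1, ], mu_f[i, ]) else NA_real_
    cn <- if (i < nrow(mu_f)) safe_cor(mu_f[i, ], mu_f[i + 1, ]) else NA_real_
    # correlation with the true states matched to the neighbours
    neigh_true <- stats::na.omit(c(
      if (i > 1) fitted_to_true[i - 1],
      if (i < nrow(mu_f)) fitted_to_true[i + 1]))
    cor_true <- if (length(neigh_true) > 0)
      max(vapply(neigh_true, function(tt) safe_cor(mu_t[tt, ], mu_f[i, ]),
                 numeric(1)), na.rm = TRUE) else NA_real_
    label <- if (!is.na(cp) && !is.na(cn) && cp > cor_threshold &&
                 cn > cor_threshold && mean_tp[i] <= bridge_max_timepoints)
      "bridge"
    else if (!is.na(cor_true) && cor_true > cor_threshold)
      "split"
    else "other"
    data.frame(fitted_state = i, label = label, cor_prev = cp,
               cor_next = cn, mean_timepoints = mean_tp[i])
  })
  do.call(rbind, rows)
}
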