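#' Trial observation container
#'
#' Bundles the reduced (component-space) activity matrices for a set of
#' trials together with their subject and condition labels.  Each trial is an
#' M x D numeric matrix of z-scored component scores, one row per scan
#' (time point) and one column per spatial component.
#'
#' @param values list of numeric matrices, one per trial (rows = time
#'   points, columns = components); all trials must share the same number of
#'   columns.
#' @param subject character or factor vector of subject labels, one per
#'   trial.
#' @param condition character or factor vector of condition labels, one per
#'   trial.  Defaults to a single condition `"all"`.
#' @param timepoint_seconds duration of one scan in seconds (the repetition
#'   time), default 2.
#'
#' @return An object of class `hsmm_trials`.
#' @export
hsmm_trials <- function(values, subject, condition = NULL,
                        timepoint_seconds = 2) {
  stopifnot(is.list(values), length(values) >= 1)
  n <- length(values)
  values <- lapply(values, function(v) {
    v <- as.matrix(v)
    storage.mode(v) <- "double"
    if (nrow(v) < 1) stop("every trial must have at least one time point")
    if (anyNA(v)) stop("trial matrices must not contain missing values")
    v
  })
  d <- unique(vapply(values, ncol, integer(1)))
  if (length(d) != 1)
    stop("all trials must have the same number of components")
  if (is.null(condition)) condition <- rep("all", n)
  subject <- as.character(subject)
  condition <- as.character(condition)
  if (length(subject) != n || length(condition) != n)
    stop("subject and condition must have one entry per trial")
  structure(
    list(values = values, subject = subject, condition = condition,
         timepoint_seconds = timepoint_seconds),
    class = "hsmm_trials")
}

#' @export
length.hsmm_trials <- function(x) length(x$values)

#' @export
print.hsmm_trials <- function(x, ...) {
  lens <- trial_lengths(x)
  cat(sprintf(
    "<hsmm_trials> %d trials, %d subjects, %d condition(s), D = %d\n",
    length(x), length(unique(x$subject)), length(unique(x$condition)),
    n_dimensions(x)))
  cat(sprintf("  lengths %d-%d time points (%.1f s each), mean %.2f\n",
              min(lens), max(lens), x$timepoint_seconds, mean(lens)))
  invisible(x)
}

#' @export
`[.hsmm_trials` <- function(x, i) {
  hsmm_trials(x$values[i], x$subject[i], x$condition[i],
              x$timepoint_seconds)
}

#' Number of time points per trial
#' @param trials an [hsmm_trials] object
#' @return integer vector of trial lengths (in time points)
#' @export
trial_lengths <- function(trials) {
  vapply(trials$values, nrow, integer(1))
}

#' Number of components (data dimensions)
#' @param trials an [hsmm_trials] object
#' @return integer, the common column count D
#' @export
n_dimensions <- function(trials) {
  ncol(trials$values[[1]])
}

#' Subjects present in a trial set
#' @param trials an [hsmm_trials] object
#' @return character vector of unique subject labels, in order of appearance
#' @export
trial_subjects <- function(trials) unique(trials$subject)
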