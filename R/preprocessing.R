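#' Normalize a run to mean 100
#'
#' Scales each voxel time series (row) so its mean is 100, the conventional
#' BOLD percent-signal scaling.
#'
#' @param x voxels x time numeric matrix of raw signal values (positive)
#' @return matrix of the same shape with per-row mean 100
#' @export
normalize_run <- function(x) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("every voxel series must have a positive mean")
  x * (100 / mu)
}

#' Remove polynomial signal drift
#'
#' Fits and subtracts a least-squares polynomial of the given degree from
#' each voxel time series.  An orthogonal polynomial basis is used
#' internally, so the fit is well conditioned at any reasonable degree; the
#' constant term is removed with the drift, leaving zero-mean residuals.
#'
#' @param x voxels x time numeric matrix
#' @param degree polynomial degree (default 4, quartic detrending)
#' @return detrended matrix of the same shape
#' @export
detrend_polynomial <- function(x, degree = 4) {
  x <- as.matrix(x)
  m <- ncol(x)
  if (m < degree + 2) stop("time series too short for the requested degree")
  basis <- cbind(1 / sqrt(m), stats::poly(seq_len(m), degree))
  # columns of `basis` are orthonormal: projection is x %*% B %*% t(B)
  x - (x %*% basis) %*% t(basis)
}

#' Hemodynamic response kernel
#'
#' The canonical difference-of-gammas HRF, `h(t) = dgamma(t, 6, 1) -
#' dgamma(t, 16, 1)/6`, sampled at multiples of the repetition time.  The
#' kernel is 0 at t = 0, peaks near 5 s and shows a shallow undershoot
#' around 15 s.
#'
#' @param repetition_time scan interval in seconds (default 2)
#' @param length_seconds kernel support in seconds (default 32; tail mass
#'   beyond this is negligible)
#' @return object of class `hrf_kernel`: list with `values`, `times` and
#'   `repetition_time`
#' @export
hrf_kernel <- function(repetition_time = 2, length_seconds = 32) {
  stopifnot(repetition_time > 0, length_seconds > 0)
  times <- seq(0, length_seconds, by = repetition_time)
  values <- stats::dgamma(times, shape = 6, scale = 1) -
    stats::dgamma(times, shape = 16, scale = 1) / 6
  structure(list(values = values, times = times,
                 repetition_time = repetition_time),
            class = "hrf_kernel")
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat(sprintf("<hrf_kernel> %d taps at %g s (peak %.3f at %g s)\n",
              length(x$values), x$repetition_time, max(x$values),
              x$times[which.max(x$values)]))
  invisible(x)
}

#' Wiener deconvolution of the hemodynamic response
#'
#' Inverts the HRF convolution in the frequency domain,
#' `X(f) = Y(f) conj(H(f)) / (|H(f)|^2 + phi)`, where `phi` is the
#' noise-to-signal regularizer.  Series are zero-padded to the next power
#' of two at least `length + kernel length` to avoid circular wrap-around.
#'
#' @param x voxels x time numeric matrix (typically normalized and
#'   detrended)
#' @param kernel an [hrf_kernel()] (or numeric vector of kernel taps)
#' @param noise_to_signal Wiener regularizer phi >= 0 (default 0.1; a wide
#'   range of plausible values yields similar deconvolved series)
#' @return deconvolved matrix, same shape as `x`
#' @export
wiener_deconvolve <- function(x, kernel, noise_to_signal = 0.1) {
  x <- as.matrix(x)
  h <- if (inherits(kernel, "hrf_kernel")) kernel$values else as.numeric(kernel)
  if (all(h == 0)) stop("kernel must not be all zero")
  if (noise_to_signal < 0) stop("noise_to_signal must be >= 0")
  m <- ncol(x)
  if (length(h) >= m) stop("kernel must be shorter than the series")
  nfft <- stats::nextn(m + length(h), 2)
  hp <- c(h, rep(0, nfft - length(h)))
  H <- stats::fft(hp)
  wfilt <- Conj(H) / (Mod(H)^2 + noise_to_signal)
  xp <- cbind(x, matrix(0, nrow(x), nfft - m))
  Y <- stats::mvfft(t(xp))
  out <- Re(stats::mvfft(Y * wfilt, inverse = TRUE)) / nfft
  t(out)[, seq_len(m), drop = FALSE]
}

#' Reduce voxel data to principal component scores
#'
#' l2-normalizes each time point (row) of the concatenated deconvolved
#' data, performs a spatial PCA, retains the leading components, and
#' z-scores the component scores so all components share the same scale
#' (after which the data behave approximately as multivariate standard
#' normal for likelihood computations).  Loading signs are fixed by making
#' each loading vector's largest-magnitude element positive.
#'
#' @param x time x voxels numeric matrix (runs concatenated along time)
#' @param n_components number of components to keep (default 20)
#' @return list with `scores` (time x k, z-scored), `loadings`
#'   (voxels x k), `variance_fractions` (length k), and `sds` (component
#'   score SDs before z-scoring)
#' @export
reduce_dimensions <- function(x, n_components = 20) {
  x <- as.matrix(x)
  if (nrow(x) < n_components)
    stop("need at least as many time points as components")
  norms <- sqrt(rowSums(x^2))
  norms[norms == 0] <- 1
  x <- x / norms
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, sum(p$sdev > 1e-12))
  if (k < n_components)
    warning(sprintf("input rank supports only %d components", k))
  load <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, `*`)
  scores <- sweep(scores, 2, flip, `*`)
  sds <- apply(scores, 2, stats::sd)
  z <- sweep(sweep(scores, 2, colMeans(scores)), 2, sds, `/`)
  list(scores = z, loadings = load,
       variance_fractions = (p$sdev^2 / sum(p$sdev^2))[seq_len(k)],
       sds = sds)
}

#' Truncate extreme values
#'
#' Clips a matrix (or vector) into `[-bound, bound]`; applied to z-scored
#' component scores to tame heavy tails before model fitting.
#'
#' @param x numeric matrix or vector
#' @param bound positive truncation bound (default 5)
#' @return clipped object of the same shape
#' @export
truncate_outliers <- function(x, bound = 5) {
  stopifnot(bound > 0)
  pmin(pmax(x, -bound), bound)
}

#' Drop trials with too many outlying time points
#'
#' Removes trials in which more than `max_bad` time points contain an
#' extreme value (absolute z score above `bound` in at least one
#' component).  Apply to z-scored scores before truncation.
#'
#' @param trials an [hsmm_trials] object
#' @param bound outlier bound on |z| (default 5)
#' @param max_bad maximum tolerated outlying time points per trial
#'   (default 2)
#' @return filtered [hsmm_trials]; the indices kept are stored in attribute
#'   `"kept"`
#' @export
drop_outlier_trials <- function(trials, bound = 5, max_bad = 2) {
  stopifnot(inherits(trials, "hsmm_trials"))
  bad <- vapply(trials$values, function(v)
    sum(apply(abs(v) > bound, 1, any)), numeric(1))
  keep <- which(bad <= max_bad)
  if (length(keep) == 0) stop("all trials were dropped as outliers")
  out <- trials[keep]
  attr(out, "kept") <- keep
  out
}

#' Build trials from a reduced score matrix and a manifest
#'
#' Cuts a concatenated time x components score matrix into trials using a
#' manifest with columns `subject`, `trial`, `condition`, `onset` (0-based
#' row index into the score matrix) and `length` (time points).
#'
#' @param scores time x components numeric matrix
#' @param manifest data frame with the columns above
#' @param timepoint_seconds scan duration (default 2)
#' @return an [hsmm_trials]
#' @export
build_trials <- function(scores, manifest, timepoint_seconds = 2) {
  req <- c("subject", "trial", "condition", "onset", "length")
  missing_cols <- setdiff(req, names(manifest))
  if (length(missing_cols) > 0)
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "))
  bad <- which(manifest$onset < 0 | manifest$length < 1 |
                 manifest$onset + manifest$length > nrow(scores))
  if (length(bad) > 0)
    stop("manifest rows out of bounds: ", paste(bad, collapse = ", "))
  values <- lapply(seq_len(nrow(manifest)), function(i)
    scores[manifest$onset[i] + seq_len(manifest$length[i]), , drop = FALSE])
  hsmm_trials(values, manifest$subject, manifest$condition,
              timepoint_seconds)
}

#' Full voxel-to-component preprocessing chain
#'
#' Applies, in order: mean-100 normalization, quartic polynomial
#' detrending and Wiener HRF deconvolution to each run (voxels x time),
#' concatenates the runs along time, l2-normalizes, reduces to principal
#' component scores, z-scores and truncates.
#'
#' @param runs list of voxels x time matrices, one per scanning run
#' @param repetition_time scan interval, seconds (default 2)
#' @param degree detrending polynomial degree (default 4)
#' @param n_components PCA components to keep (default 20)
#' @param noise_to_signal Wiener regularizer (default 0.1)
#' @param bound truncation bound on z scores (default 5)
#' @return list with `scores` (time x k, z-scored and truncated),
#'   `loadings`, `variance_fractions`, `run_rows` (row index ranges per
#'   run) and `deconvolved` (list of deconvolved voxels x time runs, for
#'   back-projection)
#' @export
preprocess_runs <- function(runs, repetition_time = 2, degree = 4,
                            n_components = 20, noise_to_signal = 0.1,
                            bound = 5) {
  stopifnot(is.list(runs), length(runs) >= 1)
  kern <- hrf_kernel(repetition_time)
  dec <- lapply(runs, function(r)
    wiener_deconvolve(detrend_polynomial(normalize_run(r), degree),
                      kern, noise_to_signal))
  concat <- do.call(rbind, lapply(dec, t))   # time x voxels
  red <- reduce_dimensions(concat, n_components)
  lens <- vapply(dec, ncol, integer(1))
  ends <- cumsum(lens)
  run_rows <- cbind(start = c(1, head(ends, -1) + 1), end = ends)
  list(scores = truncate_outliers(red$scores, bound),
       loadings = red$loadings,
       variance_fractions = red$variance_fractions,
       run_rows = run_rows,
       deconvolved = dec)
}

#' Back-project fitted states to voxel maps
#'
#' Returns, for each state (and condition), the occupancy-weighted mean of
#' the deconvolved voxel activity: the state's spatial activity map in the
#' original voxel space.
#'
#' @param occupancies list of M x N occupancy matrices, one per trial (see
#'   [occupancy()])
#' @param voxel_trials list of M x V matrices of deconvolved voxel
#'   activity, aligned time point for time point with `occupancies`
#' @param condition optional character vector of per-trial condition
#'   labels; maps are then computed per condition
#' @return N x V matrix of state mean activity, or a named list of such
#'   matrices (one per condition)
#' @export
backproject_states <- function(occupancies, voxel_trials, condition = NULL) {
  stopifnot(length(occupancies) == length(voxel_trials))
  for (i in seq_along(occupancies))
    if (nrow(occupancies[[i]]) != nrow(voxel_trials[[i]]))
      stop(sprintf("trial %d: occupancy and voxel data have different lengths", i))
  if (is.null(condition)) condition <- rep("all", length(occupancies))
  out <- lapply(unique(condition), function(cond) {
    idx <- which(condition == cond)
    num <- 0
    den <- 0
    for (i in idx) {
      num <- num + crossprod(occupancies[[i]], voxel_trials[[i]])
      den <- den + colSums(occupancies[[i]])
    }
    sweep(num, 1, pmax(den, .Machine$double.eps), `/`)
  })
  names(out) <- unique(condition)
  if (length(out) == 1) out[[1]] else out
}
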