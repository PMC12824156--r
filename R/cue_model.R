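# Per-timepoint cue probability distributions and consensus trajectories.

#' Across-observer consensus of rating series
#'
#' Aggregates several observers' rating series (same video, condition and
#' time grid) into the consensus trajectory: the per-timepoint sample mean
#' and sample standard deviation (n - 1 denominator) across observers for
#' one affect dimension. The across-observer spread at a timepoint is the
#' operational measure of cue ambiguity.
#'
#' @param series A list of `rating_series` sharing video, condition and
#'   grid, or a numeric matrix (timepoints x observers).
#' @param dimension `"valence"` or `"arousal"` (ignored for matrix input).
#' @return A `consensus_series`: list with `video_id`, `condition`,
#'   `dimension`, `times`, `mean`, `sd` (NA with a `sd_defined = FALSE`
#'   field when only one observer contributes) and `n_observers`.
#' @export
aggregate_consensus <- function(series, dimension = c("valence", "arousal")) {
  dimension <- match.arg(dimension)
  if (is.matrix(series)) {
    mat <- series
    meta <- list(video_id = NA_character_, condition = NA_character_,
                 times = seq_len(nrow(mat)))
  } else {
    if (!length(series)) stopf("need at least one series")
    if (!all(vapply(series, inherits, logical(1), "rating_series")))
      stopf("series must be rating_series objects or a matrix")
    t0 <- series[[1]]$times
    same <- vapply(series, function(s) {
      length(s$times) == length(t0) && all(s$times == t0) &&
        identical(s$video_id, series[[1]]$video_id) &&
        identical(s$condition, series[[1]]$condition)
    }, logical(1))
    if (!all(same)) stopf("series have mismatched grids or metadata")
    mat <- vapply(series, function(s) s$values[[dimension]],
                  numeric(length(t0)))
    mat <- matrix(mat, nrow = length(t0))
    meta <- list(video_id = series[[1]]$video_id,
                 condition = series[[1]]$condition, times = t0)
  }
  n <- ncol(mat)
  structure(
    list(video_id = meta$video_id, condition = meta$condition,
         dimension = dimension, times = meta$times,
         mean = rowMeans(mat), sd = row_sds(mat),
         n_observers = n, sd_defined = n >= 2L),
    class = "consensus_series"
  )
}

#' Gaussian cue distribution
#'
#' Represents a cue's per-timepoint rating distribution as a normal
#' density with the across-observer mean and standard deviation, the
#' default distributional backend. Standard deviations below `sigma_floor`
#' (e.g. when all observers agree exactly) are clamped to keep densities
#' proper. Vector `mu`/`sigma` describe one distribution per timepoint.
#'
#' @param mu Mean(s) of the rating distribution.
#' @param sigma Standard deviation(s); recycled against `mu`.
#' @param cue `"context"` or `"character"`.
#' @param dimension `"valence"` or `"arousal"`.
#' @param sigma_floor Lower bound applied to `sigma` (default 1e-3).
#' @return A `cue_distribution` with backend `"gaussian"`.
#' @export
build_gaussian_cue <- function(mu, sigma, cue = c("context", "character"),
                               dimension = c("valence", "arousal"),
                               sigma_floor = 1e-3) {
  cue <- match.arg(cue)
  dimension <- match.arg(dimension)
  if (!all(is.finite(mu))) stopf("mu must be finite")
  if (!all(is.finite(sigma))) stopf("sigma must be finite")
  n <- max(length(mu), length(sigma))
  mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n)
  if (any(sigma < sigma_floor)) {
    warning(sprintf("%d sigma value(s) below floor %g clamped",
                    sum(sigma < sigma_floor), sigma_floor), call. = FALSE)
    sigma <- pmax(sigma, sigma_floor)
  }
  structure(
    list(backend = "gaussian", cue = cue, dimension = dimension,
         mu = mu, sigma = sigma, n_timepoints = n),
    class = "cue_distribution"
  )
}

#' Kernel density cue distribution
#'
#' Alternative backend representing one timepoint's cue distribution as a
#' Gaussian kernel density over the raw observer ratings, with bandwidth
#' from Silverman's rule of thumb ([stats::bw.nrd0()]) by default. If all
#' samples coincide the KDE is degenerate and the constructor falls back
#' to a floored Gaussian.
#'
#' @param samples Observer ratings at one timepoint (length >= 2).
#' @param bandwidth_rule `"silverman"` or `"fixed"`.
#' @param bandwidth Bandwidth when `bandwidth_rule = "fixed"`.
#' @inheritParams build_gaussian_cue
#' @return A `cue_distribution` with backend `"kde"` (or `"gaussian"` on
#'   degenerate fallback).
#' @export
build_kde_cue <- function(samples, bandwidth_rule = c("silverman", "fixed"),
                          bandwidth = NULL, cue = c("context", "character"),
                          dimension = c("valence", "arousal"),
                          sigma_floor = 1e-3) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  cue <- match.arg(cue)
  dimension <- match.arg(dimension)
  if (length(samples) < 2L) stopf("kde backend requires >= 2 samples")
  if (!all(is.finite(samples))) stopf("samples must be finite")
  if (stats::sd(samples) == 0) {
    warning("all samples identical; falling back to floored gaussian",
            call. = FALSE)
    return(build_gaussian_cue(samples[1], sigma_floor, cue = cue,
                              dimension = dimension,
                              sigma_floor = sigma_floor))
  }
  bw <- switch(bandwidth_rule,
               silverman = stats::bw.nrd0(samples),
               fixed = {
                 if (is.null(bandwidth) || bandwidth <= 0)
                   stopf("fixed bandwidth_rule requires bandwidth > 0")
                 bandwidth
               })
  structure(
    list(backend = "kde", cue = cue, dimension = dimension,
         samples = samples, bandwidth = bw, n_timepoints = 1L),
    class = "cue_distribution"
  )
}

#' @export
print.cue_distribution <- function(x, ...) {
  cat(sprintf("<cue_distribution> %s / %s, backend %s, %d timepoint(s)\n",
              x$cue, x$dimension, x$backend, x$n_timepoints))
  invisible(x)
}

#' Log probability mass of a cue distribution on the affect grid
#'
#' Evaluates the cue density at the grid points, truncates it to
#' \eqn{[-1, 1]} by renormalizing on the grid, and returns per-point log
#' mass. Each column exponentiates to a probability vector summing to 1;
#' values are floored at the log of the smallest normal double so
#' downstream sums of log masses stay finite.
#'
#' @param dist A `cue_distribution`.
#' @param grid An [affect_grid()].
#' @return A `n_points` x `n_timepoints` matrix of log masses.
#' @export
log_density_on_grid <- function(dist, grid) {
  stopifnot(inherits(dist, "cue_distribution"), inherits(grid, "affect_grid"))
  x <- grid$points
  if (dist$backend == "gaussian") {
    z <- sweep(outer(x, dist$mu, "-"), 2, dist$sigma, "/")
    ld <- -0.5 * z^2
  } else {
    d <- rowMeans(dnorm(outer(x, dist$samples, "-"), sd = dist$bandwidth))
    ld <- matrix(log(pmax(d, .Machine$double.xmin)), ncol = 1)
  }
  m <- apply(ld, 2, max)
  lse <- m + log(colSums(exp(sweep(ld, 2, m, "-"))))
  out <- sweep(ld, 2, lse, "-")
  pmax(out, log(.Machine$double.xmin))
}
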