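#' Discretized affect axis
#'
#' Builds a uniform grid spanning the bounded affect axis \eqn{[-1, 1]}
#' together with a prior mass vector. All grid-based computations
#' (cue densities, Bayesian posteriors) live on this axis. The prior is
#' uniform by default; the log-sum-exp normalization used in
#' [bayes_integrate()] is exact for a flat prior.
#'
#' @param n_points Number of grid points (>= 3). The default 201 gives a
#'   step of 0.01 on \eqn{[-1, 1]}.
#' @param prior Optional per-point prior mass; renormalized to sum to 1.
#' @return An object of class `affect_grid` with fields `points`,
#'   `n_points`, `prior` and `step`.
#' @examples
#' g <- affect_grid()
#' range(g$points)
#' sum(g$prior)
#' @export
affect_grid <- function(n_points = 201, prior = NULL) {
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 3)
    stopf("n_points must be a single integer >= 3")
  n_points <- as.integer(n_points)
  points <- seq(-1, 1, length.out = n_points)
  if (is.null(prior)) {
    prior <- rep(1 / n_points, n_points)
  } else {
    if (length(prior) != n_points || any(prior < 0) || sum(prior) <= 0)
      stopf("prior must be %d nonnegative masses", n_points)
    prior <- prior / sum(prior)
  }
  structure(
    list(points = points, n_points = n_points, prior = prior,
         step = points[2] - points[1]),
    class = "affect_grid"
  )
}

#' @export
print.affect_grid <- function(x, ...) {
  cat(sprintf("<affect_grid> %d points on [-1, 1], step %.4g\n",
              x$n_points, x$step))
  invisible(x)
}
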