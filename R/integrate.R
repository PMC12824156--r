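# The seven candidate strategies mapping cue information to predicted
# affect, plus the numerically stable normalization they share.

MODEL_NAMES <- c("bayes", "heuristic", "context75", "character75",
                 "all_in", "random_switch", "correlated_switch")

#' Numerically stable log-sum-exp
#'
#' Computes \eqn{\log \sum_i e^{x_i}} with the usual max-subtraction
#' stabilization, so that sums of log probabilities can be normalized
#' without leaving log space. Shift-invariant:
#' `log_sum_exp(x + k) == log_sum_exp(x) + k`.
#'
#' @param x Non-empty numeric vector of finite log values.
#' @return A single number.
#' @examples
#' log_sum_exp(log(c(0.5, 0.5)))  # 0
#' @export
log_sum_exp <- function(x) {
  if (!length(x)) stopf("log_sum_exp: empty input")
  if (!all(is.finite(x))) stopf("log_sum_exp: non-finite input")
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Bayesian integration of two cue distributions
#'
#' Combines the context and character cue distributions on the affect
#' grid: the posterior log mass is the sum of the two cue log masses,
#' normalized by subtracting its log-sum-exp (exact normalization under
#' the flat prior). The point prediction is the posterior mean; the
#' posterior variance is never larger than either cue's variance, which is
#' the reliability gain that distinguishes Bayesian integration from
#' unweighted averaging.
#'
#' For two Gaussian cues well inside the rating bounds this matches the
#' closed-form precision-weighted product ([bayes_integrate_closed()]);
#' the grid path is authoritative for KDE cues and near the bounds, where
#' truncation to \eqn{[-1, 1]} matters.
#'
#' @param ctx,chr `cue_distribution` objects with equal numbers of
#'   timepoints.
#' @param grid An [affect_grid()].
#' @return List with `posterior` (n_points x timepoints mass matrix),
#'   `mean` and `variance` vectors.
#' @export
bayes_integrate <- function(ctx, chr, grid = affect_grid()) {
  stopifnot(inherits(ctx, "cue_distribution"),
            inherits(chr, "cue_distribution"))
  if (ctx$n_timepoints != chr$n_timepoints)
    stopf("cue distributions cover different numbers of timepoints")
  lp <- log_density_on_grid(ctx, grid) + log_density_on_grid(chr, grid)
  m <- apply(lp, 2, max)
  lse <- m + log(colSums(exp(sweep(lp, 2, m, "-"))))
  post <- exp(sweep(lp, 2, lse, "-"))
  mu <- colSums(post * grid$points)
  v <- colSums(post * grid$points^2) - mu^2
  list(posterior = post, mean = mu, variance = pmax(v, 0))
}

#' Closed-form Gaussian cue integration
#'
#' Precision-weighted product of two Gaussian cues on the unbounded axis:
#' mean \eqn{(\mu_c/\sigma_c^2 + \mu_f/\sigma_f^2) / (1/\sigma_c^2 +
#' 1/\sigma_f^2)} and variance \eqn{1 / (1/\sigma_c^2 + 1/\sigma_f^2)}.
#' Fast path for Gaussian cues, cross-checked against the grid path.
#'
#' @param mu_ctx,sd_ctx,mu_chr,sd_chr Cue means and standard deviations
#'   (vectors allowed).
#' @return List with `mean` and `variance` vectors.
#' @export
bayes_integrate_closed <- function(mu_ctx, sd_ctx, mu_chr, sd_chr) {
  p_c <- 1 / sd_ctx^2
  p_f <- 1 / sd_chr^2
  list(mean = (mu_ctx * p_c + mu_chr * p_f) / (p_c + p_f),
       variance = 1 / (p_c + p_f))
}

#' Heuristic (unweighted average) integration
#'
#' Averages the context and character ratings with equal weight,
#' disregarding cue reliability. The matching variance prediction is the
#' mean of the two cue variances, see [heuristic_variance()].
#'
#' @param r_ctx,r_chr Context and character ratings (vectors allowed).
#' @return `(r_chr + r_ctx) / 2`.
#' @export
heuristic_integrate <- function(r_ctx, r_chr) (r_chr + r_ctx) / 2

#' @rdname heuristic_integrate
#' @param var_ctx,var_chr Cue variances.
#' @export
heuristic_variance <- function(var_ctx, var_chr) (var_ctx + var_chr) / 2

#' Stable-weight integration
#'
#' Convex combination with a fixed context weight. `w_ctx = 0.75` is the
#' Context75 model and `w_ctx = 0.25` the Character75 model; `w_ctx = 0.5`
#' reproduces [heuristic_integrate()] exactly.
#'
#' @inheritParams heuristic_integrate
#' @param w_ctx Context weight in \eqn{[0, 1]}.
#' @export
fixed_weight_integrate <- function(r_ctx, r_chr, w_ctx) {
  if (!is.numeric(w_ctx) || length(w_ctx) != 1L || w_ctx < 0 || w_ctx > 1)
    stopf("w_ctx must be a single number in [0, 1]")
  w_ctx * r_ctx + (1 - w_ctx) * r_chr
}

#' All-In cue selection
#'
#' Non-integration strategy that commits entirely to the less ambiguous
#' cue: at each timepoint it returns the mean of whichever cue has the
#' lower across-observer variance. Ties go to the context cue.
#'
#' @param ctx,chr Gaussian `cue_distribution` objects, or see
#'   [all_in_means()] for the raw-vector form.
#' @return Vector of selected cue means.
#' @export
all_in_select <- function(ctx, chr) {
  stopifnot(inherits(ctx, "cue_distribution"),
            inherits(chr, "cue_distribution"),
            ctx$backend == "gaussian", chr$backend == "gaussian")
  all_in_means(ctx$mu, ctx$sigma, chr$mu, chr$sigma)
}

#' @rdname all_in_select
#' @inheritParams bayes_integrate_closed
#' @export
all_in_means <- function(mu_ctx, sd_ctx, mu_chr, sd_chr) {
  ifelse(sd_ctx <= sd_chr, mu_ctx, mu_chr)
}

#' Random Switch strategy
#'
#' At each timepoint picks the context or the character consensus rating
#' with independent 50% probability. One seeded realization per series;
#' the same seed reproduces the same choices.
#'
#' @param ctx_means,chr_means Equal-length cue mean vectors.
#' @param seed Integer seed for the switch sequence.
#' @return A `model_prediction`: list with `model`, `mean`, `variance`
#'   (NULL), `choice` (`"context"`/`"character"` per timepoint) and
#'   `rng_seed`.
#' @export
random_switch <- function(ctx_means, chr_means, seed = 1L) {
  if (length(ctx_means) != length(chr_means))
    stopf("cue mean vectors must have equal length")
  z <- withr::with_seed(seed, runif(length(ctx_means)) < 0.5)
  structure(
    list(model = "random_switch",
         mean = ifelse(z, ctx_means, chr_means), variance = NULL,
         choice = ifelse(z, "context", "character"),
         rng_seed = as.integer(seed)),
    class = "model_prediction"
  )
}

#' Correlated Switch strategy
#'
#' Two-state Markov chain over the cues: starts on either cue with a fair
#' coin, then switches cue with probability `p_switch` at each step
#' (default 0.10), producing long runs on one cue. `p_switch = 0` keeps
#' the initial cue forever; `p_switch = 1` alternates strictly.
#'
#' @inheritParams random_switch
#' @param p_switch Per-step switch probability in \eqn{[0, 1]}.
#' @export
correlated_switch <- function(ctx_means, chr_means, p_switch = 0.1,
                              seed = 1L) {
  if (length(ctx_means) != length(chr_means))
    stopf("cue mean vectors must have equal length")
  if (!is.numeric(p_switch) || p_switch < 0 || p_switch > 1)
    stopf("p_switch must be in [0, 1]")
  n <- length(ctx_means)
  z <- withr::with_seed(seed, {
    z1 <- runif(1) < 0.5
    flips <- if (n > 1) runif(n - 1) < p_switch else logical(0)
    (z1 + cumsum(c(0L, as.integer(flips)))) %% 2 == 1
  })
  structure(
    list(model = "correlated_switch",
         mean = ifelse(z, ctx_means, chr_means), variance = NULL,
         choice = ifelse(z, "context", "character"),
         rng_seed = as.integer(seed), p_switch = p_switch),
    class = "model_prediction"
  )
}

#' Monte-Carlo variance of a Bayesian posterior
#'
#' Draws `n_samples` ratings from the grid posterior mass and returns
#' their sample variance — the procedure used to obtain the Bayesian
#' model's variance prediction for comparison with ground-truth rating
#' variance (1000 draws by default).
#'
#' @param posterior Probability vector over `grid$points`.
#' @param grid An [affect_grid()].
#' @param n_samples Number of draws (>= 2, default 1000).
#' @param seed Integer seed.
#' @return Sample variance of the draws.
#' @export
bayes_predicted_variance_mc <- function(posterior, grid, n_samples = 1000,
                                        seed = 1L) {
  stopifnot(inherits(grid, "affect_grid"), n_samples >= 2,
            length(posterior) == grid$n_points)
  draws <- withr::with_seed(
    seed, sample(grid$points, n_samples, replace = TRUE, prob = posterior))
  stats::var(draws)
}

#' Predict one strategy's trajectory from per-timepoint cue summaries
#'
#' Shared dispatcher used by the group- and individual-level analyses:
#' given the per-timepoint cue means and across-observer standard
#' deviations, returns the named strategy's predicted rating trajectory
#' (and predicted variance, defined for `bayes` and `heuristic` only).
#' With `method = "closed_form"` the Bayes prediction uses the
#' precision-weighted Gaussian product; with `method = "grid"` it uses the
#' discretized posterior on `grid`.
#'
#' @param model One of `"bayes"`, `"heuristic"`, `"context75"`,
#'   `"character75"`, `"all_in"`, `"random_switch"`,
#'   `"correlated_switch"`.
#' @inheritParams bayes_integrate_closed
#' @param grid Affect grid used when `method = "grid"`.
#' @param method `"closed_form"` (default) or `"grid"`.
#' @param seed Seed for the switch strategies.
#' @param p_switch Switch probability for `correlated_switch`.
#' @param sigma_floor Floor applied to cue standard deviations.
#' @return List with `mean` and `variance` (NULL where undefined).
#' @export
predict_strategy <- function(model, mu_ctx, sd_ctx, mu_chr, sd_chr,
                             grid = NULL,
                             method = c("closed_form", "grid"),
                             seed = 1L, p_switch = 0.1,
                             sigma_floor = 1e-3) {
  method <- match.arg(method)
  model <- match.arg(model, MODEL_NAMES)
  sd_ctx <- pmax(sd_ctx, sigma_floor)
  sd_chr <- pmax(sd_chr, sigma_floor)
  switch(model,
    bayes = {
      if (method == "grid") {
        g <- grid %||% affect_grid()
        ctx <- build_gaussian_cue(mu_ctx, sd_ctx, "context",
                                  sigma_floor = sigma_floor)
        chr <- build_gaussian_cue(mu_chr, sd_chr, "character",
                                  sigma_floor = sigma_floor)
        res <- bayes_integrate(ctx, chr, g)
        list(mean = res$mean, variance = res$variance)
      } else {
        bayes_integrate_closed(mu_ctx, sd_ctx, mu_chr, sd_chr)
      }
    },
    heuristic = list(mean = heuristic_integrate(mu_ctx, mu_chr),
                     variance = heuristic_variance(sd_ctx^2, sd_chr^2)),
    context75 = list(mean = fixed_weight_integrate(mu_ctx, mu_chr, 0.75),
                     variance = NULL),
    character75 = list(mean = fixed_weight_integrate(mu_ctx, mu_chr, 0.25),
                       variance = NULL),
    all_in = list(mean = all_in_means(mu_ctx, sd_ctx, mu_chr, sd_chr),
                  variance = NULL),
    random_switch = {
      p <- random_switch(mu_ctx, mu_chr, seed = seed)
      list(mean = p$mean, variance = NULL)
    },
    correlated_switch = {
      p <- correlated_switch(mu_ctx, mu_chr, p_switch = p_switch,
                             seed = seed)
      list(mean = p$mean, variance = NULL)
    })
}
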