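# Bootstrap, paired tests, AIC-difference sign test, and protected
# exceedance probabilities.

#' Percentile bootstrap confidence interval
#'
#' Resamples the stated units (trials for the static design, subjects for
#' the dynamic designs) with replacement `n_boot` times and returns the
#' 2.5/97.5 percentile bounds of the statistic (5000 iterations by
#' default).
#'
#' @param data A numeric vector (units are elements), a data frame /
#'   matrix (units are rows), or a list (units are elements).
#' @param statistic Function mapping a resampled `data` to one number.
#' @param n_boot Number of bootstrap iterations.
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return List with `point`, `lower`, `upper`, `n_boot`.
#' @export
bootstrap_ci <- function(data, statistic = mean, n_boot = 5000, seed = 1L,
                         conf = 0.95) {
  take <- function(idx) {
    if (is.numeric(data) && is.null(dim(data))) data[idx]
    else if (is.data.frame(data) || is.matrix(data)) data[idx, , drop = FALSE]
    else data[idx]
  }
  n <- if (is.data.frame(data) || is.matrix(data)) nrow(data)
       else length(data)
  if (n < 2L) stopf("bootstrap needs at least 2 resampling units")
  point <- statistic(data)
  stats_b <- withr::with_seed(seed, {
    if (identical(statistic, mean) && is.numeric(data) &&
        is.null(dim(data))) {
      colMeans(matrix(data[sample.int(n, n * n_boot, replace = TRUE)],
                      nrow = n))
    } else {
      vapply(seq_len(n_boot), function(b) {
        statistic(take(sample.int(n, n, replace = TRUE)))
      }, numeric(1))
    }
  })
  alpha <- (1 - conf) / 2
  q <- stats::quantile(stats_b, c(alpha, 1 - alpha), names = FALSE,
                       na.rm = TRUE)
  list(point = point, lower = q[1], upper = q[2], n_boot = n_boot)
}

#' Paired two-tailed comparison of per-subject metrics
#'
#' Two-tailed paired t-test (default) or Wilcoxon signed-rank test on
#' within-subject differences. When every difference is zero the test is
#' degenerate and `(statistic = 0, p = 1)` is returned with
#' `degenerate = TRUE`.
#'
#' @param a,b Paired numeric vectors (length >= 3).
#' @param method `"t_test"` or `"wilcoxon"`.
#' @return List with `statistic`, `p_value`, `method`, `n`, `degenerate`.
#' @export
paired_compare <- function(a, b, method = c("t_test", "wilcoxon")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stopf("paired vectors must match in length")
  if (length(a) < 3L) stopf("need at least 3 pairs")
  d <- a - b
  if (all(d == 0)) {
    return(list(statistic = 0, p_value = 1, method = method,
                n = length(a), degenerate = TRUE))
  }
  res <- if (method == "t_test") {
    stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  } else {
    suppressWarnings(
      stats::wilcox.test(a, b, paired = TRUE, alternative = "two.sided",
                         exact = FALSE))
  }
  list(statistic = unname(res$statistic), p_value = res$p.value,
       method = method, n = length(a), degenerate = FALSE)
}

#' Chi-squared sign test on per-subject AIC differences
#'
#' Goodness-of-fit test of the sign counts of nonzero AIC differences
#' (Bayes minus opponent) against a 50/50 split; a small p-value means the
#' difference distribution is shifted away from zero. Zeros are excluded.
#'
#' @param differences Per-subject AIC differences.
#' @return List with `chi2`, `p_value`, `n_negative`, `n_positive`,
#'   `n_zero`, `degenerate`.
#' @export
aic_difference_test <- function(differences) {
  if (!length(differences)) stopf("need at least one difference")
  nz <- differences[differences != 0]
  n_zero <- sum(differences == 0)
  if (!length(nz)) {
    return(list(chi2 = NA_real_, p_value = NA_real_, n_negative = 0L,
                n_positive = 0L, n_zero = n_zero, degenerate = TRUE))
  }
  counts <- c(sum(nz < 0), sum(nz > 0))
  res <- suppressWarnings(stats::chisq.test(counts, p = c(0.5, 0.5)))
  list(chi2 = unname(res$statistic), p_value = res$p.value,
       n_negative = counts[1], n_positive = counts[2], n_zero = n_zero,
       degenerate = FALSE)
}

#' Protected exceedance probabilities
#'
#' Random-effects Bayesian model selection over per-subject log model
#' evidences (here taken as -AIC/2). A variational Dirichlet update
#' estimates the population frequency of each model; the exceedance
#' probability (chance a model is the most frequent) is computed by
#' Dirichlet Monte Carlo; protection multiplies by one minus the Bayesian
#' omnibus risk (the posterior probability that all models are equally
#' frequent) and mixes in the uniform distribution accordingly.
#'
#' @param evidences Subjects x models matrix of finite log evidences.
#' @param alpha0 Symmetric Dirichlet prior count per model (default 1).
#' @param n_dirichlet_samples Monte-Carlo sample count (default 1e5).
#' @param seed Integer seed for the Monte-Carlo step.
#' @return Named list with `pxp` (sums to 1), `ep`, `bor`, `alpha`,
#'   `expected_freq`.
#' @export
protected_exceedance_probability <- function(evidences, alpha0 = 1,
                                             n_dirichlet_samples = 1e5,
                                             seed = 1L) {
  lme <- as.matrix(evidences)
  if (!all(is.finite(lme))) stopf("log evidences must be finite")
  n <- nrow(lme)
  M <- ncol(lme)
  if (M < 2L) stopf("need at least 2 models")
  if (n < 2L) stopf("need at least 2 subjects")
  a0 <- rep(alpha0, M)
  a <- a0 + n / M
  g <- matrix(1 / M, n, M)
  for (iter in seq_len(500)) {
    elog <- digamma(a) - digamma(sum(a))
    u <- sweep(lme, 2, elog, "+")
    u <- u - apply(u, 1, max)
    g <- exp(u)
    g <- g / rowSums(g)
    a_new <- a0 + colSums(g)
    if (max(abs(a_new - a)) < 1e-10) { a <- a_new; break }
    a <- a_new
  }
  # exceedance probability by Dirichlet Monte Carlo
  ep <- withr::with_seed(seed, {
    draws <- matrix(rgamma(n_dirichlet_samples * M,
                           shape = rep(a, each = n_dirichlet_samples)),
                    nrow = n_dirichlet_samples)
    tabulate(max.col(draws, ties.method = "random"), M) /
      n_dirichlet_samples
  })
  # free energy of the random-effects model ...
  elog <- digamma(a) - digamma(sum(a))
  gl <- g * (lme + matrix(elog, n, M, byrow = TRUE) - log(pmax(g, 1e-300)))
  kl <- lgamma(sum(a)) - sum(lgamma(a)) - lgamma(sum(a0)) +
    sum(lgamma(a0)) + sum((a - a0) * elog)
  f1 <- sum(gl) - kl
  # ... versus the null model of equal frequencies 1/M
  f0 <- sum(apply(lme, 1, log_sum_exp) - log(M))
  bor <- 1 / (1 + exp(f1 - f0))
  pxp <- ep * (1 - bor) + bor / M
  names(pxp) <- names(ep) <- colnames(lme)
  list(pxp = pxp, ep = ep, bor = bor, alpha = a,
       expected_freq = a / sum(a))
}
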