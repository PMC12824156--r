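test_that("log_sum_exp matches direct summation and stays stable", {
  expect_equal(log_sum_exp(log(c(0.5, 0.5))), 0, tolerance = 1e-15)
  # high-precision oracle: log(e^0 + e^-1) - 1000
  expect_equal(log_sum_exp(c(-1000, -1001)), log1p(exp(-1)) - 1000,
               tolerance = 1e-12)
  expect_equal(log_sum_exp(c(-1000, -1001)), -999.6867, tolerance = 1e-4)
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(20)
    expect_equal(log_sum_exp(x), log(sum(exp(x))), tolerance = 1e-12)
    expect_equal(log_sum_exp(x + 5) - log_sum_exp(x), 5,
                 tolerance = 1e-12)
  }
  expect_error(log_sum_exp(numeric(0)), "empty")
})

test_that("grid Bayes integration matches the precision-weighted oracle", {
  g <- affect_grid()
  ctx <- build_gaussian_cue(0.0, 0.2, "context")
  chr <- build_gaussian_cue(0.5, 0.1, "character")
  res <- bayes_integrate(ctx, chr, g)
  # closed form: mean (0/0.04 + 0.5/0.01)/(25 + 100) = 0.4, var 1/125
  expect_equal(res$mean, 0.4, tolerance = 1e-3)
  expect_equal(res$variance, 0.008, tolerance = 2e-4)
  expect_equal(colSums(res$posterior), 1, tolerance = 1e-12)

  same <- bayes_integrate(build_gaussian_cue(0.3, 0.15),
                          build_gaussian_cue(0.3, 0.4), g)
  expect_equal(same$mean, 0.3, tolerance = 1e-3)
})

test_that("Bayes posterior obeys the reliability-gain contracts", {
  g <- affect_grid()
  set.seed(8)
  for (i in 1:25) {
    mu <- runif(2, -0.6, 0.6)
    sg <- runif(2, 0.05, 0.3)
    res <- bayes_integrate(build_gaussian_cue(mu[1], sg[1]),
                           build_gaussian_cue(mu[2], sg[2]), g)
    # narrower than either cue
    expect_lte(res$variance, min(sg^2) + 2e-4)
    # mean between the cues, biased toward the more reliable one
    expect_gte(res$mean, min(mu) - 1e-3)
    expect_lte(res$mean, max(mu) + 1e-3)
    sharper <- which.min(sg)
    expect_lte(abs(res$mean - mu[sharper]),
               abs(res$mean - mu[-sharper]) + 1e-9)
  }
})

test_that("equal reliabilities reduce Bayes to the Heuristic average", {
  g <- affect_grid()
  res <- bayes_integrate(build_gaussian_cue(-0.2, 0.12),
                         build_gaussian_cue(0.4, 0.12), g)
  expect_equal(res$mean, heuristic_integrate(-0.2, 0.4), tolerance = 1e-3)
})

test_that("heuristic and fixed-weight integration follow their formulas", {
  expect_equal(heuristic_integrate(0.2, 0.6), 0.4)
  expect_equal(heuristic_integrate(0.31, 0.31), 0.31)
  expect_equal(heuristic_integrate(-1, 1), 0)
  expect_equal(heuristic_variance(0.04, 0.01), 0.025)

  expect_equal(fixed_weight_integrate(0.4, 0.0, 0.75), 0.3)
  expect_identical(fixed_weight_integrate(0.123, -0.456, 0.5),
                   heuristic_integrate(0.123, -0.456))
  expect_equal(fixed_weight_integrate(0.7, -0.3, 1), 0.7)
  expect_error(fixed_weight_integrate(0, 0, 1.2), "\\[0, 1\\]")
})

test_that("all_in picks the lower-variance cue, ties to context", {
  ctx <- build_gaussian_cue(0.1, 0.1, "context")
  chr <- build_gaussian_cue(-0.4, 0.2, "character")
  expect_equal(all_in_select(ctx, chr), 0.1)
  tie <- build_gaussian_cue(-0.4, 0.1, "character")
  expect_equal(all_in_select(ctx, tie), 0.1)

  # alternating sharpness across timepoints follows per-timepoint argmin
  sd_c <- c(0.1, 0.3, 0.1, 0.3)
  sd_f <- c(0.3, 0.1, 0.3, 0.1)
  mu_c <- rep(0.5, 4)
  mu_f <- rep(-0.5, 4)
  oracle <- mapply(function(mc, mf, sc, sf) {
    if (sc <= sf) mc else mf
  }, mu_c, mu_f, sd_c, sd_f)
  expect_equal(all_in_means(mu_c, sd_c, mu_f, sd_f), oracle)
  expect_equal(oracle, c(0.5, -0.5, 0.5, -0.5))
})

test_that("random switch picks each cue with equal probability", {
  ctx <- rep(0.5, 30)
  chr <- rep(-0.5, 30)
  p1 <- random_switch(ctx, chr, seed = 3)
  expect_identical(p1$mean, random_switch(ctx, chr, seed = 3)$mean)
  expect_true(all(p1$mean %in% c(0.5, -0.5)))
  expect_equal(random_switch(ctx, ctx, seed = 5)$mean, ctx)

  means <- rowMeans(vapply(1:2000,
                           function(s) random_switch(ctx, chr, s)$mean,
                           numeric(30)))
  expect_lt(max(abs(means - heuristic_integrate(0.5, -0.5))), 0.06)
})

test_that("correlated switch is a two-state Markov chain", {
  ctx <- rep(1, 200)
  chr <- rep(-1, 200)
  frozen <- correlated_switch(ctx, chr, p_switch = 0, seed = 2)
  expect_length(unique(frozen$mean), 1L)
  alternating <- correlated_switch(ctx, chr, p_switch = 1, seed = 2)
  expect_true(all(abs(diff(alternating$mean)) == 2))

  long <- correlated_switch(rep(1, 10000), rep(-1, 10000),
                            p_switch = 0.1, seed = 4)
  switch_frac <- mean(diff(long$mean) != 0)
  expect_lt(abs(switch_frac - 0.1), 0.01)
  expect_true(all(long$mean %in% c(1, -1)))
})

test_that("Monte-Carlo posterior variance matches the closed form", {
  g <- affect_grid()
  delta <- rep(0, g$n_points)
  delta[101] <- 1
  expect_equal(bayes_predicted_variance_mc(delta, g, seed = 1), 0)

  res <- bayes_integrate(build_gaussian_cue(0.0, 0.2),
                         build_gaussian_cue(0.5, 0.1), g)
  v <- bayes_predicted_variance_mc(res$posterior[, 1], g,
                                   n_samples = 1000, seed = 6)
  se <- sqrt(2 / 999) * 0.008
  expect_lt(abs(v - 0.008), 3 * se)

  spread <- function(n) {
    sd(vapply(1:30, function(s) {
      bayes_predicted_variance_mc(res$posterior[, 1], g, n_samples = n,
                                  seed = s)
    }, numeric(1)))
  }
  expect_lt(spread(1600), spread(100))
})

test_that("switch-model outputs always come from one of the cues", {
  set.seed(12)
  ctx <- runif(50, -1, 1)
  chr <- runif(50, -1, 1)
  for (s in 1:5) {
    rs <- random_switch(ctx, chr, seed = s)$mean
    cs <- correlated_switch(ctx, chr, 0.2, seed = s)$mean
    expect_true(all(rs == ctx | rs == chr))
    expect_true(all(cs == ctx | cs == chr))
  }
})
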