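test_that("pearson_r and rmse follow their definitions", {
  x <- c(0.1, 0.4, -0.2, 0.7, 0.05)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, x + 0.3), 1)
  expect_warning(r0 <- pearson_r(rep(0.2, 5), x), "zero-variance")
  expect_true(is.na(r0))

  expect_equal(rmse(x, x), 0)
  expect_equal(rmse(x, x + 0.1), 0.1)
  expect_equal(rmse(c(0, 0), c(0.3, -0.3)), 0.3)
})

test_that("aic implements the profiled Gaussian form", {
  expect_equal(aic(1, 100, 2), 100 * log(0.01) + 4)
  expect_equal(aic(1, 100, 2), -456.5170185988091)
  expect_equal(aic(50, 50, 0), 0)
  expect_equal(aic(3, 40, 3) - aic(3, 40, 2), 2)
  expect_warning(a0 <- aic(0, 10, 1), "perfect fit")
  expect_identical(a0, -Inf)
  expect_error(aic(1, 3, 5), "n > k")
})

test_that("bootstrap percentile CI behaves on degenerate and smooth data", {
  const <- bootstrap_ci(rep(0.4, 20), mean, n_boot = 200, seed = 1)
  expect_equal(const$lower, 0.4)
  expect_equal(const$upper, 0.4)
  expect_equal(const$point, 0.4)

  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(30)
    ci <- bootstrap_ci(x, mean, n_boot = 500, seed = i)
    expect_lte(ci$lower, ci$point)
    expect_gte(ci$upper, ci$point)
  }
  expect_error(bootstrap_ci(1, mean), "at least 2")
})

test_that("bootstrap CI narrows as the number of units grows", {
  set.seed(14)
  pool <- rnorm(400)
  w <- vapply(c(40, 400), function(n) {
    ci <- bootstrap_ci(pool[seq_len(n)], mean, n_boot = 2000, seed = 2)
    ci$upper - ci$lower
  }, numeric(1))
  expect_lt(w[2], w[1])
})

test_that("paired comparisons are two-tailed and flag degenerate input", {
  a <- c(0.1, 0.2, 0.3, 0.15, 0.22)
  same <- paired_compare(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  set.seed(6)
  b <- a + 2 + rnorm(5, sd = 0.01)
  shifted <- paired_compare(b, a, method = "t_test")
  # closed-form paired t oracle
  d <- b - a
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(shifted$statistic, t_oracle)
  expect_lt(shifted$p_value, 0.001)
})

test_that("wilcoxon p-values are calibrated under a symmetric null", {
  set.seed(10)
  p <- vapply(1:400, function(i) {
    d <- rnorm(20)
    paired_compare(d, rep(0, 20), method = "wilcoxon")$p_value
  }, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.04)
  expect_lt(abs(mean(p) - 0.5), 0.06)
})

test_that("AIC-difference sign test matches its closed form", {
  balanced <- aic_difference_test(c(rep(-1, 50), rep(1, 50)))
  expect_equal(balanced$chi2, 0)
  expect_equal(balanced$p_value, 1)

  skewed <- aic_difference_test(c(rep(-1, 90), rep(1, 10)))
  expect_equal(skewed$chi2, 64)  # (40^2 + 40^2) / 50

  # p decreases monotonically with imbalance at fixed n
  ps <- vapply(c(55, 65, 75, 85), function(k) {
    aic_difference_test(c(rep(-1, k), rep(1, 100 - k)))$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))

  with_zeros <- aic_difference_test(c(rep(-1, 90), rep(1, 10), rep(0, 7)))
  expect_equal(with_zeros$chi2, 64)
  expect_equal(with_zeros$n_zero, 7L)
  expect_true(aic_difference_test(rep(0, 5))$degenerate)
})

test_that("PXP is uniform for indistinguishable models and certain for a
           dominant one", {
  set.seed(21)
  base <- rnorm(20, -50, 5)
  same <- matrix(base, nrow = 20, ncol = 3)
  colnames(same) <- c("a", "b", "c")
  res <- protected_exceedance_probability(same, seed = 3)
  expect_equal(sum(res$pxp), 1, tolerance = 1e-9)
  expect_true(all(abs(res$pxp - 1 / 3) < 0.02))
  expect_gt(res$bor, 0.9)

  dominant <- same
  dominant[, 1] <- dominant[, 1] + 100
  res2 <- protected_exceedance_probability(dominant, seed = 3)
  expect_gt(res2$pxp[["a"]], 0.99)
  expect_equal(sum(res2$pxp), 1, tolerance = 1e-9)

  # invariant to adding a per-subject constant to all models
  shifted <- dominant + rnorm(20)
  res3 <- protected_exceedance_probability(shifted, seed = 3)
  expect_equal(res3$pxp, res2$pxp, tolerance = 1e-12)

  expect_error(protected_exceedance_probability(cbind(1:3, c(1, NA, 2))),
               "finite")
})

test_that("variance predictions are scored against ground-truth variance", {
  v <- c(0.01, 0.02, 0.04, 0.03)
  perfect <- variance_prediction_check(v, v * 2, v)
  expect_equal(perfect$pearson_r[1], 1)
  expect_equal(perfect$rmse[1], 0)
  expect_equal(heuristic_variance(0.04, 0.01), 0.025)
})

test_that("heuristic variance prediction wins on heuristic-generated data", {
  cfg <- small_config(n_videos = 2, n_observers = 30,
                      generating_strategy = "heuristic",
                      gt_noise = "strategy_variance", seed = 21)
  rep_h <- run_group_level(generate_dataset(cfg),
                           models = c("bayes", "heuristic"), n_boot = 0,
                           variance_check = TRUE, seed = 3)
  vc <- rep_h$variance_check
  expect_lt(vc$rmse[vc$model == "heuristic"],
            vc$rmse[vc$model == "bayes"])
})

test_that("group-level comparison recovers the generating strategy", {
  for (gen in c("bayes", "heuristic")) {
    coh <- generate_dataset(small_config(generating_strategy = gen,
                                         seed = 31))
    rep <- run_group_level(coh, n_boot = 0, seed = 2)
    expect_equal(rep$winner, gen)
    expect_equal(nrow(rep$metrics), 7L)
    # duplicated model entries yield identical metrics
    dup <- run_group_level(coh, models = c("heuristic", "heuristic"),
                           n_boot = 0, seed = 2)
    expect_equal(dup$metrics$aic[1], dup$metrics$aic[2])
  }
})

test_that("bayes and heuristic metrics coincide when cue spreads are equal", {
  coh <- generate_dataset(small_config(sigma_schedule = "constant",
                                       generating_strategy = "heuristic",
                                       seed = 13))
  # whenever both cues carry the same per-timepoint sd, the two
  # strategies produce the same prediction, hence identical metrics
  for (v in names(coh$videos)) {
    r <- coh$videos[[v]]$dims$valence$ratings
    mu_c <- rowMeans(r$context_only)
    mu_f <- rowMeans(r$character_only)
    sd_shared <- apply(r$context_only, 1, sd)
    pb <- predict_strategy("bayes", mu_c, sd_shared, mu_f, sd_shared)
    ph <- predict_strategy("heuristic", mu_c, sd_shared, mu_f, sd_shared)
    expect_equal(pb$mean, ph$mean, tolerance = 1e-12)
  }
})

test_that("individual-level analysis records winners, tests and PXP", {
  coh <- generate_dataset(small_config(seed = 17))
  rep <- run_individual_level(coh, models = c("bayes", "heuristic"),
                              n_boot = 100, seed = 5)
  expect_equal(sort(unique(rep$per_observer$model)),
               c("bayes", "heuristic"))
  expect_length(rep$winners, 15L)
  expect_equal(rep$winner, "bayes")
  expect_gt(mean(rep$winners == "bayes"), 0.9)
  expect_equal(sum(rep$pxp$pxp), 1, tolerance = 1e-9)
  expect_false(is.null(rep$aic_diff_tests$heuristic$chi2))
  expect_true(all(rep$ci$lower <= rep$ci$upper))

  # observers with identical data get identical metrics
  one_video <- coh$videos[[1]]
  for (d in c("valence", "arousal")) {
    r <- one_video$dims[[d]]$ratings
    for (cond in names(r)) r[[cond]][, 2] <- r[[cond]][, 1]
    one_video$dims[[d]]$ratings <- r
  }
  coh2 <- coh
  coh2$videos <- list(video01 = one_video)
  rep2 <- run_individual_level(coh2, models = c("bayes", "heuristic"),
                               n_boot = 0, pxp = FALSE, seed = 5)
  a <- rep2$per_observer[rep2$per_observer$model == "bayes", ]
  expect_equal(a$aic[1], a$aic[2])
})

test_that("a single observer yields a flagged, test-free report", {
  coh <- generate_dataset(small_config(n_observers = 1, n_videos = 1,
                                       seed = 23))
  rep <- run_individual_level(coh, models = c("bayes", "heuristic"),
                              n_boot = 100, seed = 2)
  expect_true(rep$single_observer)
  expect_null(rep$aic_diff_tests)
  expect_null(rep$pxp)
  expect_null(rep$ci)
})
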