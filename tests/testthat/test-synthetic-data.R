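test_that("trajectories are smooth, bounded, and seed-deterministic", {
  times <- seq(0, 30, 0.1)
  t1 <- generate_trajectory(times, seed = 5)
  expect_identical(t1, generate_trajectory(times, seed = 5))
  for (s in 1:200) {
    tr <- generate_trajectory(times, amplitude = 0.9, seed = s)
    expect_true(all(tr >= -1 & tr <= 1))
  }
  flat <- generate_trajectory(times, smoothness_s = 1e7, seed = 5)
  expect_lt(diff(range(flat)), 1e-4)
})

test_that("cue channels recover the configured ambiguity schedule", {
  times <- seq(0, 30, 0.1)
  latent <- generate_trajectory(times, amplitude = 0.3, seed = 2)

  clean <- generate_cue_channels(latent, rep(1e-12, length(times)),
                                 rep(1e-12, length(times)),
                                 n_observers = 3, seed = 1)
  expect_equal(clean$ctx[, 1], latent, tolerance = 1e-9)
  expect_equal(clean$chr[, 3], latent, tolerance = 1e-9)

  const <- generate_cue_channels(latent, rep(0.2, length(times)),
                                 rep(0.2, length(times)),
                                 n_observers = 200, seed = 3)
  sds <- apply(const$ctx, 1, sd)
  expect_lt(abs(mean(sds) - 0.2), 0.02)

  sched <- 0.25 + 0.2 * sin(2 * pi * times / 10)
  varying <- generate_cue_channels(latent, sched, rep(0.2, length(times)),
                                   n_observers = 200, seed = 4)
  est <- apply(varying$ctx, 1, sd)
  expect_gt(cor(est, sched), 0.9)
})

test_that("ground truth follows the generating strategy's formula", {
  n <- 50
  mu_c <- seq(-0.5, 0.5, length.out = n)
  mu_f <- rev(mu_c)
  sd_c <- rep(0.2, n)
  sd_f <- rep(0.1, n)

  heur <- generate_ground_truth(mu_c, mu_f, sd_c, sd_f, "heuristic",
                                noise_sd = 1e-12, n_observers = 2,
                                seed = 1, gt_from = "true_means")
  expect_equal(heur$gt[, 1], (mu_c + mu_f) / 2, tolerance = 1e-9)

  bay_eq <- generate_ground_truth(mu_c, mu_f, sd_c, sd_c, "bayes",
                                  noise_sd = 1e-12, n_observers = 1,
                                  seed = 1, gt_from = "true_means")
  expect_equal(bay_eq$gt[, 1], (mu_c + mu_f) / 2, tolerance = 1e-9)

  allin <- generate_ground_truth(mu_c, mu_f, sd_c, sd_f, "all_in",
                                 noise_sd = 1e-12, n_observers = 1,
                                 seed = 1, gt_from = "true_means")
  expect_equal(allin$gt[, 1], mu_f, tolerance = 1e-9)  # sharper cue

  mixed <- generate_ground_truth(mu_c, mu_f, sd_c, sd_f,
                                 rep(c("heuristic", "context75"), 2),
                                 noise_sd = 1e-12, n_observers = 4,
                                 seed = 1, gt_from = "true_means")
  expect_equal(mixed$gt[, 2], 0.75 * mu_c + 0.25 * mu_f,
               tolerance = 1e-9)
  expect_equal(mixed$strategies,
               c("heuristic", "context75", "heuristic", "context75"))
})

test_that("datasets are deterministic and validate as rating tables", {
  cfg <- small_config(n_videos = 1, duration_s = 8, n_observers = 4)
  coh1 <- generate_dataset(cfg)
  coh2 <- generate_dataset(cfg)
  expect_identical(coh1, coh2)

  df <- as_rating_table(coh1)
  expect_s3_class(validate_ratings(df), "rating_table")
  # 4 observers x 3 conditions x 81 timepoints
  expect_equal(nrow(df), 4 * 3 * 81)

  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_ratings(as_rating_table(coh1), p1)
  write_ratings(as_rating_table(generate_dataset(cfg)), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("a rating table round-trips into an equivalent cohort", {
  cfg <- small_config(n_videos = 2, duration_s = 6, n_observers = 3)
  coh <- generate_dataset(cfg)
  back <- as_cohort(as_rating_table(coh))
  expect_equal(length(back$videos), 2L)
  orig <- coh$videos$video01$dims$valence$ratings$ground_truth
  rt <- back$videos$video01$dims$valence$ratings$ground_truth
  expect_equal(unname(rt), unname(orig))
})

test_that("equal ambiguity schedules erase the generator's identity", {
  coh_b <- generate_dataset(small_config(sigma_schedule = "constant",
                                         generating_strategy = "bayes",
                                         seed = 41))
  coh_h <- generate_dataset(small_config(sigma_schedule = "constant",
                                         generating_strategy = "heuristic",
                                         seed = 41))
  gt_b <- coh_b$videos$video01$dims$valence$ratings$ground_truth
  gt_h <- coh_h$videos$video01$dims$valence$ratings$ground_truth
  expect_equal(gt_b, gt_h, tolerance = 1e-12)
})

test_that("config validation rejects impossible study conditions", {
  expect_error(synthetic_config(sigma_base = 0.1, sigma_amplitude = 0.2),
               "sigma_base")
  expect_error(synthetic_config(duration_s = 1.03, dt_s = 0.1),
               "multiple")
  expect_error(synthetic_config(generating_strategy = "oracle"),
               "unknown generating_strategy")
})
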