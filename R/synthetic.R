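# Synthetic rating cohorts with a known generating strategy: a smooth
# latent affect trajectory, two cue channels with time-varying ambiguity,
# observer noise, and a ground-truth channel produced by one of the seven
# strategies. Everything is deterministic under the config seed.

#' Configuration for a synthetic rating cohort
#'
#' Defines the study conditions a generated cohort emulates. The dynamic
#' mode mirrors continuous-tracking designs (ratings on a uniform grid,
#' 100 ms by default); the static mode mirrors independent-frame designs
#' (one sample per trial, frames drawn at 2 Hz from source videos, so
#' consecutive trials are independent draws).
#'
#' Cue ambiguity follows a schedule: `"sinusoidal"` (default) makes the
#' two cues' across-observer spreads oscillate in antiphase between
#' `sigma_base - sigma_amplitude` and `sigma_base + sigma_amplitude`, so
#' the reliability ratio sweeps well above 3 and reliability-sensitive
#' strategies are identifiable; `"constant"` fixes both spreads at
#' `sigma_base` (the identifiability boundary where Bayes and Heuristic
#' coincide); `"piecewise"` alternates blocks of high/low ambiguity.
#'
#' @param mode `"dynamic"` or `"static"`.
#' @param n_videos Number of videos (dynamic) or pseudo-videos grouping
#'   trials (static).
#' @param duration_s Video duration in seconds (dynamic mode).
#' @param dt_s Sampling grid step in seconds; 0.1 by default, 0.04 for
#'   finer tracking, 0.5 for frame-paced designs.
#' @param n_trials Trials per pseudo-video in static mode.
#' @param n_observers Observers per condition.
#' @param traj_amplitude Peak absolute value of the latent trajectory.
#' @param traj_smoothness_s Timescale (s) of the slowest trajectory
#'   component; larger is smoother.
#' @param bias_amplitude Peak systematic deviation of each cue's mean from
#'   the latent trajectory (cues carry partial, not identical,
#'   information).
#' @param bias_smoothness_s Timescale (s) of the cue bias drift.
#' @param sigma_schedule `"sinusoidal"`, `"constant"` or `"piecewise"`.
#' @param sigma_base,sigma_amplitude Center and half-range of the cue
#'   ambiguity schedules (standard deviations of observer ratings around
#'   the cue mean); must satisfy `sigma_base > sigma_amplitude >= 0`.
#' @param sigma_cycles Oscillation count of the ambiguity schedule per
#'   video.
#' @param generating_strategy Strategy producing the ground-truth channel;
#'   either one model name or one per observer (enables mixed cohorts).
#' @param gt_from Whether ground-truth observers apply the strategy to
#'   their own cue-channel ratings (`"own_ratings"`, the within-subject
#'   reading, default) or to the true cue means (`"true_means"`); see
#'   [generate_ground_truth()].
#' @param gt_noise Ground-truth noise model, `"fixed"` or
#'   `"strategy_variance"`; see [generate_ground_truth()].
#' @param observer_noise_sd Motor/decision noise added to each ground-truth
#'   observer's rating.
#' @param p_switch Switch probability used when the generating strategy is
#'   `correlated_switch`.
#' @param lag_s Optional response lag applied to ground-truth observers.
#' @param seed Integer master seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(mode = c("dynamic", "static"),
                             n_videos = 12, duration_s = 90, dt_s = 0.1,
                             n_trials = 200, n_observers = 50,
                             traj_amplitude = 0.6, traj_smoothness_s = 15,
                             bias_amplitude = 0.25, bias_smoothness_s = 20,
                             sigma_schedule = c("sinusoidal", "constant",
                                                "piecewise"),
                             sigma_base = 0.28, sigma_amplitude = 0.22,
                             sigma_cycles = 2,
                             generating_strategy = "bayes",
                             gt_from = c("own_ratings", "true_means"),
                             gt_noise = c("fixed", "strategy_variance"),
                             observer_noise_sd = 0.1, p_switch = 0.1,
                             lag_s = 0, seed = 1L) {
  cfg <- list(mode = match.arg(mode), n_videos = as.integer(n_videos),
              duration_s = duration_s, dt_s = dt_s,
              n_trials = as.integer(n_trials),
              n_observers = as.integer(n_observers),
              traj_amplitude = traj_amplitude,
              traj_smoothness_s = traj_smoothness_s,
              bias_amplitude = bias_amplitude,
              bias_smoothness_s = bias_smoothness_s,
              sigma_schedule = match.arg(sigma_schedule),
              sigma_base = sigma_base,
              sigma_amplitude = sigma_amplitude,
              sigma_cycles = sigma_cycles,
              generating_strategy = generating_strategy,
              gt_from = match.arg(gt_from),
              gt_noise = match.arg(gt_noise),
              observer_noise_sd = observer_noise_sd,
              p_switch = p_switch, lag_s = lag_s,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  required <- c("mode", "n_videos", "dt_s", "n_observers",
                "generating_strategy", "seed")
  for (key in required) {
    if (is.null(cfg[[key]])) stopf("config is missing required key '%s'", key)
  }
  if (!cfg$mode %in% c("dynamic", "static")) stopf("unknown mode '%s'", cfg$mode)
  if (cfg$dt_s <= 0) stopf("dt_s must be positive")
  if (cfg$mode == "dynamic" &&
      abs(cfg$duration_s / cfg$dt_s - round(cfg$duration_s / cfg$dt_s)) > 1e-9)
    stopf("duration_s must be an integer multiple of dt_s")
  if (cfg$sigma_base <= cfg$sigma_amplitude || cfg$sigma_amplitude < 0)
    stopf("need sigma_base > sigma_amplitude >= 0 (all sds positive)")
  if (cfg$observer_noise_sd <= 0) stopf("observer_noise_sd must be > 0")
  if (!all(cfg$generating_strategy %in% MODEL_NAMES))
    stopf("unknown generating_strategy: %s",
          paste(setdiff(cfg$generating_strategy, MODEL_NAMES),
                collapse = ", "))
  if (cfg$n_observers < 1) stopf("n_observers must be >= 1")
  structure(cfg, class = "synthetic_config")
}

#' Smooth bounded latent affect trajectory
#'
#' Band-limited sum of five harmonic components with random amplitudes and
#' phases, rescaled to peak at `amplitude` and clipped to \eqn{[-1, 1]}.
#' The slowest component has period `2 * smoothness_s`; as
#' `smoothness_s` grows the trajectory flattens toward a constant.
#'
#' @param times Time grid in seconds.
#' @param amplitude Peak absolute value (<= 1).
#' @param smoothness_s Timescale of the slowest component in seconds.
#' @param seed Integer seed.
#' @return Numeric vector over `times`, within \eqn{[-1, 1]}.
#' @export
generate_trajectory <- function(times, amplitude = 0.6, smoothness_s = 15,
                                seed = 1L) {
  withr::with_seed(seed, {
    k <- 1:5
    a <- rnorm(5, sd = 1 / k)
    phi <- runif(5, 0, 2 * pi)
    raw <- rowSums(sapply(seq_along(k), function(i) {
      a[i] * sin(2 * pi * k[i] * times / (2 * smoothness_s) + phi[i])
    }))
    peak <- max(abs(raw))
    if (peak > 0) raw <- raw / peak
    clip1(amplitude * raw)
  })
}

# Ambiguity schedules for the two cues over one video.
sigma_schedules <- function(cfg, times, seed) {
  n <- length(times)
  if (cfg$sigma_schedule == "constant")
    return(list(ctx = rep(cfg$sigma_base, n), chr = rep(cfg$sigma_base, n)))
  phase <- withr::with_seed(seed, runif(1, 0, 2 * pi))
  span <- if (cfg$mode == "static") n * 1.0 else cfg$duration_s
  u <- 2 * pi * cfg$sigma_cycles * (times - times[1]) / span + phase
  if (cfg$sigma_schedule == "sinusoidal") {
    list(ctx = cfg$sigma_base + cfg$sigma_amplitude * sin(u),
         chr = cfg$sigma_base - cfg$sigma_amplitude * sin(u))
  } else {
    high <- sin(u) >= 0
    list(ctx = ifelse(high, cfg$sigma_base + cfg$sigma_amplitude,
                      cfg$sigma_base - cfg$sigma_amplitude),
         chr = ifelse(high, cfg$sigma_base - cfg$sigma_amplitude,
                      cfg$sigma_base + cfg$sigma_amplitude))
  }
}

#' Observer rating matrices for the two cue channels
#'
#' Each observer's rating at time t is the cue mean (latent trajectory
#' plus the cue's systematic bias) plus independent Gaussian noise with
#' the scheduled ambiguity sd, clipped to the rating bounds. The
#' across-observer spread therefore recovers the configured schedule
#' wherever the cue mean is comfortably inside the bounds.
#'
#' @param latent Latent trajectory vector.
#' @param sd_ctx,sd_chr Per-timepoint ambiguity schedules (> 0).
#' @param bias_ctx,bias_chr Per-timepoint cue mean deviations.
#' @param n_observers Observers per cue condition.
#' @param seed Integer seed.
#' @return List with cue means `mu_ctx`, `mu_chr` and rating matrices
#'   `ctx`, `chr` (timepoints x observers).
#' @export
generate_cue_channels <- function(latent, sd_ctx, sd_chr,
                                  bias_ctx = 0, bias_chr = 0,
                                  n_observers = 50, seed = 1L) {
  if (any(sd_ctx <= 0) || any(sd_chr <= 0)) stopf("sigma schedules must be positive")
  n_t <- length(latent)
  mu_ctx <- clip1(latent + bias_ctx)
  mu_chr <- clip1(latent + bias_chr)
  mats <- withr::with_seed(seed, {
    list(ctx = clip1(mu_ctx + matrix(rnorm(n_t * n_observers), n_t) * sd_ctx),
         chr = clip1(mu_chr + matrix(rnorm(n_t * n_observers), n_t) * sd_chr))
  })
  list(mu_ctx = mu_ctx, mu_chr = mu_chr, ctx = mats$ctx, chr = mats$chr)
}

#' Ground-truth rating matrix from a known strategy
#'
#' Builds the ground-truth condition of a cohort whose generating
#' strategy is known. By default (`gt_from = "own_ratings"`, the
#' within-subject reading) each ground-truth observer applies the
#' strategy to their *own* cue-channel ratings — the same percepts they
#' reported in the context-only and character-only conditions — with the
#' reliability weights taken from the true ambiguity schedules; observer
#' noise is then added and the result clipped to the rating bounds. With
#' `gt_from = "true_means"` every observer instead shares the strategy's
#' prediction from the true cue mean trajectories. Switch strategies get
#' one seeded realization per observer. A vector of strategies (one per
#' observer) produces a mixed cohort.
#'
#' @param mu_ctx,mu_chr True cue mean trajectories.
#' @param sd_ctx,sd_chr True ambiguity schedules.
#' @param strategy Model name, length 1 or `n_observers`.
#' @param noise_sd Observer noise standard deviation.
#' @param n_observers Number of ground-truth observers.
#' @param p_switch Switch probability for `correlated_switch`.
#' @param seed Integer seed.
#' @param ctx_ratings,chr_ratings Timepoints x observers cue rating
#'   matrices (required for `gt_from = "own_ratings"`).
#' @param gt_from `"own_ratings"` (default) or `"true_means"`.
#' @param gt_noise `"fixed"` (default): observer noise has constant sd
#'   `noise_sd`, so cohorts generated by different strategies under equal
#'   ambiguity schedules are distributionally identical (the
#'   identifiability boundary). `"strategy_variance"`: each rating
#'   additionally samples from the strategy's own integrated distribution
#'   where one is defined (Bayes posterior variance, Heuristic mean of
#'   cue variances), making the ground-truth rating spread carry the
#'   strategy's variance signature.
#' @return List with `gt` (timepoints x observers matrix) and
#'   `strategies` (per-observer generating model).
#' @export
generate_ground_truth <- function(mu_ctx, mu_chr, sd_ctx, sd_chr,
                                  strategy = "bayes", noise_sd = 0.1,
                                  n_observers = 50, p_switch = 0.1,
                                  seed = 1L,
                                  ctx_ratings = NULL, chr_ratings = NULL,
                                  gt_from = c("own_ratings",
                                              "true_means"),
                                  gt_noise = c("fixed",
                                               "strategy_variance")) {
  gt_from <- match.arg(gt_from)
  gt_noise <- match.arg(gt_noise)
  strategies <- rep_len(strategy, n_observers)
  n_t <- length(mu_ctx)
  if (gt_from == "own_ratings") {
    if (is.null(ctx_ratings) || is.null(chr_ratings))
      stopf("gt_from = 'own_ratings' requires the cue rating matrices")
    stopifnot(ncol(ctx_ratings) >= n_observers,
              nrow(ctx_ratings) == n_t)
  }
  gt <- matrix(NA_real_, n_t, n_observers)
  noise_var <- matrix(noise_sd^2, n_t, n_observers)
  for (s in unique(strategies)) {
    idx <- which(strategies == s)
    in_ctx <- if (gt_from == "own_ratings") {
      ctx_ratings[, idx, drop = FALSE]
    } else matrix(mu_ctx, n_t, length(idx))
    in_chr <- if (gt_from == "own_ratings") {
      chr_ratings[, idx, drop = FALSE]
    } else matrix(mu_chr, n_t, length(idx))
    gt[, idx] <- predict_battery(s, in_ctx, in_chr, sd_ctx, sd_chr,
                                 seed = derive_seed(seed, "strategy", s),
                                 p_switch = p_switch)[[1]]
    if (gt_noise == "strategy_variance") {
      sv <- switch(s,
                   bayes = bayes_integrate_closed(0, sd_ctx, 0,
                                                  sd_chr)$variance,
                   heuristic = heuristic_variance(sd_ctx^2, sd_chr^2),
                   rep(0, n_t))
      noise_var[, idx] <- noise_var[, idx] + sv
    }
  }
  noise <- withr::with_seed(derive_seed(seed, "noise"),
                            matrix(rnorm(n_t * n_observers), n_t) *
                              sqrt(noise_var))
  list(gt = clip1(gt + noise), strategies = strategies)
}

#' Generate a full synthetic rating cohort
#'
#' Produces a `cue_cohort`: for each video and each affect dimension, the
#' latent trajectory, the true cue means and ambiguity schedules, and the
#' three observer rating matrices (context-only, character-only,
#' ground-truth). Byte-identical under the same config.
#'
#' @param config A [synthetic_config()].
#' @return A `cue_cohort` object.
#' @export
generate_dataset <- function(config) {
  cfg <- validate_synthetic_config(config)
  times <- if (cfg$mode == "dynamic") {
    seq(0, cfg$duration_s, by = cfg$dt_s)
  } else {
    seq_len(cfg$n_trials) - 1
  }
  dims <- c("valence", "arousal")
  videos <- vector("list", cfg$n_videos)
  names(videos) <- sprintf("video%02d", seq_len(cfg$n_videos))
  for (v in seq_len(cfg$n_videos)) {
    per_dim <- lapply(setNames(dims, dims), function(d) {
      sv <- derive_seed(cfg$seed, "video", v, d)
      if (cfg$mode == "dynamic") {
        latent <- generate_trajectory(times, cfg$traj_amplitude,
                                      cfg$traj_smoothness_s,
                                      seed = derive_seed(sv, "traj"))
        bias_ctx <- generate_trajectory(times, cfg$bias_amplitude,
                                        cfg$bias_smoothness_s,
                                        seed = derive_seed(sv, "bias_ctx"))
        bias_chr <- generate_trajectory(times, cfg$bias_amplitude,
                                        cfg$bias_smoothness_s,
                                        seed = derive_seed(sv, "bias_chr"))
        sig <- sigma_schedules(cfg, times, derive_seed(sv, "sigma"))
      } else {
        # static frames: independent draws per trial
        n <- length(times)
        draws <- withr::with_seed(derive_seed(sv, "static"), {
          list(latent = runif(n, -cfg$traj_amplitude, cfg$traj_amplitude),
               bias_ctx = runif(n, -cfg$bias_amplitude, cfg$bias_amplitude),
               bias_chr = runif(n, -cfg$bias_amplitude, cfg$bias_amplitude),
               sig_ctx = runif(n, cfg$sigma_base - cfg$sigma_amplitude,
                               cfg$sigma_base + cfg$sigma_amplitude),
               sig_chr = runif(n, cfg$sigma_base - cfg$sigma_amplitude,
                               cfg$sigma_base + cfg$sigma_amplitude))
        })
        latent <- draws$latent
        bias_ctx <- draws$bias_ctx
        bias_chr <- draws$bias_chr
        sig <- if (cfg$sigma_schedule == "constant") {
          list(ctx = rep(cfg$sigma_base, n), chr = rep(cfg$sigma_base, n))
        } else {
          list(ctx = draws$sig_ctx, chr = draws$sig_chr)
        }
      }
      cues <- generate_cue_channels(latent, sig$ctx, sig$chr,
                                    bias_ctx, bias_chr,
                                    n_observers = cfg$n_observers,
                                    seed = derive_seed(sv, "cues"))
      gt <- generate_ground_truth(cues$mu_ctx, cues$mu_chr,
                                  sig$ctx, sig$chr,
                                  strategy = cfg$generating_strategy,
                                  noise_sd = cfg$observer_noise_sd,
                                  n_observers = cfg$n_observers,
                                  p_switch = cfg$p_switch,
                                  seed = derive_seed(sv, "gt"),
                                  ctx_ratings = cues$ctx,
                                  chr_ratings = cues$chr,
                                  gt_from = cfg$gt_from %||% "own_ratings",
                                  gt_noise = cfg$gt_noise %||% "fixed")
      list(latent = latent, mu_ctx = cues$mu_ctx, mu_chr = cues$mu_chr,
           sd_ctx = sig$ctx, sd_chr = sig$chr,
           ratings = list(context_only = cues$ctx,
                          character_only = cues$chr,
                          ground_truth = gt$gt),
           gt_strategies = gt$strategies)
    })
    videos[[v]] <- list(times = times, dims = per_dim)
  }
  structure(
    list(config = cfg, dt_s = cfg$dt_s,
         observers = sprintf("obs%03d", seq_len(cfg$n_observers)),
         videos = videos),
    class = "cue_cohort"
  )
}

#' @export
print.cue_cohort <- function(x, ...) {
  cat(sprintf(paste0("<cue_cohort> %d video(s) x %d observers/condition, ",
                     "%s mode, generator: %s\n"),
              length(x$videos), length(x$observers), x$config$mode,
              paste(unique(x$config$generating_strategy), collapse = "+")))
  invisible(x)
}

#' @export
as_rating_table.cue_cohort <- function(x) {
  parts <- list()
  i <- 1L
  for (v in names(x$videos)) {
    vid <- x$videos[[v]]
    n_t <- length(vid$times)
    for (cond in RATING_CONDITIONS) {
      val <- vid$dims$valence$ratings[[cond]]
      aro <- vid$dims$arousal$ratings[[cond]]
      parts[[i]] <- data.frame(
        observer_id = rep(x$observers, each = n_t),
        video_id = v,
        condition = cond,
        time_s = rep(vid$times, times = ncol(val)),
        valence = as.vector(val),
        arousal = as.vector(aro),
        stringsAsFactors = FALSE)
      i <- i + 1L
    }
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("rating_table", "data.frame")
  out
}

#' Reassemble a cue cohort from a long rating table
#'
#' Inverse of [as_rating_table()] for balanced tables: every
#' video/condition must have the same time grid across its observers.
#' Observer ids are shared across conditions in within-subject designs;
#' between-subject designs may use disjoint pools (the group-level
#' analysis never matches observers across conditions).
#'
#' @param df A `rating_table` (or path handled by [read_ratings()]).
#' @return A `cue_cohort` with `ratings` matrices only (no generator
#'   metadata).
#' @export
as_cohort <- function(df) {
  if (inherits(df, "cue_cohort")) return(df)
  if (is.character(df)) df <- read_ratings(df)
  df <- as_rating_table(df)
  videos <- list()
  base_ids <- NULL
  for (v in sort(unique(df$video_id))) {
    dv <- df[df$video_id == v, ]
    times <- sort(unique(dv$time_s))
    dims <- list()
    for (d in c("valence", "arousal")) {
      ratings <- list()
      for (cond in RATING_CONDITIONS) {
        dc <- dv[dv$condition == cond, ]
        if (!nrow(dc)) stopf("video %s is missing condition %s", v, cond)
        obs <- sort(unique(dc$observer_id))
        dc <- dc[order(dc$observer_id, dc$time_s), ]
        if (nrow(dc) != length(obs) * length(times))
          stopf("video %s / %s is not on a balanced grid", v, cond)
        mat <- matrix(dc[[d]], nrow = length(times))
        colnames(mat) <- obs
        ratings[[cond]] <- mat
      }
      dims[[d]] <- list(ratings = ratings)
    }
    videos[[v]] <- list(times = times, dims = dims)
    base_ids <- union(
      base_ids, colnames(videos[[v]]$dims$valence$ratings$ground_truth))
  }
  dt <- unique(round(diff(videos[[1]]$times), 9))
  structure(
    list(config = NULL, dt_s = if (length(dt) == 1) dt else NA_real_,
         observers = base_ids, videos = videos),
    class = "cue_cohort"
  )
}
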