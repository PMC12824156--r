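# Group-level and individual-level model comparison: metrics, bootstrap
# CIs, AIC-difference tests, PXP, and variance-prediction checks.

# Clamp across-observer sds to the floor; undefined sds (a single
# contributing observer) fall back to the floor, which makes the two cues
# equally reliable and Bayes coincide with Heuristic.
floor_sd <- function(x, sigma_floor = 1e-3) {
  x[is.na(x)] <- sigma_floor
  pmax(x, sigma_floor)
}

# Predictions of every requested model for one video/dimension, from
# per-timepoint cue means and across-observer sds. `mu_*` may be matrices
# (timepoints x observers) for the individual-level analysis, in which
# case sds are shared (group-level) per timepoint and each observer gets
# an independent seeded realization of the switch strategies.
predict_battery <- function(models, mu_ctx, mu_chr, sd_ctx, sd_chr,
                            seed, p_switch = 0.1, sigma_floor = 1e-3) {
  sd_ctx <- floor_sd(sd_ctx, sigma_floor)
  sd_chr <- floor_sd(sd_chr, sigma_floor)
  as_mat <- is.matrix(mu_ctx)
  n_t <- if (as_mat) nrow(mu_ctx) else length(mu_ctx)
  n_o <- if (as_mat) ncol(mu_ctx) else 1L
  w_bayes <- (1 / sd_ctx^2) / (1 / sd_ctx^2 + 1 / sd_chr^2)
  sel_ctx <- sd_ctx <= sd_chr
  out <- vector("list", length(models))
  for (i in seq_along(models)) {
    m <- models[i]
    pred <- switch(m,
      bayes = mu_ctx * w_bayes + mu_chr * (1 - w_bayes),
      heuristic = (mu_ctx + mu_chr) / 2,
      context75 = 0.75 * mu_ctx + 0.25 * mu_chr,
      character75 = 0.25 * mu_ctx + 0.75 * mu_chr,
      all_in = {
        p <- mu_ctx
        if (as_mat) p[!sel_ctx, ] <- mu_chr[!sel_ctx, ]
        else p[!sel_ctx] <- mu_chr[!sel_ctx]
        p
      },
      random_switch = {
        z <- withr::with_seed(derive_seed(seed, "rs", i),
                              matrix(runif(n_t * n_o) < 0.5, n_t))
        if (!as_mat) z <- z[, 1]
        ifelse(z, mu_ctx, mu_chr)
      },
      correlated_switch = {
        z <- withr::with_seed(derive_seed(seed, "cs", i), {
          z1 <- runif(n_o) < 0.5
          flips <- matrix(runif((n_t - 1) * n_o) < p_switch, n_t - 1)
          st <- rbind(as.integer(z1),
                      matrix(as.integer(flips), n_t - 1))
          apply(st, 2, cumsum) %% 2 == 1
        })
        if (!as_mat) z <- z[, 1]
        ifelse(z, mu_ctx, mu_chr)
      },
      stopf("unknown model '%s'", m))
    out[[i]] <- pred
  }
  names(out) <- make.unique(models)
  out
}

# Per-timepoint Bayesian posterior variance via grid + Monte Carlo,
# chunked by timepoint.
bayes_variance_mc_series <- function(mu_ctx, sd_ctx, mu_chr, sd_chr,
                                     grid, n_samples, seed) {
  ctx <- build_gaussian_cue(mu_ctx, floor_sd(sd_ctx), "context")
  chr <- build_gaussian_cue(mu_chr, floor_sd(sd_chr), "character")
  post <- bayes_integrate(ctx, chr, grid)$posterior
  vapply(seq_len(ncol(post)), function(t) {
    bayes_predicted_variance_mc(post[, t], grid, n_samples = n_samples,
                                seed = derive_seed(seed, "vmc", t))
  }, numeric(1))
}

#' Compare predicted and observed rating variance
#'
#' Scores the Bayes and Heuristic variance predictions against the
#' ground-truth across-observer rating variance with Pearson r and RMSE.
#' The Heuristic prediction is the mean of the two cue variances; the
#' Bayes prediction is the Monte-Carlo variance of draws from the
#' integrated posterior.
#'
#' @param bayes_var,heuristic_var,ground_truth_var Aligned per-trial or
#'   per-timepoint variance vectors.
#' @return Data frame with one row per model: `model`, `pearson_r`,
#'   `rmse`.
#' @export
variance_prediction_check <- function(bayes_var, heuristic_var,
                                      ground_truth_var) {
  data.frame(
    model = c("bayes", "heuristic"),
    pearson_r = c(pearson_r(bayes_var, ground_truth_var),
                  pearson_r(heuristic_var, ground_truth_var)),
    rmse = c(rmse(bayes_var, ground_truth_var),
             rmse(heuristic_var, ground_truth_var)),
    stringsAsFactors = FALSE)
}

#' Group-level model comparison
#'
#' The consensus analysis: for each video and affect dimension, the
#' across-observer mean and sd of the context-only and character-only
#' ratings define the cue distributions; each strategy predicts the
#' consensus ground-truth trajectory; predictions are pooled over videos
#' within each dimension and scored with Pearson r, RMSE and AIC, then the
#' two dimensions are averaged (per-dimension values are retained).
#' Bootstrap CIs resample pooled trials/timepoints.
#'
#' @param data A `cue_cohort`, `rating_table`, data frame, or CSV path.
#' @param models Character vector of strategy names (duplicates allowed).
#' @param n_boot Bootstrap iterations for the CIs (0 disables).
#' @param seed Integer seed governing switch realizations, bootstrap and
#'   the variance-check Monte Carlo.
#' @param k_params Named AIC parameter counts, see [default_k_params()].
#' @param p_switch Switch probability for `correlated_switch`.
#' @param variance_check If TRUE, also score Bayes (Monte Carlo,
#'   `n_var_samples` draws per timepoint) and Heuristic variance
#'   predictions against the ground-truth rating variance.
#' @param n_var_samples Posterior draws per timepoint for the Bayes
#'   variance prediction.
#' @param grid Affect grid used for the variance-check posterior.
#' @param sigma_floor Floor for across-observer sds.
#' @return A `comparison_report`.
#' @export
run_group_level <- function(data, models = MODEL_NAMES, n_boot = 5000,
                            seed = 1L, k_params = default_k_params(),
                            p_switch = 0.1, variance_check = FALSE,
                            n_var_samples = 1000, grid = affect_grid(),
                            sigma_floor = 1e-3) {
  cohort <- as_cohort(data)
  dims <- c("valence", "arousal")
  model_ids <- make.unique(models)
  preds <- list(valence = NULL, arousal = NULL)
  targets <- list(valence = NULL, arousal = NULL)
  varchk <- list()
  for (d in dims) {
    pred_parts <- list()
    targ_parts <- list()
    for (v in names(cohort$videos)) {
      r <- cohort$videos[[v]]$dims[[d]]$ratings
      mu_c <- rowMeans(r$context_only)
      mu_f <- rowMeans(r$character_only)
      sd_c <- row_sds(r$context_only)
      sd_f <- row_sds(r$character_only)
      target <- rowMeans(r$ground_truth)
      pv <- predict_battery(models, mu_c, mu_f, sd_c, sd_f,
                            seed = derive_seed(seed, "fit", v, d),
                            p_switch = p_switch,
                            sigma_floor = sigma_floor)
      pred_parts[[v]] <- do.call(cbind, pv)
      targ_parts[[v]] <- target
      if (variance_check && ncol(r$ground_truth) >= 2) {
        bv <- bayes_variance_mc_series(mu_c, sd_c, mu_f, sd_f, grid,
                                       n_var_samples,
                                       derive_seed(seed, "var", v, d))
        hv <- heuristic_variance(floor_sd(sd_c, sigma_floor)^2,
                                 floor_sd(sd_f, sigma_floor)^2)
        varchk[[paste(v, d)]] <-
          cbind(bayes = bv, heuristic = hv,
                truth = row_sds(r$ground_truth)^2)
      }
    }
    preds[[d]] <- do.call(rbind, pred_parts)
    targets[[d]] <- do.call(c, targ_parts)
  }
  per_dim <- lapply(setNames(dims, dims), function(d) {
    do.call(rbind, lapply(seq_along(models), function(i) {
      fit_metrics(preds[[d]][, i], targets[[d]],
                  k = k_params[[models[i]]], model = model_ids[i])
    }))
  })
  metrics <- average_dim_metrics(per_dim, model_ids)
  ci <- NULL
  if (n_boot > 0) {
    ci <- bootstrap_group_metrics(preds, targets, models, model_ids,
                                  k_params, n_boot,
                                  derive_seed(seed, "boot"))
  }
  vc <- NULL
  if (length(varchk)) {
    allv <- do.call(rbind, varchk)
    vc <- variance_prediction_check(allv[, "bayes"], allv[, "heuristic"],
                                    allv[, "truth"])
  }
  new_comparison_report(
    level = "group", models = model_ids, metrics = metrics,
    per_dimension = per_dim, ci = ci, variance_check = vc,
    winner = metrics$model[which.min(metrics$aic)],
    config = list(seed = seed, n_boot = n_boot, k_params = k_params,
                  p_switch = p_switch, n_videos = length(cohort$videos)))
}

average_dim_metrics <- function(per_dim, model_ids) {
  out <- data.frame(model = model_ids, stringsAsFactors = FALSE)
  for (col in c("pearson_r", "rmse", "aic")) {
    vals <- sapply(per_dim, function(m) m[[col]])
    vals <- matrix(vals, nrow = length(model_ids))
    out[[col]] <- rowMeans(vals)
    for (d in names(per_dim)) out[[paste(col, d, sep = "_")]] <-
      per_dim[[d]][[col]]
  }
  out
}

bootstrap_group_metrics <- function(preds, targets, models, model_ids,
                                    k_params, n_boot, seed) {
  dims <- names(preds)
  n_models <- length(models)
  draw <- function() {
    res <- matrix(0, n_models, 3)
    for (d in dims) {
      n <- length(targets[[d]])
      idx <- sample.int(n, n, replace = TRUE)
      tg <- targets[[d]][idx]
      for (i in seq_len(n_models)) {
        p <- preds[[d]][idx, i]
        sse <- sum((p - tg)^2)
        res[i, ] <- res[i, ] +
          c(if (stats::sd(p) == 0 || stats::sd(tg) == 0) NA_real_
            else stats::cor(p, tg),
            sqrt(sse / n),
            aic(sse, n, k_params[[models[i]]]))
      }
    }
    res / length(dims)
  }
  boots <- withr::with_seed(seed, {
    replicate(n_boot, draw())
  })
  ci <- expand.grid(model = model_ids,
                    metric = c("pearson_r", "rmse", "aic"),
                    stringsAsFactors = FALSE)
  ci$lower <- NA_real_
  ci$upper <- NA_real_
  for (i in seq_len(n_models)) {
    for (j in 1:3) {
      q <- stats::quantile(boots[i, j, ], c(0.025, 0.975), names = FALSE,
                           na.rm = TRUE)
      row <- which(ci$model == model_ids[i])[j]
      ci$lower[row] <- q[1]
      ci$upper[row] <- q[2]
    }
  }
  ci
}

#' Individual-level model comparison
#'
#' The within-observer analysis: each observer's own context-only and
#' character-only ratings provide the cue means, combined with the
#' group-level per-timepoint across-observer sds, to predict that
#' observer's own ground-truth ratings. Per-observer Pearson r, RMSE and
#' AIC are pooled over videos within each dimension and averaged across
#' dimensions. The report records each observer's winning (lowest-AIC)
#' model, AIC-difference distributions of Bayes against every opponent
#' with the chi-squared sign test and a paired test, protected exceedance
#' probabilities over the battery, and bootstrap CIs over observers.
#'
#' @inheritParams run_group_level
#' @param paired_method `"t_test"` or `"wilcoxon"` for the pairwise AIC
#'   comparisons.
#' @param pxp Compute protected exceedance probabilities (needs >= 2
#'   observers).
#' @param n_dirichlet_samples Monte-Carlo samples for the PXP.
#' @return A `comparison_report` with `per_observer`, `winners`,
#'   `aic_diff_tests` and `pxp` components.
#' @export
run_individual_level <- function(data, models = MODEL_NAMES, n_boot = 5000,
                                 seed = 1L, k_params = default_k_params(),
                                 p_switch = 0.1,
                                 paired_method = c("t_test", "wilcoxon"),
                                 pxp = TRUE, n_dirichlet_samples = 1e5,
                                 sigma_floor = 1e-3) {
  paired_method <- match.arg(paired_method)
  cohort <- as_cohort(data)
  check_within_subject(cohort)
  dims <- c("valence", "arousal")
  model_ids <- make.unique(models)
  n_m <- length(models)
  n_o <- length(cohort$observers)
  acc <- list()
  for (d in dims) {
    sse <- matrix(0, n_o, n_m)
    sp <- spp <- spt <- matrix(0, n_o, n_m)
    st <- stt <- rep(0, n_o)
    n_tot <- 0L
    for (v in names(cohort$videos)) {
      r <- cohort$videos[[v]]$dims[[d]]$ratings
      sd_c <- row_sds(r$context_only)
      sd_f <- row_sds(r$character_only)
      gt <- r$ground_truth
      pv <- predict_battery(models, r$context_only, r$character_only,
                            sd_c, sd_f,
                            seed = derive_seed(seed, "ind", v, d),
                            p_switch = p_switch,
                            sigma_floor = sigma_floor)
      for (i in seq_len(n_m)) {
        p <- pv[[i]]
        diffs <- p - gt
        sse[, i] <- sse[, i] + colSums(diffs^2)
        sp[, i] <- sp[, i] + colSums(p)
        spp[, i] <- spp[, i] + colSums(p^2)
        spt[, i] <- spt[, i] + colSums(p * gt)
      }
      st <- st + colSums(gt)
      stt <- stt + colSums(gt^2)
      n_tot <- n_tot + nrow(gt)
    }
    denom_t <- stt - st^2 / n_tot
    r_mat <- (spt - sp * st / n_tot) /
      sqrt(pmax(spp - sp^2 / n_tot, 0) * denom_t)
    aic_mat <- matrix(NA_real_, n_o, n_m)
    for (i in seq_len(n_m)) {
      aic_mat[, i] <- vapply(sse[, i], aic, numeric(1), n = n_tot,
                             k = k_params[[models[i]]])
    }
    acc[[d]] <- list(r = r_mat, rmse = sqrt(sse / n_tot), aic = aic_mat)
  }
  r_avg <- (acc$valence$r + acc$arousal$r) / 2
  rmse_avg <- (acc$valence$rmse + acc$arousal$rmse) / 2
  aic_avg <- (acc$valence$aic + acc$arousal$aic) / 2
  dimnames(aic_avg) <- list(cohort$observers, model_ids)
  per_observer <- data.frame(
    observer_id = rep(cohort$observers, times = n_m),
    model = rep(model_ids, each = n_o),
    pearson_r = as.vector(r_avg),
    rmse = as.vector(rmse_avg),
    aic = as.vector(aic_avg),
    stringsAsFactors = FALSE)
  metrics <- data.frame(model = model_ids,
                        pearson_r = colMeans(r_avg),
                        rmse = colMeans(rmse_avg),
                        aic = colMeans(aic_avg),
                        stringsAsFactors = FALSE)
  winners <- model_ids[apply(aic_avg, 1, which.min)]
  names(winners) <- cohort$observers
  single <- n_o < 2L
  ci <- NULL
  aic_diff_tests <- NULL
  pxp_res <- NULL
  if (!single && n_boot > 0) {
    ci <- expand.grid(model = model_ids,
                      metric = c("pearson_r", "rmse", "aic"),
                      stringsAsFactors = FALSE)
    ci$lower <- NA_real_
    ci$upper <- NA_real_
    mats <- list(pearson_r = r_avg, rmse = rmse_avg, aic = aic_avg)
    for (i in seq_len(n_m)) for (met in names(mats)) {
      b <- bootstrap_ci(mats[[met]][, i], statistic = mean,
                        n_boot = n_boot,
                        seed = derive_seed(seed, "bci", i, met))
      row <- which(ci$model == model_ids[i] & ci$metric == met)
      ci$lower[row] <- b$lower
      ci$upper[row] <- b$upper
    }
  }
  if (!single && "bayes" %in% models && n_m >= 2) {
    b_idx <- which(models == "bayes")[1]
    aic_diff_tests <- lapply(
      setNames(seq_len(n_m)[-b_idx], model_ids[-b_idx]), function(i) {
        diffs <- aic_avg[, b_idx] - aic_avg[, i]
        c(list(differences = unname(diffs)),
          aic_difference_test(diffs),
          paired = list(paired_compare(aic_avg[, b_idx], aic_avg[, i],
                                       method = paired_method)))
      })
  }
  if (!single && pxp && n_m >= 2) {
    pxp_res <- protected_exceedance_probability(
      -aic_avg / 2, n_dirichlet_samples = n_dirichlet_samples,
      seed = derive_seed(seed, "pxp"))
  }
  new_comparison_report(
    level = "individual", models = model_ids, metrics = metrics,
    per_dimension = NULL, ci = ci, variance_check = NULL,
    winner = metrics$model[which.min(metrics$aic)],
    per_observer = per_observer, winners = winners,
    aic_diff_tests = aic_diff_tests, pxp = pxp_res,
    single_observer = single,
    config = list(seed = seed, n_boot = n_boot, k_params = k_params,
                  p_switch = p_switch, paired_method = paired_method,
                  n_observers = n_o, n_videos = length(cohort$videos)))
}

check_within_subject <- function(cohort) {
  for (v in names(cohort$videos)) {
    r <- cohort$videos[[v]]$dims$valence$ratings
    cols <- lapply(r, colnames)
    same_n <- length(unique(vapply(r, ncol, integer(1)))) == 1L
    named <- !any(vapply(cols, is.null, logical(1)))
    if (!same_n ||
        (named && !(identical(cols[[1]], cols[[2]]) &&
                    identical(cols[[1]], cols[[3]]))))
      stopf(paste0("individual-level analysis requires every observer to ",
                   "have all three conditions (video %s)"), v)
  }
  invisible(cohort)
}

new_comparison_report <- function(...) {
  structure(list(...), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 4, ...) {
  cat(sprintf("<comparison_report> %s level, %d model(s)\n",
              x$level, length(x$models)))
  tab <- x$metrics[c("model", "pearson_r", "rmse", "aic")]
  print(format(tab, digits = digits), row.names = FALSE)
  cat(sprintf("AIC winner: %s\n", x$winner))
  if (!is.null(x$winners)) {
    counts <- sort(table(x$winners), decreasing = TRUE)
    cat("per-observer winners:",
        paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
        "\n")
  }
  if (!is.null(x$pxp)) {
    cat("PXP:", paste(sprintf("%s=%.3f", names(x$pxp$pxp), x$pxp$pxp),
                      collapse = ", "), "\n")
  }
  invisible(x)
}
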