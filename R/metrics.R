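# Fit metrics: Pearson r, RMSE, AIC.

#' Pearson correlation between prediction and target
#'
#' Standard product-moment correlation. Undefined (NA, with a warning)
#' when either input has zero variance.
#'
#' @param pred,target Equal-length numeric vectors (length >= 3).
#' @export
pearson_r <- function(pred, target) {
  if (length(pred) != length(target)) stopf("length mismatch")
  if (length(pred) < 3L) stopf("need at least 3 observations")
  if (stats::sd(pred) == 0 || stats::sd(target) == 0) {
    warning("zero-variance input: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(pred, target)
}

#' Root mean square error
#'
#' @param pred,target Equal-length numeric vectors.
#' @export
rmse <- function(pred, target) {
  if (length(pred) != length(target)) stopf("length mismatch")
  if (!length(pred)) stopf("empty input")
  sqrt(mean((pred - target)^2))
}

#' Akaike information criterion from a residual sum of squares
#'
#' For a Gaussian residual model with the residual variance profiled out,
#' \eqn{AIC = n \log(SSE / n) + 2k}. Lower is better. A zero SSE (perfect
#' fit) returns `-Inf` with a warning.
#'
#' @param sse Residual sum of squares (> 0).
#' @param n Number of observations (> k).
#' @param k Number of free parameters.
#' @export
aic <- function(sse, n, k) {
  if (n <= k) stopf("aic requires n > k")
  if (sse < 0) stopf("sse must be nonnegative")
  if (sse == 0) {
    warning("sse = 0: AIC is -Inf (perfect fit)", call. = FALSE)
    return(-Inf)
  }
  n * log(sse / n) + 2 * k
}

#' All three fit metrics for one model prediction
#'
#' @param pred,target Equal-length numeric vectors.
#' @param k Parameter count charged to the model in the AIC.
#' @param model Optional model label carried into the result.
#' @return A one-row data frame with `model`, `pearson_r`, `rmse`, `aic`,
#'   `sse`, `n_obs`, `k_params`.
#' @export
fit_metrics <- function(pred, target, k = 1L, model = NA_character_) {
  sse <- sum((pred - target)^2)
  data.frame(model = model,
             pearson_r = pearson_r(pred, target),
             rmse = rmse(pred, target),
             aic = aic(sse, length(pred), k),
             sse = sse, n_obs = length(pred), k_params = k,
             stringsAsFactors = FALSE)
}

# Default AIC parameter counts per strategy: the Bayes model is charged an
# extra parameter for its use of the two cue-reliability channels.
#' Default AIC parameter counts for the model battery
#' @return Named integer vector over the seven strategies.
#' @export
default_k_params <- function() {
  c(bayes = 2L, heuristic = 1L, context75 = 1L, character75 = 1L,
    all_in = 1L, random_switch = 1L, correlated_switch = 1L)
}
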