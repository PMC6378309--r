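#' Initial belief state for a trial
#'
#' Beliefs about both item values start from the same broad prior: mean 0,
#' variance `sigma0^2`. The state tracks the posterior mean and variance of
#' each item, the number of samples taken so far, and which item is
#' currently fixated (the fixated/non-fixated role assignment).
#'
#' @param params A [model_params()] object.
#' @param fixated Which item is fixated at trial start, `"left"` or
#'   `"right"`.
#' @return An object of class `ps_belief` with fields `mu_left`, `mu_right`,
#'   `var_left`, `var_right`, `t`, `fixated`.
#' @examples
#' belief_state(model_params(), "left")
#' @export
belief_state <- function(params, fixated = c("left", "right")) {
  stopifnot(inherits(params, "ps_params"))
  fixated <- match.arg(fixated)
  structure(list(mu_left = 0, mu_right = 0,
                 var_left = params$sigma0^2, var_right = params$sigma0^2,
                 t = 0L, fixated = fixated),
            class = "ps_belief")
}

check_belief <- function(state) {
  if (!inherits(state, "ps_belief")) stop("not a ps_belief", call. = FALSE)
  if (!(state$var_left > 0) || !(state$var_right > 0))
    stop("belief variances must be positive", call. = FALSE)
  invisible(state)
}

#' Draw noisy evidence samples from an item's value distribution
#'
#' The fixated item yields unbiased samples `N(v, sigma0^2)`. The
#' non-fixated item is perceived with distortion: its samples come from
#' `N(gamma * v, kappa * sigma0^2)`, i.e. mean-discounted by `gamma` and
#' variance-inflated by `kappa`.
#'
#' @param true_value The item's true value (its rating).
#' @param role `"fixated"` or `"non-fixated"`.
#' @param params A [model_params()] object.
#' @param n Number of draws.
#' @return Numeric vector of `n` evidence samples.
#' @examples
#' set.seed(1)
#' mean(draw_evidence_sample(7, "fixated", model_params(), n = 1e4))
#' @export
draw_evidence_sample <- function(true_value, role = c("fixated", "non-fixated"),
                                 params, n = 1L) {
  role <- match.arg(role)
  stopifnot(inherits(params, "ps_params"), is.finite(true_value))
  if (role == "fixated") {
    stats::rnorm(n, mean = true_value, sd = params$sigma0)
  } else {
    stats::rnorm(n, mean = params$gamma * true_value,
                 sd = sqrt(params$kappa) * params$sigma0)
  }
}

#' Conjugate posterior-mean update
#'
#' Precision-weighted average of the previous posterior mean and the new
#' sample: `(var_prev * x + sampling_var * mu_prev) / (var_prev +
#' sampling_var)`. Pass `sampling_var = sigma0^2` for the fixated item and
#' `kappa * sigma0^2` for the non-fixated item.
#'
#' @param mu_prev Previous posterior mean.
#' @param var_prev Previous posterior variance (> 0).
#' @param sample The new evidence sample.
#' @param sampling_var Variance of the sampling distribution (> 0).
#' @return The updated posterior mean.
#' @examples
#' posterior_mean_update(0, 16, 8, 16) # equal variances average to 4
#' @export
posterior_mean_update <- function(mu_prev, var_prev, sample, sampling_var) {
  if (any(var_prev <= 0)) stop("var_prev must be positive", call. = FALSE)
  if (any(sampling_var <= 0)) stop("sampling_var must be positive",
                                   call. = FALSE)
  (var_prev * sample + sampling_var * mu_prev) / (var_prev + sampling_var)
}

#' Posterior-variance update for the fixated item
#'
#' Standard conjugate shrinkage `var_prev * sigma0^2 / (var_prev +
#' sigma0^2)`; strictly smaller than `var_prev`.
#'
#' @param var_prev Previous posterior variance (> 0).
#' @param params A [model_params()] object.
#' @return The updated posterior variance.
#' @export
fixated_variance_update <- function(var_prev, params) {
  stopifnot(inherits(params, "ps_params"))
  if (any(var_prev <= 0)) stop("var_prev must be positive", call. = FALSE)
  s2 <- params$sigma0^2
  var_prev * s2 / (var_prev + s2)
}

#' Posterior-variance update for the non-fixated item
#'
#' Conjugate shrinkage against the inflated sampling variance
#' `kappa * sigma0^2`, then expanded by the forgetting factor `lam`:
#' `lam * var_prev * kappa * sigma0^2 / (var_prev + kappa * sigma0^2)`.
#' With `lam > 1` iteration converges to the positive fixed point
#' `(lam - 1) * kappa * sigma0^2`; with `lam = 1` it contracts to zero.
#'
#' @inheritParams fixated_variance_update
#' @return The updated posterior variance.
#' @export
nonfixated_variance_update <- function(var_prev, params) {
  stopifnot(inherits(params, "ps_params"))
  if (any(var_prev <= 0)) stop("var_prev must be positive", call. = FALSE)
  sn2 <- params$kappa * params$sigma0^2
  params$lam * var_prev * sn2 / (var_prev + sn2)
}

#' Confidence that the higher-rated belief is the better item
#'
#' Treats the two posteriors as independent normals and returns the
#' probability that the item with the higher posterior mean truly has the
#' higher value: `pnorm(|mu_f - mu_n| / sqrt(var_f + var_n))`. Always in
#' `[0.5, 1)`. The relative decision value `RDV = |mu_f - mu_n|` is
#' returned alongside.
#'
#' @param state A [belief_state()] object.
#' @return A list with elements `confidence` and `rdv`.
#' @examples
#' s <- belief_state(model_params(), "left")
#' choice_confidence(s)$confidence # 0.5 under the symmetric prior
#' @export
choice_confidence <- function(state) {
  check_belief(state)
  rdv <- abs(state$mu_left - state$mu_right)
  conf <- stats::pnorm(rdv / sqrt(state$var_left + state$var_right))
  list(confidence = conf, rdv = rdv)
}

#' Collapsing decision threshold
#'
#' Linear collapse `theta_t = 1 - delta * t`. Not floored: because
#' confidence never drops below 0.5, a decision is guaranteed once
#' `theta_t < 0.5`, bounding every trial at `floor(0.5 / delta) + 1`
#' samples.
#'
#' @param t Number of samples taken so far (non-negative integer).
#' @param params A [model_params()] object.
#' @return The threshold value.
#' @examples
#' decision_threshold(20, model_params()) # 0.9 at delta = 0.005
#' @export
decision_threshold <- function(t, params) {
  stopifnot(inherits(params, "ps_params"))
  if (any(t < 0) || any(t != floor(t))) stop("t must be a non-negative integer",
                                             call. = FALSE)
  1 - params$delta * t
}

#' Probability of switching fixation to the other item
#'
#' Logistic policy on the posterior uncertainty ratio:
#' `plogis(omega * (sd_nonfixated / sd_fixated) + omega0)`. The more
#' uncertain the non-fixated item relative to the fixated one, the more
#' likely a saccade toward it.
#'
#' @param sd_nonfixated Posterior standard deviation of the non-fixated
#'   item (> 0).
#' @param sd_fixated Posterior standard deviation of the fixated item
#'   (> 0).
#' @param params A [model_params()] object.
#' @return Switch probability in (0, 1).
#' @examples
#' switch_probability(2.6, 1, model_params()) # ratio at the logistic midpoint
#' @export
switch_probability <- function(sd_nonfixated, sd_fixated, params) {
  stopifnot(inherits(params, "ps_params"))
  if (any(sd_nonfixated <= 0) || any(sd_fixated <= 0))
    stop("standard deviations must be positive", call. = FALSE)
  stats::plogis(params$omega * (sd_nonfixated / sd_fixated) + params$omega0)
}

#' Draw per-sample durations
#'
#' Sampling takes time: each evidence sample consumes a duration drawn
#' uniformly between `sample_time_min_ms` and `sample_time_max_ms`.
#'
#' @param params A [model_params()] object.
#' @param n Number of draws.
#' @return Numeric vector of durations in milliseconds.
#' @export
draw_sample_duration <- function(params, n = 1L) {
  stopifnot(inherits(params, "ps_params"))
  stats::runif(n, params$sample_time_min_ms, params$sample_time_max_ms)
}
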