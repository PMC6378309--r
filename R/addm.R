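#' Parameters for the attentional drift-diffusion baseline
#'
#' A minimal aDDM used as a comparison baseline: a noisy accumulator whose
#' drift favours the fixated item, with the non-fixated item's value
#' discounted. The defaults were calibrated once so that mean reaction
#' time at an absolute rating difference of 2 roughly matches the
#' proactive-sampling simulator at its own defaults; they are a
#' qualitative baseline, not a fit to any dataset.
#'
#' @param drift_scale Drift per ms per rating unit of weighted value
#'   difference (> 0).
#' @param noise_sd Standard deviation of the Gaussian increment noise per
#'   integration step (> 0).
#' @param gamma_addm Discount on the non-fixated item's value, in
#'   `[0, 1]`.
#' @param bound Decision barrier magnitude; the accumulator starts at 0
#'   and chooses left/right on hitting `+bound`/`-bound`.
#' @param step_ms Integration step in ms (> 0).
#' @return An object of class `ps_addm_params`.
#' @export
addm_params <- function(drift_scale = 2e-4, noise_sd = 0.08,
                        gamma_addm = 0.3, bound = 1, step_ms = 10) {
  p <- list(drift_scale = drift_scale, noise_sd = noise_sd,
            gamma_addm = gamma_addm, bound = bound, step_ms = step_ms)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in names(p))
    if (!num1(p[[f]])) stop("invalid aDDM parameter '", f, "'", call. = FALSE)
  if (p$drift_scale <= 0 || p$noise_sd <= 0 || p$bound <= 0 || p$step_ms <= 0)
    stop("aDDM parameters must be positive", call. = FALSE)
  if (p$gamma_addm < 0 || p$gamma_addm > 1)
    stop("invalid aDDM parameter 'gamma_addm': must be in [0, 1]",
         call. = FALSE)
  structure(p, class = "ps_addm_params")
}

#' Simulate one aDDM trial on a fixation schedule
#'
#' The accumulator integrates `drift_scale * step_ms * (v_fix -
#' gamma_addm * v_nonfix)` toward the fixated item's bound plus Gaussian
#' noise per step, following the supplied fixation schedule (e.g.
#' harvested from proactive-sampler output). If no bound is hit before
#' the schedule runs out, fixations continue by alternating items while
#' recycling the schedule's durations.
#'
#' @param spec A [trial_spec()].
#' @param schedule Data frame with columns `item` (`"left"`/`"right"`)
#'   and `duration_ms`, in fixation order; non-empty.
#' @param params An [addm_params()] object.
#' @return A list with `choice` (`"left"`/`"right"`) and `rt_ms`.
#' @examples
#' set.seed(1)
#' sched <- data.frame(item = c("left", "right"), duration_ms = c(300, 400))
#' simulate_addm_trial(trial_spec(1, 8, 2), sched, addm_params())
#' @export
simulate_addm_trial <- function(spec, schedule, params = addm_params()) {
  stopifnot(inherits(spec, "ps_trial_spec"),
            inherits(params, "ps_addm_params"))
  if (!is.data.frame(schedule) || nrow(schedule) == 0L ||
      !all(c("item", "duration_ms") %in% names(schedule)))
    stop("schedule must be a non-empty data frame with item, duration_ms",
         call. = FALSE)
  if (!all(schedule$item %in% c("left", "right")))
    stop("schedule items must be 'left' or 'right'", call. = FALSE)

  e <- 0
  t_ms <- 0
  fix_i <- 0L
  n_sched <- nrow(schedule)
  cur_item <- NA_character_
  repeat {
    fix_i <- fix_i + 1L
    if (fix_i <= n_sched) {
      cur_item <- schedule$item[fix_i]
      dur <- schedule$duration_ms[fix_i]
    } else {
      # schedule exhausted: keep alternating, recycling the durations
      cur_item <- if (cur_item == "left") "right" else "left"
      dur <- schedule$duration_ms[(fix_i - 1L) %% n_sched + 1L]
    }
    k <- max(1L, ceiling(dur / params$step_ms))
    drift <- params$drift_scale * params$step_ms *
      (if (cur_item == "left")
         spec$v_left - params$gamma_addm * spec$v_right
       else
         -(spec$v_right - params$gamma_addm * spec$v_left))
    path <- e + cumsum(drift + stats::rnorm(k, 0, params$noise_sd))
    hit <- which(abs(path) >= params$bound)
    if (length(hit)) {
      j <- hit[1L]
      return(list(choice = if (path[j] > 0) "left" else "right",
                  rt_ms = t_ms + j * params$step_ms))
    }
    e <- path[k]
    t_ms <- t_ms + k * params$step_ms
    if (t_ms > 600000) stop("aDDM trial exceeded 10 minutes of model time",
                            call. = FALSE)
  }
}

#' Simulate an aDDM batch on harvested fixation schedules
#'
#' Runs [simulate_addm_trial()] for every trial, taking each trial's
#' fixation schedule from a fixation table in the package's CSV schema
#' (e.g. [fixations_frame()] output).
#'
#' @param trials Data frame with `trial_id`, `v_left`, `v_right`.
#' @param fixations Fixation table with `trial_id`, `fixation_index`,
#'   `item`, `duration_ms`.
#' @param params An [addm_params()] object.
#' @param seed Integer master seed.
#' @return Data frame with `trial_id`, `v_left`, `v_right`, `choice`,
#'   `rt_ms`.
#' @export
simulate_addm_batch <- function(trials, fixations, params = addm_params(),
                                seed) {
  if (missing(seed) || !is.finite(seed))
    stop("a master seed is required", call. = FALSE)
  if (nrow(trials) == 0L) stop("empty trial list", call. = FALSE)
  specs <- as_trial_specs(trials)
  choice <- character(length(specs))
  rt <- numeric(length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    sched <- fixations[fixations$trial_id == sp$trial_id, ]
    sched <- sched[order(sched$fixation_index), c("item", "duration_ms")]
    if (nrow(sched) == 0L)
      stop("no fixation schedule for trial_id ", sp$trial_id, call. = FALSE)
    set.seed(derive_seed(seed, i))
    res <- simulate_addm_trial(sp, sched, params)
    choice[i] <- res$choice
    rt[i] <- res$rt_ms
  }
  data.frame(trial_id = trials$trial_id, v_left = trials$v_left,
             v_right = trials$v_right, choice = choice, rt_ms = rt,
             stringsAsFactors = FALSE)
}

#' Compare psychometric curves of the two simulators
#'
#' Bins both models' choices by signed rating difference on a common
#' integer grid and reports the curves plus the largest absolute per-bin
#' gap between them (over bins populated in both).
#'
#' @param bayes_results A `ps_results` list (or `list(trials, fixations)`
#'   frames) from the proactive sampler.
#' @param addm_results Data frame from [simulate_addm_batch()].
#' @return A list with `bayes` and `addm` (`ps_curve`s on common bins)
#'   and `max_gap`.
#' @export
compare_choice_curves <- function(bayes_results, addm_results) {
  ch <- extract_choice_features(bayes_results)
  if (!all(c("v_left", "v_right", "choice") %in% names(addm_results)))
    stop("addm_results lacks required columns", call. = FALSE)
  da <- addm_results$v_left - addm_results$v_right
  lo <- max(min(ch$d_rating), min(da))
  hi <- min(max(ch$d_rating), max(da))
  if (lo > hi) stop("disjoint rating-difference support", call. = FALSE)
  breaks <- seq(floor(lo) - 0.5, ceiling(hi) + 0.5, by = 1)
  cb <- binned_proportion(ch$d_rating, ch$chose_left, breaks)
  ca <- binned_proportion(da, addm_results$choice == "left", breaks)
  both <- cb$n > 0 & ca$n > 0
  if (!any(both)) stop("disjoint rating-difference support", call. = FALSE)
  list(bayes = cb, addm = ca,
       max_gap = max(abs(cb$value[both] - ca$value[both])))
}
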