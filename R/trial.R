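#' Specify one choice trial
#'
#' A trial presents two items, identified only by their true values (the
#' participant's ratings). By design of the experiment, ratings are
#' non-negative: negatively rated items never enter the choice phase.
#'
#' @param trial_id Identifier (integer or character).
#' @param v_left,v_right True values of the left and right items (rating
#'   units, finite and >= 0).
#' @return An object of class `ps_trial_spec`.
#' @examples
#' trial_spec(1, 7, 3)
#' @export
trial_spec <- function(trial_id, v_left, v_right) {
  if (!is.finite(v_left) || !is.finite(v_right))
    stop("ratings must be finite", call. = FALSE)
  if (v_left < 0 || v_right < 0)
    stop("ratings must be non-negative (negatively rated items are excluded)",
         call. = FALSE)
  structure(list(trial_id = trial_id, v_left = v_left, v_right = v_right),
            class = "ps_trial_spec")
}

#' Draw the first fixation of a trial
#'
#' The initial fixation target is random with a leftward bias:
#' `p_first_left` (default 0.74) for the left item.
#'
#' @param params A [model_params()] object.
#' @return `"left"` or `"right"`.
#' @export
draw_initial_fixation <- function(params) {
  stopifnot(inherits(params, "ps_params"))
  if (stats::runif(1) < params$p_first_left) "left" else "right"
}

#' Advance a trial by one sample
#'
#' One pass through the model's four stages: draw one evidence sample from
#' each item according to its current role, update both posteriors,
#' increment the sample count, and compare confidence against the
#' collapsing threshold. If the threshold is exceeded the trial decides
#' for the higher-mean item (fair coin on an exact tie); otherwise a
#' switch of fixation is drawn from the uncertainty-ratio policy.
#'
#' @param state A [belief_state()]; must not already carry a decision.
#' @param spec A [trial_spec()].
#' @param params A [model_params()] object.
#' @param max_samples Termination guard: once `state$t` reaches this many
#'   samples the step decides for the higher-mean item regardless of
#'   confidence. Defaults to `floor(0.5 / delta) + 1`, which never binds
#'   (confidence >= 0.5 always exceeds the threshold by then); lower it
#'   only to study the sampling dynamics with the decision stage held off.
#' @return A list with `state` (updated; roles swapped on a switch),
#'   `event` (`"continue"`, `"switched"` or `"decided"`), `choice`
#'   (`"left"`/`"right"` when decided, else `NA`), `duration_ms` (the
#'   sample's duration draw) and `forced` (`TRUE` when the guard fired).
#' @examples
#' p <- model_params()
#' set.seed(1)
#' st <- belief_state(p, draw_initial_fixation(p))
#' step_trial(st, trial_spec(1, 8, 2), p)$event
#' @export
step_trial <- function(state, spec, params, max_samples = NULL) {
  check_belief(state)
  stopifnot(inherits(spec, "ps_trial_spec"), inherits(params, "ps_params"))
  if (!is.null(state$decided) && isTRUE(state$decided))
    stop("trial already decided; step_trial must not be called again",
         call. = FALSE)
  if (is.null(max_samples)) max_samples <- floor(0.5 / params$delta) + 1
  s0sq <- params$sigma0^2
  snsq <- params$kappa * s0sq

  fix_left <- state$fixated == "left"
  vf <- if (fix_left) spec$v_left else spec$v_right
  vn <- if (fix_left) spec$v_right else spec$v_left
  xf <- stats::rnorm(1, vf, params$sigma0)
  xn <- stats::rnorm(1, params$gamma * vn, sqrt(snsq))
  xL <- if (fix_left) xf else xn
  xR <- if (fix_left) xn else xf

  svL <- if (fix_left) s0sq else snsq
  svR <- if (fix_left) snsq else s0sq
  state$mu_left <- posterior_mean_update(state$mu_left, state$var_left, xL, svL)
  state$mu_right <- posterior_mean_update(state$mu_right, state$var_right,
                                          xR, svR)
  if (fix_left) {
    state$var_left <- fixated_variance_update(state$var_left, params)
    state$var_right <- nonfixated_variance_update(state$var_right, params)
  } else {
    state$var_right <- fixated_variance_update(state$var_right, params)
    state$var_left <- nonfixated_variance_update(state$var_left, params)
  }
  state$t <- state$t + 1L
  duration <- draw_sample_duration(params)

  conf <- choice_confidence(state)$confidence
  theta <- decision_threshold(state$t, params)

  decide <- conf > theta
  forced <- FALSE
  if (!decide && state$t >= max_samples) {
    decide <- TRUE
    forced <- TRUE
  }
  if (decide) {
    choice <- if (state$mu_left > state$mu_right) "left"
              else if (state$mu_right > state$mu_left) "right"
              else if (stats::runif(1) < 0.5) "left" else "right"
    state$decided <- TRUE
    return(list(state = state, event = "decided", choice = choice,
                duration_ms = duration, forced = forced,
                sample = c(x_left = xL, x_right = xR),
                confidence = conf, threshold = theta))
  }
  sd_f <- sqrt(if (fix_left) state$var_left else state$var_right)
  sd_n <- sqrt(if (fix_left) state$var_right else state$var_left)
  p_sw <- switch_probability(sd_n, sd_f, params)
  if (stats::runif(1) < p_sw) {
    state$fixated <- if (fix_left) "right" else "left"
    event <- "switched"
  } else {
    event <- "continue"
  }
  list(state = state, event = event, choice = NA_character_,
       duration_ms = duration, forced = FALSE,
       sample = c(x_left = xL, x_right = xR),
       confidence = conf, threshold = theta)
}

#' Simulate one complete trial
#'
#' Draws the initial fixation, then iterates the sample/update/decide/
#' switch loop until a decision fires. A fixation is a maximal run of
#' samples with a fixed role assignment; it ends on a switch or on the
#' decision (the final fixation is truncated by the decision). Reaction
#' time is the sum of all per-sample durations. Termination is guaranteed
#' within `floor(0.5 / delta) + 1` samples.
#'
#' @param spec A [trial_spec()].
#' @param params A [model_params()] object.
#' @param trace If `TRUE`, record a per-sample trace (sample values,
#'   posterior means and variances, threshold, confidence).
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure R via
#'   [step_trial()]). Both consume the RNG stream identically, so the same
#'   seed yields bit-identical trials.
#' @param max_samples Optional termination guard; see [step_trial()].
#' @return An object of class `ps_trial`: a list with `spec`, `choice`,
#'   `rt_ms`, `n_samples_total`, `fixations` (data frame: `index`, `item`,
#'   `n_samples`, `duration_ms`, `is_last`), `final_beliefs`, `forced`,
#'   and `trace` (data frame or `NULL`).
#' @examples
#' set.seed(7)
#' tr <- simulate_trial(trial_spec(1, 8, 3), model_params())
#' tr$choice; nrow(tr$fixations)
#' @export
simulate_trial <- function(spec, params, trace = FALSE,
                           engine = c("cpp", "r"), max_samples = NULL) {
  stopifnot(inherits(spec, "ps_trial_spec"), inherits(params, "ps_params"))
  engine <- match.arg(engine)
  if (is.null(max_samples)) max_samples <- floor(0.5 / params$delta) + 1
  max_samples <- as.integer(min(max_samples, .Machine$integer.max))
  if (max_samples < 1L) stop("max_samples must be >= 1", call. = FALSE)
  if (trace && max_samples > 1e6)
    stop("tracing is limited to max_samples <= 1e6", call. = FALSE)

  first <- draw_initial_fixation(params)
  if (engine == "cpp") {
    raw <- .sim_trial_cpp(spec$v_left, spec$v_right,
                          params$sigma0, params$delta, params$gamma,
                          params$kappa, params$lam, params$omega,
                          params$omega0,
                          params$sample_time_min_ms, params$sample_time_max_ms,
                          as.integer(first == "left"), max_samples, trace)
    items <- c("left", "right")[raw$fix_item]
    nfix <- length(items)
    fixations <- data.frame(
      index = seq_len(nfix),
      item = items,
      n_samples = raw$fix_n,
      duration_ms = raw$fix_dur,
      is_last = seq_len(nfix) == nfix,
      stringsAsFactors = FALSE)
    beliefs <- structure(list(mu_left = raw$mu_left, mu_right = raw$mu_right,
                              var_left = raw$var_left,
                              var_right = raw$var_right,
                              t = raw$n_samples_total,
                              fixated = items[nfix]),
                         class = "ps_belief")
    trace_df <- NULL
    if (trace) {
      m <- raw$trace[seq_len(raw$n_samples_total), , drop = FALSE]
      trace_df <- as.data.frame(m)
      names(trace_df) <- c("t", "fixated", "x_left", "x_right", "mu_left",
                           "mu_right", "var_left", "var_right", "threshold",
                           "confidence")
      trace_df$fixated <- c("left", "right")[trace_df$fixated]
    }
    return(structure(list(spec = spec,
                          choice = c("left", "right")[raw$choice],
                          rt_ms = raw$rt_ms,
                          n_samples_total = raw$n_samples_total,
                          fixations = fixations,
                          final_beliefs = beliefs,
                          forced = raw$forced,
                          trace = trace_df),
                     class = "ps_trial"))
  }

  # pure-R engine
  state <- belief_state(params, first)
  fix_item <- character()
  fix_n <- integer()
  fix_dur <- numeric()
  cur_n <- 0L
  cur_dur <- 0
  rt <- 0
  trace_rows <- if (trace) vector("list", max_samples) else NULL
  repeat {
    cur_fix <- state$fixated
    res <- step_trial(state, spec, params, max_samples = max_samples)
    state <- res$state
    cur_n <- cur_n + 1L
    cur_dur <- cur_dur + res$duration_ms
    rt <- rt + res$duration_ms
    if (trace) {
      trace_rows[[state$t]] <- data.frame(
        t = state$t, fixated = cur_fix,
        x_left = res$sample[["x_left"]], x_right = res$sample[["x_right"]],
        mu_left = state$mu_left, mu_right = state$mu_right,
        var_left = state$var_left, var_right = state$var_right,
        threshold = res$threshold, confidence = res$confidence,
        stringsAsFactors = FALSE)
    }
    if (res$event == "decided") {
      fix_item <- c(fix_item, cur_fix)
      fix_n <- c(fix_n, cur_n)
      fix_dur <- c(fix_dur, cur_dur)
      choice <- res$choice
      forced <- res$forced
      break
    }
    if (res$event == "switched") {
      fix_item <- c(fix_item, cur_fix)
      fix_n <- c(fix_n, cur_n)
      fix_dur <- c(fix_dur, cur_dur)
      cur_n <- 0L
      cur_dur <- 0
    }
  }
  nfix <- length(fix_item)
  fixations <- data.frame(index = seq_len(nfix), item = fix_item,
                          n_samples = fix_n, duration_ms = fix_dur,
                          is_last = seq_len(nfix) == nfix,
                          stringsAsFactors = FALSE)
  trace_df <- if (trace) do.call(rbind, trace_rows[seq_len(state$t)]) else NULL
  structure(list(spec = spec, choice = choice, rt_ms = rt,
                 n_samples_total = as.integer(state$t), fixations = fixations,
                 final_beliefs = state[c("mu_left", "mu_right", "var_left",
                                         "var_right", "t", "fixated")],
                 forced = forced, trace = trace_df),
            class = "ps_trial")
}

#' @export
print.ps_trial <- function(x, ...) {
  cat(sprintf("Trial %s: chose %s after %d samples (%.0f ms, %d fixations)\n",
              format(x$spec$trial_id), x$choice, x$n_samples_total, x$rt_ms,
              nrow(x$fixations)))
  invisible(x)
}

# Deterministic per-trial substream seed: a scrambled mix of the master
# seed and the trial's position, kept below 2^31 - 1. Exact in doubles.
derive_seed <- function(master, index) {
  m <- 2147483647
  s <- (abs(master) %% m) + 1
  s <- (s * 48271) %% m
  s <- (s + index) %% m
  s <- (s * 48271) %% m
  as.integer(s)
}

#' Simulate a batch of independent trials
#'
#' Each trial runs in its own RNG substream derived deterministically from
#' the master seed and the trial's position, so the same `(seed, trials,
#' params)` always reproduces the same results, trial by trial.
#'
#' @param trials A data frame with columns `trial_id`, `v_left`, `v_right`
#'   (e.g. from [build_trial_pairs()]), or a list of [trial_spec()]s.
#' @param params A [model_params()] object.
#' @param seed Integer master seed (mandatory).
#' @param trace Record per-sample traces (large; off by default).
#' @param engine Passed to [simulate_trial()].
#' @param max_samples Optional termination guard; see [step_trial()].
#' @return A list of `ps_trial` objects, classed `ps_results`.
#' @examples
#' set.seed(3)
#' trials <- build_trial_pairs(generate_item_ratings(10), 5)
#' res <- simulate_batch(trials, model_params(), seed = 11)
#' trials_frame(res)
#' @export
simulate_batch <- function(trials, params, seed, trace = FALSE,
                           engine = c("cpp", "r"), max_samples = NULL) {
  stopifnot(inherits(params, "ps_params"))
  engine <- match.arg(engine)
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("a master seed is required", call. = FALSE)
  specs <- as_trial_specs(trials)
  if (length(specs) == 0L) stop("empty trial list", call. = FALSE)
  out <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    set.seed(derive_seed(seed, i))
    out[[i]] <- simulate_trial(specs[[i]], params, trace = trace,
                               engine = engine, max_samples = max_samples)
  }
  structure(out, class = c("ps_results", "list"),
            seed = as.integer(seed))
}

as_trial_specs <- function(trials) {
  if (is.data.frame(trials)) {
    need <- c("trial_id", "v_left", "v_right")
    miss <- setdiff(need, names(trials))
    if (length(miss)) stop("trial table lacks column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    lapply(seq_len(nrow(trials)), function(i)
      trial_spec(trials$trial_id[i], trials$v_left[i], trials$v_right[i]))
  } else if (is.list(trials) &&
             all(vapply(trials, inherits, TRUE, "ps_trial_spec"))) {
    trials
  } else {
    stop("trials must be a data frame or a list of trial_spec objects",
         call. = FALSE)
  }
}

#' Trial-level and fixation-level data frames from simulation results
#'
#' `trials_frame()` returns one row per trial (`trial_id`, `v_left`,
#' `v_right`, `choice`, `rt_ms`, `n_fixations`, `n_samples_total`);
#' `fixations_frame()` one row per fixation (`trial_id`, `fixation_index`,
#' `item`, `n_samples`, `duration_ms`, `is_last`). These are the package's
#' CSV schemas.
#'
#' @param results A `ps_results` list (or plain list of `ps_trial`).
#' @return A data frame.
#' @export
trials_frame <- function(results) {
  check_results(results)
  data.frame(
    trial_id = vapply(results, function(r) as.integer(r$spec$trial_id), 1L),
    v_left = vapply(results, function(r) r$spec$v_left, 1),
    v_right = vapply(results, function(r) r$spec$v_right, 1),
    choice = vapply(results, function(r) r$choice, ""),
    rt_ms = vapply(results, function(r) r$rt_ms, 1),
    n_fixations = vapply(results, function(r) nrow(r$fixations), 1L),
    n_samples_total = vapply(results, function(r)
      as.integer(r$n_samples_total), 1L),
    stringsAsFactors = FALSE)
}

#' @rdname trials_frame
#' @export
fixations_frame <- function(results) {
  check_results(results)
  frames <- lapply(results, function(r) {
    f <- r$fixations
    data.frame(trial_id = as.integer(r$spec$trial_id),
               fixation_index = f$index, item = f$item,
               n_samples = f$n_samples, duration_ms = f$duration_ms,
               is_last = f$is_last, stringsAsFactors = FALSE)
  })
  do.call(rbind, frames)
}

check_results <- function(results) {
  if (!is.list(results) || length(results) == 0L ||
      !all(vapply(results, inherits, TRUE, "ps_trial")))
    stop("expected a non-empty list of ps_trial results", call. = FALSE)
  invisible(results)
}
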