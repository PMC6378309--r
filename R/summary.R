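#' Binned proportion and binned mean curves
#'
#' The common representation of every behavioral summary in the package:
#' an x variable is cut into half-open bins `[lo, hi)` (the last bin is
#' closed on the right) and a per-bin proportion or mean is computed with
#' its standard error. Empty bins keep their row with `value = NA`,
#' `se = NA` and `n = 0`; observations outside the bin range are dropped
#' and counted in the `n_dropped` attribute.
#'
#' @param x Numeric vector of bin variables.
#' @param outcome Logical vector (for `binned_proportion`) or numeric
#'   vector `y` (for `binned_mean`), same length as `x`.
#' @param breaks Strictly increasing numeric vector of bin edges
#'   (length >= 2).
#' @return A data frame of class `ps_curve` with columns `bin_label`,
#'   `lo`, `hi`, `mid`, `value`, `se`, `n`.
#' @examples
#' binned_proportion(c(1, 1, 2, 2), c(TRUE, FALSE, TRUE, TRUE), c(0, 1.5, 3))
#' @export
binned_proportion <- function(x, outcome, breaks) {
  check_bins(x, outcome, breaks)
  if (!is.logical(outcome)) stop("outcome must be logical", call. = FALSE)
  agg <- bin_aggregate(x, as.numeric(outcome), breaks)
  p <- agg$sum / agg$n
  se <- sqrt(p * (1 - p) / agg$n)
  make_curve(breaks, p, se, agg$n, agg$n_dropped)
}

#' @rdname binned_proportion
#' @export
binned_mean <- function(x, outcome, breaks) {
  check_bins(x, outcome, breaks)
  if (!is.numeric(outcome)) stop("outcome must be numeric", call. = FALSE)
  agg <- bin_aggregate(x, outcome, breaks, want_sd = TRUE)
  m <- agg$sum / agg$n
  se <- agg$sd / sqrt(agg$n)
  make_curve(breaks, m, se, agg$n, agg$n_dropped)
}

check_bins <- function(x, outcome, breaks) {
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  if (length(x) != length(outcome))
    stop("x and outcome lengths differ", call. = FALSE)
  if (!is.numeric(breaks) || length(breaks) < 2L || any(diff(breaks) <= 0))
    stop("breaks must be strictly increasing with length >= 2",
         call. = FALSE)
  invisible(NULL)
}

bin_aggregate <- function(x, y, breaks, want_sd = FALSE) {
  idx <- cut(x, breaks, right = FALSE, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(idx)
  nb <- length(breaks) - 1L
  n <- tabulate(idx[keep], nbins = nb)
  s <- vapply(seq_len(nb), function(b) sum(y[keep][idx[keep] == b]), 1)
  sdv <- if (want_sd)
    vapply(seq_len(nb), function(b) {
      yy <- y[keep][idx[keep] == b]
      if (length(yy) > 1L) stats::sd(yy) else NA_real_
    }, 1)
  else NULL
  list(n = n, sum = s, sd = sdv, n_dropped = sum(!keep))
}

make_curve <- function(breaks, value, se, n, n_dropped) {
  nb <- length(breaks) - 1L
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  value[n == 0L] <- NA_real_
  se[n == 0L] <- NA_real_
  out <- data.frame(
    bin_label = sprintf("[%g,%g%s", lo, hi,
                        c(rep(")", nb - 1L), "]")),
    lo = lo, hi = hi, mid = (lo + hi) / 2,
    value = value, se = se, n = n,
    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("ps_curve", "data.frame")
  out
}

#' @export
plot.ps_curve <- function(x, ..., xlab = "bin", ylab = "value") {
  ok <- x$n > 0
  graphics::plot(x$mid[ok], x$value[ok], type = "b", pch = 16,
                 xlab = xlab, ylab = ylab, ...)
  graphics::arrows(x$mid[ok], x$value[ok] - x$se[ok],
                   x$mid[ok], x$value[ok] + x$se[ok],
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

resolve_frames <- function(results) {
  if (is.list(results) && !is.null(results$trials) &&
      !is.null(results$fixations) && is.data.frame(results$trials)) {
    list(trials = results$trials, fixations = results$fixations)
  } else {
    check_results(results)
    list(trials = trials_frame(results), fixations = fixations_frame(results))
  }
}

#' Per-trial choice features
#'
#' One record per trial with the quantities behind the choice-pattern
#' panels: signed rating difference (left - right), whether the left item
#' was chosen, the total fixation-duration advantage of the left item
#' (ms), the side of the last fixation, the absolute rating difference,
#' reaction time, and fixation count.
#'
#' @param results A `ps_results` list, or a list with elements `trials`
#'   and `fixations` in the package's CSV schemas.
#' @return A data frame with columns `trial_id`, `d_rating`,
#'   `abs_d_rating`, `chose_left`, `dur_adv_left_ms`, `last_fix_item`,
#'   `rt_ms`, `n_fixations`.
#' @export
extract_choice_features <- function(results) {
  fr <- resolve_frames(results)
  tr <- fr$trials
  fx <- fr$fixations
  if (nrow(tr) == 0L) stop("no trials", call. = FALSE)
  if (!all(tr$trial_id %in% fx$trial_id))
    stop("trial without fixations in fixation table", call. = FALSE)
  left_dur <- tapply(fx$duration_ms * (fx$item == "left"), fx$trial_id, sum)
  right_dur <- tapply(fx$duration_ms * (fx$item == "right"), fx$trial_id, sum)
  last_item <- tapply(seq_len(nrow(fx)), fx$trial_id,
                      function(i) fx$item[i][which.max(fx$fixation_index[i])])
  key <- as.character(tr$trial_id)
  data.frame(
    trial_id = tr$trial_id,
    d_rating = tr$v_left - tr$v_right,
    abs_d_rating = abs(tr$v_left - tr$v_right),
    chose_left = tr$choice == "left",
    dur_adv_left_ms = as.numeric(left_dur[key] - right_dur[key]),
    last_fix_item = as.character(last_item[key]),
    rt_ms = tr$rt_ms,
    n_fixations = tr$n_fixations,
    stringsAsFactors = FALSE)
}

#' Per-fixation features
#'
#' One record per fixation, typed `first` (index 1, not trial-final),
#' `last` (trial-final; a single-fixation trial's only fixation is
#' `last`), or `middle`. Carries the fixated item's rating, the trial's
#' absolute rating difference and the trial's fixation count, so that
#' index analyses can exclude single-fixation trials.
#'
#' @inheritParams extract_choice_features
#' @return A data frame with columns `trial_id`, `index`, `item`, `type`,
#'   `duration_ms`, `n_samples`, `item_rating`, `abs_d_rating`,
#'   `n_fixations`.
#' @export
extract_fixation_features <- function(results) {
  fr <- resolve_frames(results)
  tr <- fr$trials
  fx <- fr$fixations
  if (nrow(fx) == 0L) stop("no fixations", call. = FALSE)
  key <- match(fx$trial_id, tr$trial_id)
  if (anyNA(key)) stop("fixation references unknown trial_id", call. = FALSE)
  type <- ifelse(fx$is_last, "last",
                 ifelse(fx$fixation_index == 1L, "first", "middle"))
  rating <- ifelse(fx$item == "left", tr$v_left[key], tr$v_right[key])
  data.frame(
    trial_id = fx$trial_id,
    index = fx$fixation_index,
    item = fx$item,
    type = type,
    duration_ms = fx$duration_ms,
    n_samples = fx$n_samples,
    item_rating = rating,
    abs_d_rating = abs(tr$v_left - tr$v_right)[key],
    n_fixations = tr$n_fixations[key],
    stringsAsFactors = FALSE)
}

#' Probability that a fixation ends the trial, by duration and index
#'
#' For each fixation ordinal (1..`max_index`) and duration bin, the
#' fraction of such fixations that were the trial's last. Under the full
#' model this proportion falls with duration at later indices — the
#' signature of the forgetting factor — whereas without belief-variance
#' expansion longer fixations only make a decision more likely.
#'
#' @inheritParams extract_choice_features
#' @param duration_bins Bin edges in ms (strictly increasing).
#' @param max_index Largest fixation ordinal reported.
#' @return Data frame with columns `index`, `bin_label`, `lo`, `hi`,
#'   `mid`, `prop_last`, `se`, `n`.
#' @export
last_fixation_surface <- function(results,
                                  duration_bins = seq(0, 3000, by = 500),
                                  max_index = 6L) {
  feats <- extract_fixation_features(results)
  if (!is.numeric(duration_bins) || length(duration_bins) < 2L ||
      any(diff(duration_bins) <= 0))
    stop("duration_bins must be strictly increasing", call. = FALSE)
  out <- lapply(seq_len(max_index), function(ix) {
    sub <- feats[feats$index == ix, ]
    if (nrow(sub) == 0L) return(NULL)
    cv <- binned_proportion(sub$duration_ms, sub$type == "last",
                            duration_bins)
    data.frame(index = ix, bin_label = cv$bin_label, lo = cv$lo, hi = cv$hi,
               mid = cv$mid, prop_last = cv$value, se = cv$se, n = cv$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Histogram of middle-fixation durations
#'
#' Counts of middle fixations (neither first nor last of their trial) in
#' fixed-width duration bins; the final bin aggregates everything longer
#' than `cap_ms`.
#'
#' @inheritParams extract_choice_features
#' @param bin_width_ms Bin width in ms (> 0).
#' @param cap_ms All durations above this go into the final overflow bin.
#' @return Data frame with columns `lo`, `hi` (`Inf` for the overflow
#'   bin), `count`.
#' @export
fixation_duration_histogram <- function(results, bin_width_ms = 100,
                                        cap_ms = 3000) {
  if (!is.numeric(bin_width_ms) || bin_width_ms <= 0)
    stop("bin_width_ms must be positive", call. = FALSE)
  feats <- extract_fixation_features(results)
  dur <- feats$duration_ms[feats$type == "middle"]
  edges <- c(seq(0, cap_ms, by = bin_width_ms), Inf)
  idx <- cut(dur, edges, right = FALSE, labels = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(lo = edges[-length(edges)], hi = edges[-1], count = counts)
}

#' Maximum-likelihood slopes on simulated records (convenience)
#'
#' `fit_choice_slope()` fits a logistic regression of choosing the left
#' item on the signed rating difference; `fit_rt_slope()` an ordinary
#' linear regression of reaction time on the absolute rating difference.
#' Both are descriptive conveniences for simulated data, not inferential
#' analyses.
#'
#' @param features Output of [extract_choice_features()].
#' @return Named numeric vector `c(intercept, slope)`.
#' @export
fit_choice_slope <- function(features) {
  fit <- stats::glm(chose_left ~ d_rating, data = features,
                    family = stats::binomial())
  stats::setNames(as.numeric(stats::coef(fit)), c("intercept", "slope"))
}

#' @rdname fit_choice_slope
#' @export
fit_rt_slope <- function(features) {
  fit <- stats::lm(rt_ms ~ abs_d_rating, data = features)
  stats::setNames(as.numeric(stats::coef(fit)), c("intercept", "slope"))
}

#' All standard summary panels in one call
#'
#' Computes every behavioral/oculomotor panel the package reports from a
#' set of simulated (or schema-conforming) trials: the psychometric curve,
#' duration-advantage curve, last-fixation-conditioned psychometric
#' curves, RT by difficulty, the middle-fixation duration histogram,
#' fixation counts by difficulty, middle-fixation duration by item
#' rating / difficulty / ordinal, mean duration by fixation type, and the
#' last-fixation surface.
#'
#' @inheritParams extract_choice_features
#' @return A named list of `ps_curve` data frames (and the histogram and
#'   surface data frames), with names `choice_vs_drating`,
#'   `choice_vs_duradv`, `choice_by_lastfix`, `rt_vs_absdiff`,
#'   `middur_hist`, `nfix_vs_absdiff`, `middur_vs_rating`,
#'   `middur_vs_absdiff`, `middur_vs_index`, `dur_by_type`,
#'   `last_surface`.
#' @export
summarize_results <- function(results) {
  ch <- extract_choice_features(results)
  fx <- extract_fixation_features(results)
  mid <- fx[fx$type == "middle", ]

  dr_breaks <- seq(-5.5, 5.5, by = 1)
  ad_breaks <- seq(-0.5, 5.5, by = 1)
  adv_lim <- max(200, 200 * ceiling(max(abs(ch$dur_adv_left_ms)) / 200))
  adv_breaks <- seq(-adv_lim, adv_lim, by = 200)

  by_last <- list(
    left = binned_proportion(ch$d_rating[ch$last_fix_item == "left"],
                             ch$chose_left[ch$last_fix_item == "left"],
                             dr_breaks),
    right = binned_proportion(ch$d_rating[ch$last_fix_item == "right"],
                              ch$chose_left[ch$last_fix_item == "right"],
                              dr_breaks))

  mid_index <- mid[mid$n_fixations > 1 & mid$index >= 2 & mid$index <= 5, ]
  middur_vs_index <- if (nrow(mid_index) > 0)
    binned_mean(mid_index$index, mid_index$duration_ms, seq(1.5, 5.5, 1))
  else NULL

  dur_by_type <- do.call(rbind, lapply(c("first", "middle", "last"),
    function(tp) {
      d <- fx$duration_ms[fx$type == tp]
      data.frame(type = tp,
                 mean_ms = if (length(d)) mean(d) else NA_real_,
                 se = if (length(d) > 1) stats::sd(d) / sqrt(length(d))
                      else NA_real_,
                 n = length(d), stringsAsFactors = FALSE)
    }))

  list(
    choice_vs_drating = binned_proportion(ch$d_rating, ch$chose_left,
                                          dr_breaks),
    choice_vs_duradv = binned_proportion(ch$dur_adv_left_ms, ch$chose_left,
                                         adv_breaks),
    choice_by_lastfix = by_last,
    rt_vs_absdiff = binned_mean(ch$abs_d_rating, ch$rt_ms, ad_breaks),
    middur_hist = fixation_duration_histogram(results),
    nfix_vs_absdiff = binned_mean(ch$abs_d_rating, ch$n_fixations, ad_breaks),
    middur_vs_rating = if (nrow(mid))
      binned_mean(mid$item_rating, mid$duration_ms, seq(-0.5, 10.5, 1))
      else NULL,
    middur_vs_absdiff = if (nrow(mid))
      binned_mean(mid$abs_d_rating, mid$duration_ms, ad_breaks) else NULL,
    middur_vs_index = middur_vs_index,
    dur_by_type = dur_by_type,
    last_surface = last_fixation_surface(results))
}
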