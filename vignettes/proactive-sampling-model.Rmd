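---
title: "The proactive sampling model: assumptions, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The proactive sampling model: assumptions, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prosamp)
```

## The model

`prosamp` simulates a two-alternative value-based choice as a loop of four
stages per evidence sample: *sampling*, *belief updating*, *decision*, and
*fixation switch*.

The observer never sees the true item values `v_left`, `v_right` (their own
ratings of the items). Each sample yields one noisy draw from **both**
items, with the currently fixated item read out faithfully,
`x_f ~ N(v_f, sigma0^2)`, and the non-fixated one mean-discounted and
variance-inflated, `x_n ~ N(gamma * v_n, kappa * sigma0^2)`. Beliefs about
each value are Gaussian, start at `N(0, sigma0^2)`, and update conjugately
(`posterior_mean_update()`, `fixated_variance_update()`). The non-fixated
item's posterior variance is additionally multiplied by a forgetting factor
`lam` each step (`nonfixated_variance_update()`); the competition between
this exponential expansion and the hyperbolic conjugate contraction gives
the non-fixated uncertainty a positive fixed point,
`(lam - 1) * kappa * sigma0^2` (3.2 rating-units² at the defaults), rather
than letting it vanish.

After each update the observer computes the probability that the item with
the higher posterior mean is truly the better one. Treating the two
posteriors as independent normals this is
`pnorm(|mu_f - mu_n| / sqrt(var_f + var_n))` (`choice_confidence()`), which
also exposes the relative decision value `|mu_f - mu_n|`. The model never
states this computation beyond "probability of a correct choice given the
value estimates"; the closed form is our choice, and a Monte-Carlo test
(paired draws from the two posteriors) guards it. A decision fires when
confidence strictly exceeds the collapsing threshold
`theta_t = 1 - delta * t` (`decision_threshold()`). The threshold is not
floored: since confidence is always at least 0.5, a decision necessarily
fires once `theta_t < 0.5`, so every trial halts within
`floor(0.5 / delta) + 1` samples (101 at the defaults) without any
auxiliary stopping rule. If no decision fires, a saccade is drawn with
probability `plogis(omega * sd_n / sd_f + omega0)`
(`switch_probability()`): gaze is re-aimed at the item one is currently
*more uncertain* about, with `omega0` absorbing the cost of repositioning.

## Parameters

| name | meaning | unit | default |
|---|---|---|---|
| `sigma0` | sampling noise sd; also the prior belief sd | rating units | 4 |
| `delta` | per-sample threshold collapse | — | 0.005 |
| `gamma` | mean discount for the non-fixated item | — | 0.1 |
| `kappa` | sampling-variance inflation, non-fixated | — | 2 |
| `lam` | belief-variance forgetting factor, non-fixated | — | 1.1 |
| `omega` | switch-policy slope on the sd ratio | — | 2.5 |
| `omega0` | switch-policy intercept (repositioning cost) | — | −6.5 |
| `p_first_left` | left bias of the first fixation | — | 0.74 |
| `sample_time_min_ms`, `sample_time_max_ms` | uniform per-sample duration | ms | 50, 150 |

The defaults are the model's reference simulation vector. `p_first_left`
encodes the strong empirical left-first bias of the task display, and the
50–150 ms sample duration reflects the approximate time scale on which
visual information reaches working memory. With the default `omega`,
`omega0` the switch policy crosses 50% at an uncertainty ratio of 2.6 and
sits at about 1.8% when both items are equally uncertain, so switches are
rare until the non-fixated item's uncertainty has grown substantially.

## Stage order and other ambiguities we had to fix

Several details are under-determined by the verbal model; the package's
choices are:

- **Both items are sampled and updated on every step**, regardless of
  fixation — fixation only assigns the fixated/non-fixated roles. This
  holds during the first fixation too, an acknowledged idealization (one
  cannot ruminate on an item not yet seen); we keep the model uniform.
- **Order within a step**: sample → update both posteriors → increment `t`
  → decision check → (only if no decision) switch draw. `t` counts all
  samples of the trial, and `theta_t` is evaluated at the post-increment
  `t`, so the first check happens at `theta_1 = 1 - delta`.
- The forgetting factor applies from the very first update onward; the
  prior itself is not expanded.
- **Ties** (`mu_left == mu_right` at decision time) are broken by a fair
  coin from the trial's own random stream. This is a measure-zero event
  under continuous sampling and only matters for degenerate configurations.
- **Switches are instantaneous** and carry beliefs over unchanged; the
  saccade cost lives in `omega0`, not in added time. A fixation's duration
  is exactly the sum of its samples' uniform durations, and the final
  fixation is truncated by the decision.
- **Termination guard**: `simulate_trial()`/`step_trial()` accept a
  `max_samples` cap defaulting to `floor(0.5/delta) + 1`. At that default
  it can never bind (the collapse guarantees an earlier decision); its
  purpose is to let users hold the decision stage off (near-zero `delta`)
  and study the switch process in isolation, which is also how the
  geometric within-fixation-count property is tested.

## Reproducibility and the two engines

The per-trial loop exists twice: a compiled Rcpp path (default) and a pure
R path built from `step_trial()`. Both consume R's RNG in the identical
order (two normal draws, the duration draw, then either a tie coin or a
switch draw), so the same seed gives bit-identical trials — a dual-route
check the test suite enforces on traces. Batches derive one substream seed
per trial position from the master seed via an integer scrambling map, so
`(seed, trials, params)` reproduces results trial-by-trial, and
`run_simulate()` writes byte-identical CSVs for identical configurations.
Durations are rounded to whole milliseconds only at serialization.

## The synthetic experiment

The generator emulates the food-rating design the model targets: ratings
live on a −10..10 scale, items rated below zero never enter the choice
phase (`generate_item_ratings()` redraws until `n_items` non-negative
ratings are retained, integer-uniform by default), and trials draw two
distinct items with uniformly random left/right placement
(`build_trial_pairs()`). The real rating distribution and pairing scheme of
the original experiment are not public; the integer-uniform source and
uniform pairing are our neutral stand-ins, and `rating_sampler` is a hook
for alternatives. Consequences worth keeping in mind: the synthetic
difficulty distribution is broad (absolute rating differences 0–10,
roughly triangular), there are no participant-level random effects, and
standard errors in the summary curves are trial-level, not
participant-level. Passing tests on synthetic data show the simulator and
pipeline are internally correct — not that the model fits any particular
empirical dataset.

## Summary statistics

Every behavioral panel is a binned curve: `binned_proportion()` /
`binned_mean()` cut an x variable into half-open bins `[lo, hi)` (last bin
closed), keep empty bins as `NA` with `n = 0`, and report binomial or
normal-theory standard errors. Default bin choices: integer rating
difference bins −5..5, absolute-difference bins 0..5, 200 ms bins for the
duration advantage, 100 ms histogram bins capped with a 3,000 ms overflow
bin, and fixation ordinals 2–5 for the index analysis (with
single-fixation trials excluded). Fixations are typed `first` / `middle` /
`last`, where a single-fixation trial's only fixation is `last` (it ends
the trial). Monotonicity checks in the tests compare consecutive populated
bins with a slack of one pooled standard error.

## The aDDM baseline

`simulate_addm_trial()` is a deliberately minimal attentional
drift-diffusion accumulator driven by externally supplied fixation
schedules (typically harvested from the proactive sampler's own output):
per `step_ms`, the accumulator moves by
`drift_scale * step_ms * (v_fix - gamma_addm * v_nonfix)` toward the
fixated item's bound plus Gaussian noise, and recycles the schedule by
alternation if no bound is hit. In the reduced proactive model
(`gamma = kappa = 1, lam = 1`) the posterior-mean difference is exactly the
cumulative sample-difference walk scaled by `1/(t+1)` — the algebraic bridge
between the Bayesian formulation and such accumulators, asserted on traces
in the tests. The aDDM defaults were calibrated once so that its mean RT at
an absolute rating difference of 2 roughly matches the proactive sampler at
its defaults; it is a qualitative comparison baseline, not a fitted model.

## Problem sizes

The simulator runs about 10,000 default trials in a few seconds (compiled
path). The test suite uses 10,000-trial batches for the behavioral-pattern
checks, 100,000 fixations for the geometric switch-count test, 10^6 paired
posterior draws per state for the confidence oracle, and 500-iteration
orbits for the variance fixed point; `scripts/acceptance.R` reports
quantities from a 10,000-trial run.

## Known limitations

- At the default parameters, trials are short (about 13 samples and 1.7
  fixations on average; over half are single-fixation trials, an
  overestimate the model family is known for). The decision stage
  therefore censors the fixation process noticeably: which fixations
  survive as "middle" depends on when the trial ends.
- Two classic qualitative patterns are *not* reproduced at the defaults
  because of that censoring, although the underlying switch mechanism
  produces them when the decision stage is held off: middle-fixation
  durations drift slightly *down*, not up, across fixation ordinals 2–5,
  and they acquire a negative rank correlation (≈ −0.3) with the fixated
  item's rating through trial-length selection, even though the switch
  hazard itself is value-independent (the variance recursions never see
  the sample values). The corresponding assertions in the acceptance suite
  are left failing rather than weakened; the remaining patterns —
  psychometric curve, RT and fixation counts by difficulty, last-fixation
  choice bias, duration-by-difficulty, first-vs-middle durations,
  right-skewed duration histogram, and the fall of P(fixation is last)
  with duration at later ordinals together with its disappearance at
  `lam = 1` — all reproduce.
- The discount `gamma = 0.1` is strong: the non-fixated belief is pulled
  most of the way to zero during long fixations, which makes the
  last-fixation choice bias at equal ratings close to saturation rather
  than the moderate empirical effect.
- No physiological latencies, no response deadlines, two items only, no
  parameter fitting: the package is a forward simulator.
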