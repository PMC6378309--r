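# Shared fixtures: hand-built trial results for the summary pipeline, and
# a compact batch for invariant sweeps.

make_trial <- function(trial_id, v_left, v_right, choice,
                       items, durations, n_samples = NULL) {
  stopifnot(length(items) == length(durations))
  if (is.null(n_samples)) n_samples <- rep(1L, length(items))
  nfix <- length(items)
  fixations <- data.frame(index = seq_len(nfix), item = items,
                          n_samples = n_samples, duration_ms = durations,
                          is_last = seq_len(nfix) == nfix,
                          stringsAsFactors = FALSE)
  structure(list(spec = trial_spec(trial_id, v_left, v_right),
                 choice = choice, rt_ms = sum(durations),
                 n_samples_total = sum(n_samples), fixations = fixations,
                 final_beliefs = NULL, forced = FALSE, trace = NULL),
            class = "ps_trial")
}

default_batch <- local({
  cache <- NULL
  function(n = 500, seed = 1) {
    key <- paste(n, seed)
    if (!is.null(cache) && identical(attr(cache, "key"), key)) return(cache)
    set.seed(seed)
    trials <- build_trial_pairs(generate_item_ratings(70), n)
    res <- simulate_batch(trials, model_params(), seed = seed)
    attr(res, "key") <- key
    cache <<- res
    res
  }
})

# monotonicity on curve bin means with 1 pooled-s.e. slack
curve_monotone <- function(cv, direction = c("up", "down"), min_n = 1) {
  direction <- match.arg(direction)
  ok <- which(cv$n >= min_n)
  v <- cv$value[ok]
  s <- cv$se[ok]
  d <- diff(v)
  slack <- sqrt(s[-1]^2 + s[-length(s)]^2)
  if (direction == "up") all(d >= -slack) else all(d <= slack)
}
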