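test_that("initial fixation honours the leftward bias", {
  set.seed(1)
  p1 <- model_params(p_first_left = 1)
  expect_true(all(replicate(50, draw_initial_fixation(p1)) == "left"))
  p <- model_params()
  frac <- mean(replicate(2e4, draw_initial_fixation(p)) == "left")
  expect_lt(abs(frac - 0.74), 3 * sqrt(0.74 * 0.26 / 2e4))
  p5 <- model_params(p_first_left = 0.5)
  frac5 <- mean(replicate(2e4, draw_initial_fixation(p5)) == "left")
  expect_lt(abs(frac5 - 0.5), 3 * sqrt(0.25 / 2e4))
})

test_that("compiled and pure-R trial engines are bit-identical", {
  p <- model_params()
  specs <- list(trial_spec(1, 7, 5), trial_spec(2, 0, 0), trial_spec(3, 10, 1),
                trial_spec(4, 4, 4))
  for (s in specs) for (seed in c(3, 17)) {
    set.seed(seed)
    a <- simulate_trial(s, p, trace = TRUE, engine = "cpp")
    set.seed(seed)
    b <- simulate_trial(s, p, trace = TRUE, engine = "r")
    expect_identical(a$choice, b$choice)
    expect_equal(a$rt_ms, b$rt_ms)
    expect_identical(a$n_samples_total, b$n_samples_total)
    expect_equal(a$fixations$duration_ms, b$fixations$duration_ms)
    expect_identical(a$fixations$item, b$fixations$item)
    expect_identical(a$fixations$n_samples, as.integer(b$fixations$n_samples))
    num <- setdiff(names(a$trace), "fixated")
    expect_equal(a$trace[num], b$trace[num], tolerance = 1e-12)
    expect_identical(a$trace$fixated, b$trace$fixated)
  }
})

test_that("step_trial refuses to run past a decision and obeys stage order", {
  p <- model_params()
  spec <- trial_spec(1, 9, 1)
  set.seed(2)
  st <- belief_state(p, "left")
  repeat {
    res <- step_trial(st, spec, p)
    st <- res$state
    if (res$event == "decided") break
  }
  expect_error(step_trial(st, spec, p), "already decided")

  # omega0 -> -Inf never switches: a trial is a single fixation
  pns <- model_params(omega0 = -1e6)
  set.seed(3)
  tr <- simulate_trial(spec, pns)
  expect_identical(nrow(tr$fixations), 1L)
})

test_that("trial results satisfy their structural invariants", {
  res <- default_batch(300, seed = 1)
  p <- model_params()
  bound <- floor(0.5 / p$delta) + 1
  for (r in res) {
    f <- r$fixations
    expect_true(all(f$n_samples >= 1))
    expect_true(all(f$duration_ms >= f$n_samples * p$sample_time_min_ms - 1e-9))
    expect_true(all(f$duration_ms <= f$n_samples * p$sample_time_max_ms + 1e-9))
    expect_equal(sum(f$duration_ms), r$rt_ms)
    expect_identical(sum(f$n_samples), r$n_samples_total)
    expect_lte(r$n_samples_total, bound)
    expect_identical(sum(f$is_last), 1L)
    expect_true(f$is_last[nrow(f)])
    if (nrow(f) > 1) expect_true(all(f$item[-1] != f$item[-nrow(f)]))
    expect_false(r$forced)
  }
})

test_that("an immediately collapsed threshold decides on the first sample", {
  p <- model_params(delta = 0.5)
  set.seed(4)
  res <- simulate_batch(data.frame(trial_id = 1:200, v_left = 7, v_right = 2),
                        p, seed = 9)
  expect_true(all(vapply(res, function(r) r$n_samples_total, 1L) == 1L))
  expect_true(all(vapply(res, function(r) nrow(r$fixations), 1L) == 1L))
})

test_that("fully symmetric trials split choices evenly", {
  p <- model_params(p_first_left = 0.5)
  res <- simulate_batch(data.frame(trial_id = 1:8000, v_left = 5, v_right = 5),
                        p, seed = 21)
  frac <- mean(vapply(res, function(r) r$choice, "") == "left")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 8000))
})

test_that("batches are deterministic and reordering-stable per trial", {
  trials <- data.frame(trial_id = 1:50,
                       v_left = rep(c(3, 8), 25), v_right = rep(c(6, 1), 25))
  p <- model_params()
  a <- simulate_batch(trials, p, seed = 123)
  b <- simulate_batch(trials, p, seed = 123)
  expect_identical(trials_frame(a), trials_frame(b))
  expect_identical(fixations_frame(a), fixations_frame(b))
  c2 <- simulate_batch(trials, p, seed = 124)
  expect_false(identical(trials_frame(a)$rt_ms, trials_frame(c2)$rt_ms))
  expect_error(simulate_batch(list(), p, seed = 1), "empty")
  expect_error(simulate_batch(trials, p), "seed")
})

test_that("easier decisions are faster", {
  p <- model_params()
  easy <- simulate_batch(data.frame(trial_id = 1:3000, v_left = 8, v_right = 3),
                         p, seed = 31)
  hard <- simulate_batch(data.frame(trial_id = 1:3000, v_left = 6, v_right = 5),
                         p, seed = 31)
  expect_lt(mean(trials_frame(easy)$rt_ms), mean(trials_frame(hard)$rt_ms))
})

test_that("mirroring the display mirrors the behavior distribution", {
  n <- 5000
  p <- model_params()
  pm <- model_params(p_first_left = 1 - p$p_first_left)
  orig <- simulate_batch(data.frame(trial_id = 1:n, v_left = 7, v_right = 4),
                         p, seed = 77)
  mirr <- simulate_batch(data.frame(trial_id = 1:n, v_left = 4, v_right = 7),
                         pm, seed = 78)
  to <- trials_frame(orig); tm <- trials_frame(mirr)
  p_left <- mean(to$choice == "left"); p_right_m <- mean(tm$choice == "right")
  se <- sqrt(p_left * (1 - p_left) / n + p_right_m * (1 - p_right_m) / n)
  expect_lt(abs(p_left - p_right_m), 4 * se)
  expect_lt(abs(mean(to$n_fixations) - mean(tm$n_fixations)),
            4 * sqrt(var(to$n_fixations) / n + var(tm$n_fixations) / n))
  fo <- fixations_frame(orig); fm <- fixations_frame(mirr)
  f1o <- mean(fo$item[fo$fixation_index == 1] == "left")
  f1m <- mean(fm$item[fm$fixation_index == 1] == "right")
  expect_lt(abs(f1o - f1m), 4 * sqrt(2 * 0.74 * 0.26 / n))
})

test_that("holding the decision off reveals the pure switch process", {
  # with a near-flat threshold and a cap, every trial runs to the cap and
  # within-fixation sample counts are censored only by the cap
  p <- model_params(delta = 1e-9)
  set.seed(6)
  res <- simulate_batch(data.frame(trial_id = 1:20, v_left = 5, v_right = 3),
                        p, seed = 13, max_samples = 2000)
  expect_true(all(vapply(res, function(r) r$n_samples_total, 1L) == 2000L))
  expect_true(all(vapply(res, function(r) r$forced, TRUE)))
})
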