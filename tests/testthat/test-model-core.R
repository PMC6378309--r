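test_that("parameter validation names the offending field", {
  expect_s3_class(model_params(), "ps_params")
  expect_error(model_params(gamma = 1.5), "gamma")
  expect_error(model_params(sigma0 = 0), "sigma0")
  expect_error(model_params(kappa = 0.5), "kappa")
  expect_error(model_params(lam = 0.9), "lam")
  expect_error(model_params(omega = -1), "omega")
  expect_error(model_params(p_first_left = 1.2), "p_first_left")
  expect_error(model_params(sample_time_min_ms = 200,
                            sample_time_max_ms = 100), "sample_time_max_ms")
})

test_that("evidence samples have the role-dependent mean and variance", {
  p <- model_params()
  set.seed(11)
  xf <- draw_evidence_sample(7, "fixated", p, n = 1e6)
  se_m <- p$sigma0 / sqrt(1e6)
  expect_lt(abs(mean(xf) - 7), 3 * se_m)
  # s.e. of the sample variance of a normal: sigma^2 * sqrt(2/(n-1))
  expect_lt(abs(var(xf) - 16), 3 * 16 * sqrt(2 / (1e6 - 1)))

  xn <- draw_evidence_sample(9, "non-fixated", model_params(gamma = 0), n = 1e5)
  expect_lt(abs(mean(xn)), 3 * sqrt(2) * p$sigma0 / sqrt(1e5))

  xn2 <- draw_evidence_sample(5, "non-fixated", p, n = 1e6)
  expect_lt(abs(mean(xn2) - 0.5), 3 * sqrt(32) / sqrt(1e6))
  expect_lt(abs(var(xn2) - 32), 3 * 32 * sqrt(2 / (1e6 - 1)))

  expect_error(draw_evidence_sample(5, "sideways", p))
})

test_that("posterior mean update matches the precision-weighted form", {
  expect_equal(posterior_mean_update(0, 16, 8, 16), 4)
  expect_equal(posterior_mean_update(3.2, 5, 3.2, 16), 3.2) # fixed point
  expect_error(posterior_mean_update(0, -1, 8, 16), "var_prev")
  expect_error(posterior_mean_update(0, 16, 8, 0), "sampling_var")
})

test_that("iterated updates of a continuously fixated item match closed forms", {
  p <- model_params()
  # samples [2, 6, 10]: running mean includes the zero-mean prior as one
  # pseudo-observation, so the final mean is 18/4 = 4.5
  mu <- 0; v <- p$sigma0^2
  for (x in c(2, 6, 10)) {
    mu <- posterior_mean_update(mu, v, x, p$sigma0^2)
    v <- fixated_variance_update(v, p)
  }
  expect_equal(mu, 4.5)
  expect_equal(v, 16 / 4)

  set.seed(2)
  xs <- rnorm(50, 5, 4)
  mu <- 0; v <- p$sigma0^2
  for (t in seq_along(xs)) {
    mu <- posterior_mean_update(mu, v, xs[t], p$sigma0^2)
    v <- fixated_variance_update(v, p)
    expect_equal(mu, sum(xs[seq_len(t)]) / (t + 1), tolerance = 1e-12)
    expect_equal(v, p$sigma0^2 / (t + 1), tolerance = 1e-12)
  }
})

test_that("fixated variance update is a strict contraction", {
  p <- model_params()
  expect_equal(fixated_variance_update(16, p), 8) # equal-variance halving
  for (v0 in c(0.01, 1, 16, 1000))
    expect_lt(fixated_variance_update(v0, p), v0)
  expect_error(fixated_variance_update(0, p), "var_prev")
})

test_that("non-fixated variance update has the forgetting fixed point", {
  p <- model_params()
  expect_equal(nonfixated_variance_update(16, p), 1.1 * 16 * 32 / 48)
  # lam = 1 reduces to plain shrinkage against kappa * sigma0^2
  p1 <- model_params(lam = 1)
  expect_equal(nonfixated_variance_update(7, p1), 7 * 32 / 39)
  # fixed point (lam - 1) * kappa * sigma0^2 = 3.2 from above and below
  for (s0 in c(0.5, 50)) {
    s <- s0
    for (i in 1:500) s <- nonfixated_variance_update(s, p)
    expect_equal(s, 3.2, tolerance = 1e-6)
  }
})

test_that("choice confidence is a calibrated posterior ordering probability", {
  p <- model_params()
  st <- belief_state(p, "left")
  expect_equal(choice_confidence(st)$confidence, 0.5)
  st$mu_left <- 3; st$mu_right <- 3
  expect_equal(choice_confidence(st)$confidence, 0.5)
  # |mu difference| equal to the sd of the difference gives pnorm(1)
  st$mu_left <- 2; st$mu_right <- 2 + sqrt(st$var_left + st$var_right)
  expect_equal(choice_confidence(st)$confidence, pnorm(1))
  expect_equal(choice_confidence(st)$rdv, sqrt(32))

  # invariance under swapping items and under common mean shifts
  st$mu_left <- 1.7; st$mu_right <- -2.2
  st$var_left <- 3; st$var_right <- 9
  sw <- st
  sw$mu_left <- st$mu_right; sw$mu_right <- st$mu_left
  sw$var_left <- st$var_right; sw$var_right <- st$var_left
  expect_equal(choice_confidence(sw)$confidence,
               choice_confidence(st)$confidence)
  sh <- st
  sh$mu_left <- st$mu_left + 100; sh$mu_right <- st$mu_right + 100
  expect_equal(choice_confidence(sh)$confidence,
               choice_confidence(st)$confidence)

  # strictly increasing in the mean separation
  confs <- sapply(seq(0, 5, by = 0.5), function(d) {
    s <- st; s$mu_left <- d; s$mu_right <- 0
    choice_confidence(s)$confidence
  })
  expect_true(all(diff(confs) > 0))
})

test_that("confidence agrees with Monte-Carlo posterior ordering frequency", {
  p <- model_params()
  set.seed(4)
  for (i in 1:5) {
    st <- belief_state(p, "left")
    st$mu_left <- runif(1, -5, 5); st$mu_right <- runif(1, -5, 5)
    st$var_left <- runif(1, 0.5, 20); st$var_right <- runif(1, 0.5, 20)
    n <- 2e5
    dl <- rnorm(n, st$mu_left, sqrt(st$var_left))
    dr <- rnorm(n, st$mu_right, sqrt(st$var_right))
    hi_wins <- if (st$mu_left >= st$mu_right) mean(dl > dr) else mean(dr > dl)
    cc <- choice_confidence(st)$confidence
    expect_lt(abs(cc - hi_wins), 3 * sqrt(cc * (1 - cc) / n))
  }
})

test_that("decision threshold collapses linearly and is not floored", {
  p <- model_params()
  expect_equal(decision_threshold(0, p), 1)
  expect_equal(decision_threshold(20, p), 0.9)
  expect_true(decision_threshold(100, p) >= 0.5)
  expect_true(decision_threshold(101, p) < 0.5)
  expect_lt(decision_threshold(300, p), 0)
  expect_error(decision_threshold(-1, p), "non-negative")
})

test_that("switch probability follows the uncertainty-ratio logistic", {
  p <- model_params()
  # midpoint at ratio -omega0/omega = 2.6
  expect_equal(switch_probability(2.6, 1, p), 0.5)
  expect_equal(switch_probability(1, 1, p), 1 / (1 + exp(4)))
  ratios <- seq(0.1, 5, by = 0.1)
  ps <- switch_probability(ratios, 1, p)
  expect_true(all(diff(ps) > 0))
  expect_true(all(ps > 0 & ps < 1))
  expect_error(switch_probability(-1, 1, p), "positive")
  expect_error(switch_probability(1, 0, p), "positive")
})

test_that("sample durations are uniform on the configured bounds", {
  p <- model_params()
  set.seed(5)
  d <- draw_sample_duration(p, n = 1e5)
  expect_true(all(d >= 50 & d <= 150))
  # uniform mean se: (b-a)/sqrt(12 n)
  expect_lt(abs(mean(d) - 100), 3 * 100 / sqrt(12 * 1e5))
  pd <- model_params(sample_time_min_ms = 100, sample_time_max_ms = 100)
  expect_true(all(draw_sample_duration(pd, n = 10) == 100))
})

test_that("config files round-trip and fall back to defaults", {
  tf <- tempfile(fileext = ".cfg")
  writeLines(c("# comment", "sigma0: 6", "delta = 0.01", "seed: 99"), tf)
  cfg <- read_config(tf)
  expect_equal(cfg$params$sigma0, 6)
  expect_equal(cfg$params$delta, 0.01)
  expect_equal(cfg$params$gamma, 0.1)   # default fallback
  expect_equal(cfg$seed, 99L)

  p <- model_params(kappa = 3, omega0 = -4)
  tf2 <- tempfile(fileext = ".cfg")
  write_config(p, tf2, seed = 7)
  cfg2 <- read_config(tf2)
  expect_equal(unclass(cfg2$params), unclass(p))
  expect_equal(cfg2$seed, 7L)

  tf3 <- tempfile()
  writeLines("sigma0: banana", tf3)
  expect_error(read_config(tf3), "non-numeric")
  writeLines("unknown_key: 1", tf3)
  expect_error(read_config(tf3), "unknown")
})
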