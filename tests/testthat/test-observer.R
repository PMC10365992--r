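test_that("Fisher information follows the power law", {
  pr <- orient_prior()
  # q = 0: flat allocation
  expect_equal(fisher_information(c(0, 20, 45), pr, observer_params(7, 0)),
               rep(7, 3))
  # cardinal / oblique ratio ((a+1)/(a-1))^q
  for (q in c(1, 4 / 3, 2)) {
    obs <- observer_params(100, q)
    ratio <- fisher_information(0, pr, obs) / fisher_information(45, pr, obs)
    expect_equal(ratio, (2.85 / 0.85)^q, tolerance = 1e-6)
  }
  # linearity in k
  j1 <- fisher_information(30, pr, observer_params(50, 1.5))
  j2 <- fisher_information(30, pr, observer_params(100, 1.5))
  expect_equal(j2, 2 * j1)
})

test_that("encoding is Gaussian with inverse-Fisher variance and seeded", {
  pr <- orient_prior()
  obs <- observer_params(3000, 4 / 3)
  r1 <- encode_stimulus(rep(30, 500), pr, obs, seed = 5)
  r2 <- encode_stimulus(rep(30, 500), pr, obs, seed = 5)
  expect_identical(r1, r2)
  big <- encode_stimulus(rep(30, 5e4), pr, obs, seed = 6)
  v_true <- (180 / pi)^2 / fisher_information(30, pr, obs)
  expect_lt(abs(var(big) - v_true), 3 * v_true * sqrt(2 / (5e4 - 1)))
  # k -> infinity: responses collapse onto the stimulus
  tight <- encode_stimulus(rep(30, 10), pr, observer_params(1e12, 1), seed = 7)
  expect_lt(max(abs(tight - 30)), 1e-3)
  expect_error(encode_stimulus(300, pr, obs), class = "fitmax_domain_error")
})

test_that("posterior-mean decoding tracks the response under a flat prior", {
  pr <- orientation_prior(a = 1e6, domain = stimulus_domain(0, 180, TRUE, 512))
  obs <- observer_params(5e4, 1)
  est <- decode_posterior_mean(c(40, 90, 130), pr, obs)
  expect_equal(est, c(40, 90, 130), tolerance = 1e-2)
})

test_that("closed-form moments: zero bias at q = 1 and on the axes", {
  pr <- orient_prior()
  m1 <- estimate_moments(seq(5, 85, by = 10), pr, observer_params(2000, 1))
  expect_equal(m1$bias, rep(0, 9))
  m2 <- estimate_moments(c(0, 45, 90), pr, observer_params(2000, 4 / 3))
  expect_equal(m2$bias, rep(0, 3), tolerance = 1e-12)
  expect_equal(m2$mean, m2$s0 + m2$bias)
  # variance ratio oblique / cardinal at q = 4/3 is about 5.0
  expect_equal(m2$var[2] / m2$var[1], (2.85 / 0.85)^(4 / 3), tolerance = 1e-6)
  expect_error(estimate_moments(10, pr, observer_params(100, 0)),
               class = "fitmax_range_error")
})

test_that("closed-form moments match the grid-decode Monte Carlo", {
  pr <- orient_prior(1024)
  k <- 2e4
  n <- 4000
  for (q in c(1, 4 / 3, 2)) {
    obs <- observer_params(k, q)
    for (s0 in c(20, 40, 65)) {
      set.seed(1000 + round(10 * q) + s0)
      r <- encode_stimulus(rep(s0, n), pr, obs)
      est <- decode_posterior_mean(r, pr, obs, n_grid = 3000)
      cf <- estimate_moments(s0, pr, obs)
      expect_lt(abs(mean(est) - cf$mean), 3 * sd(est) / sqrt(n))
      expect_lt(abs(var(est) - cf$var), 3 * cf$var * sqrt(2 / (n - 1)) + 0.05 * cf$var)
    }
  }
})

test_that("generic-prior moment path agrees with the analytic one", {
  pr <- orient_prior(2048)
  gen <- prior_from_density(stimulus_domain(0, 180, TRUE, 2048), pr$density)
  obs <- observer_params(3000, 4 / 3)
  s0 <- seq(10, 80, by = 10)
  ana <- estimate_moments(s0, pr, obs)
  num <- estimate_moments(s0, gen, obs)
  expect_equal(num$var, ana$var, tolerance = 1e-4)
  expect_equal(num$bias, ana$bias, tolerance = 0.05)
})

test_that("the two bias proportionality constants agree over q in [0.5, 2]", {
  for (q in c(0.5, 0.75, 1.33, 2)) {
    bc <- bias_constant_pair(q, 1)
    # both forms vanish at q = 1 and stay within ~15% of each other
    if (q != 1) {
      expect_lt(abs(bc["simulation"] - bc["analytic"]),
                0.15 * max(abs(bc)))
    }
  }
  expect_equal(unname(bias_constant_pair(1, 5)), c(0, 0))
  b1 <- bias_constant_pair(2, 1)
  b2 <- bias_constant_pair(2, 2)
  expect_equal(unname(b1 / b2), c(2, 2))
})

test_that("choice probability obeys symmetry, lapse and bias structure", {
  pr <- diag_prior()
  obs <- observer_params(500, 4 / 3)
  expect_equal(choice_probability(20, 20, pr, obs), 0.5)
  expect_equal(choice_probability(10, 40, pr, obs,
                                  behavior_params(lambda = 1)), 0.5)
  # swap symmetry at beta0 = 0
  p12 <- choice_probability(12, 30, pr, obs)
  p21 <- choice_probability(30, 12, pr, obs)
  expect_equal(p12 + p21, 1, tolerance = 1e-12)
  # degenerate zero-variance tie falls back to the lapse-adjusted bias
  obs_inf <- observer_params(1e14, 1)
  pb <- choice_probability(20, 20, pr, obs_inf, behavior_params(beta0 = 0.5))
  expect_equal(pb, pnorm(0.5), tolerance = 1e-3)
})

test_that("choice probability matches encode-decode simulation", {
  pr <- diag_prior(1024)
  obs <- observer_params(300, 4 / 3)
  d1 <- 25; d2 <- 18
  p_closed <- choice_probability(d1, d2, pr, obs)
  n <- 3e4
  set.seed(99)
  e1 <- decode_posterior_mean(encode_stimulus(rep(d1, n), pr, obs), pr, obs)
  e2 <- decode_posterior_mean(encode_stimulus(rep(d2, n), pr, obs), pr, obs)
  p_mc <- mean(e1 > e2)
  expect_lt(abs(p_closed - p_mc), 3 * sqrt(p_mc * (1 - p_mc) / n) + 0.01)
})

test_that("estimation reports combine encoding and motor noise", {
  pr <- orient_prior(1024)
  # motor sd 0 and huge k: reports equal the stimulus
  rep0 <- simulate_estimation_report(c(30, 60), pr, observer_params(1e10, 1),
                                     motor_sd = 0, seed = 1)
  expect_equal(rep0, c(30, 60), tolerance = 0.05)
  # report variance = encoding variance + motor variance
  obs <- observer_params(2e4, 4 / 3)
  s0 <- 22.5
  n <- 4000
  reps <- simulate_estimation_report(rep(s0, n), pr, obs, motor_sd = 2,
                                     seed = 12)
  cf <- estimate_moments(s0, pr, obs)
  tot <- cf$var + 4
  expect_lt(abs(var(reps) - tot), 3 * tot * sqrt(2 / (n - 1)))
  expect_lt(abs(mean(reps) - cf$mean), 3 * sqrt(tot / n))
})

test_that("prediction pattern: lowering q helps obliques, hurts cardinals", {
  pr <- diag_prior()
  hi <- observer_params(400, 2)
  lo <- observer_params(400, 4 / 3)
  # oblique pair accuracy rises as q falls; cardinal pair accuracy falls
  acc_obl_hi <- choice_probability(40, 34, pr, hi)
  acc_obl_lo <- choice_probability(40, 34, pr, lo)
  acc_card_hi <- choice_probability(8, 2, pr, hi)
  acc_card_lo <- choice_probability(8, 2, pr, lo)
  expect_gt(acc_obl_lo, acc_obl_hi)
  expect_lt(acc_card_lo, acc_card_hi)
  # estimation variance falls at obliques, rises at cardinals
  vh <- estimate_moments(c(2, 43), pr, hi)$var
  vl <- estimate_moments(c(2, 43), pr, lo)$var
  expect_gt(vl[1], vh[1])
  expect_lt(vl[2], vh[2])
  # raising k helps everywhere
  k2 <- observer_params(800, 2)
  expect_true(all(estimate_moments(c(2, 20, 43), pr, k2)$var <
                    estimate_moments(c(2, 20, 43), pr, hi)$var))
  expect_gt(choice_probability(8, 2, pr, k2), acc_card_hi)
  expect_gt(choice_probability(40, 34, pr, k2), acc_obl_hi)
})
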