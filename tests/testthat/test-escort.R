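test_that("escort response is the identity ramp for a uniform prior", {
  pr <- uniform_prior()
  for (g in c(0.5, 1, 2)) {
    h <- escort_response(pr, g)
    expect_equal(h$h, pr$s, tolerance = 1e-10)
  }
})

test_that("gamma = 1 escort response equals the prior CDF", {
  pr <- piecewise_prior()
  h <- escort_response(pr, 1)
  expect_equal(h$h, fitmax:::prior_cdf(pr), tolerance = 1e-12)
})

test_that("piecewise prior escort value matches the closed form", {
  # f = 1.6 on [0, .5], 0.4 on [.5, 1]; gamma = 2/3:
  # h(0.5) = 1.6^(2/3) / (1.6^(2/3) + 0.4^(2/3)) = 0.71594...
  pr <- piecewise_prior()
  h <- escort_response(pr, 2 / 3)
  closed <- 1.6^(2 / 3) / (1.6^(2 / 3) + 0.4^(2 / 3))
  expect_equal(approx(h$s, h$h, 0.5)$y, closed, tolerance = 2e-3)
})

test_that("escort self-consistency: gamma-power prior with exponent 1", {
  pr <- piecewise_prior()
  for (g in c(0.5, 2 / 3, 1.3)) {
    h1 <- escort_response(pr, g)
    raised <- prior_from_density(unit_dom(1025), pr$density^g)
    h2 <- escort_response(raised, 1)
    expect_lt(max(abs(h1$h - h2$h)), 1e-10)
  }
})

test_that("exponent algebra links p, gamma, q and the objective exponent", {
  e <- exponent_set(gamma = 2 / 3)
  expect_equal(e$p, 0.5)
  expect_equal(e$q, 4 / 3)
  e2 <- exponent_set(gamma = 1, beta_cap = 0.5)
  expect_equal(e2$q, 2)
  expect_equal(e2$p, 0)
  # p -> 0 gives gamma -> 1 (infomax)
  expect_equal(exponent_set(p = 1e-12)$gamma, 1, tolerance = 1e-9)
  # mutual consistency: gamma = beta/(beta+alpha), q = 1/(beta+alpha)
  for (g in c(0.4, 2 / 3, 0.9)) {
    e <- exponent_set(gamma = g, beta_cap = 0.7)
    expect_equal(e$gamma, e$beta_cap / (e$beta_cap + e$alpha_obj),
                 tolerance = 1e-12)
    expect_equal(e$q, 1 / (e$beta_cap + e$alpha_obj), tolerance = 1e-12)
    expect_equal(e$gamma, 1 / (1 + e$p), tolerance = 1e-12)
  }
  expect_error(exponent_set(gamma = 1.2), class = "fitmax_range_error")
  expect_error(exponent_set(p = -0.1), class = "fitmax_range_error")
  expect_error(exponent_set(), class = "fitmax_range_error")
})

test_that("quantization boundaries sit at response quantiles", {
  pr <- uniform_prior()
  code <- quantize_code(escort_response(pr, 1), 4)
  expect_equal(code$boundaries, c(0.25, 0.5, 0.75), tolerance = 1e-6)

  pro <- orient_prior()
  code10 <- quantize_code(escort_response(pro, 1), 10)
  cdf <- fitmax:::prior_cdf(pro)
  deciles <- approx(cdf, pro$s, seq(0.1, 0.9, 0.1), ties = "ordered")$y
  expect_equal(code10$boundaries, deciles, tolerance = 1e-6)

  # piecewise prior, gamma = 1, n = 2: CDF = 0.5 at s = 0.5/1.6 = 0.3125
  prp <- piecewise_prior()
  code2 <- quantize_code(escort_response(prp, 1), 2)
  expect_equal(code2$boundaries, 0.3125, tolerance = 1e-3)

  expect_error(quantize_code(escort_response(pr, 1), 1),
               class = "fitmax_range_error")
})

test_that("quantization reports degenerate plateaus", {
  dom <- unit_dom(513)
  pr <- prior_from_density(dom, function(s) ifelse(s < 0.4 | s > 0.6, 1, 0))
  h <- escort_response(pr, 1)
  expect_error(quantize_code(h, 2), class = "fitmax_plateau_error")
})

test_that("error-probability loss matches mass arithmetic", {
  pr <- uniform_prior()
  code <- quantize_code(escort_response(pr, 1), 10)
  expect_equal(prob_error_loss(pr, code), 0.05, tolerance = 1e-6)

  # piecewise prior with a forced boundary at 0.5: masses 0.8 / 0.2
  prp <- piecewise_prior()
  forced <- structure(list(n = 2L, boundaries = 0.5, response = NULL),
                      class = "fm_code")
  # the density step at 0.5 is smeared over one grid cell by the trapezoid
  expect_equal(prob_error_loss(prp, forced), (0.64 + 0.04) / 2,
               tolerance = 1e-3)
})

test_that("reward loss reproduces closed forms and the Monte-Carlo oracle", {
  pr <- uniform_prior()
  dom <- unit_dom()
  rl <- linear_reward(dom)
  code <- quantize_code(escort_response(pr, 1), 10)
  expect_equal(reward_loss(pr, code, rl), 1 / 600, tolerance = 1e-3)

  rc <- reward_map(dom, "constant", value = 3)
  expect_equal(reward_loss(pr, code, rc), 0, tolerance = 1e-12)

  prp <- piecewise_prior()
  forced <- structure(list(n = 2L, boundaries = 0.5, response = NULL),
                      class = "fm_code")
  mc <- mc_code_loss(prp, forced, 2e5, reward = linear_reward(unit_dom(1025)))
  expect_lt(abs(reward_loss(prp, forced, linear_reward(unit_dom(1025))) - mc$mean),
            3 * mc$se)
})

test_that("both loss functionals are non-increasing in the level count", {
  for (pr in list(piecewise_prior(), orient_prior(1024))) {
    dom <- fitmax:::prior_domain(pr)
    rl <- linear_reward(dom)
    pe <- rw <- numeric(0)
    for (n in c(2, 4, 8, 16, 32)) {
      code <- quantize_code(escort_response(pr, 0.8), n)
      pe <- c(pe, prob_error_loss(pr, code))
      rw <- c(rw, reward_loss(pr, code, rl))
    }
    expect_true(all(diff(pe) < 1e-10))
    expect_true(all(diff(rw) < 1e-10))
  }
})

test_that("losses agree with pairwise Monte-Carlo on distinct priors", {
  dom <- unit_dom(1025)
  priors <- list(
    piecewise_prior(),
    prior_from_density(dom, function(s) exp(-2 * s)),
    prior_from_density(dom, function(s) 0.5 + s)
  )
  rl <- linear_reward(dom)
  for (i in seq_along(priors)) {
    pr <- priors[[i]]
    code <- quantize_code(escort_response(pr, 0.7), 5)
    mc_p <- mc_code_loss(pr, code, 2e5, seed = 100 + i)
    expect_lt(abs(prob_error_loss(pr, code) - mc_p$mean), 3 * mc_p$se)
    mc_r <- mc_code_loss(pr, code, 2e5, reward = rl, seed = 200 + i)
    expect_lt(abs(reward_loss(pr, code, rl) - mc_r$mean), 3 * mc_r$se)
  }
})

test_that("escort optimizer warns on a flat prior", {
  pr <- uniform_prior(257)
  expect_warning(
    optimize_escort_exponent(pr, "accuracy", n = 5,
                             gamma_grid = seq(0.5, 1.2, 0.1)),
    class = "fitmax_flat_objective"
  )
})

test_that("golden-section refinement agrees with a fine grid scan", {
  pr <- piecewise_prior(513)
  dom <- unit_dom(513)
  rl <- linear_reward(dom)
  opt <- optimize_escort_exponent(pr, "reward", reward = rl, n = 8)
  fine <- seq(0.3, 1.5, by = 0.01)
  losses <- vapply(fine, function(g) {
    reward_loss(pr, quantize_code(escort_response(pr, g), 8), rl)
  }, numeric(1))
  expect_lt(abs(opt$gamma_star - fine[which.min(losses)]), 0.011)
})

test_that("response density is flat for infomax and conserves mass", {
  pr <- piecewise_prior()
  g1 <- response_density(pr, escort_response(pr, 1))
  expect_lt(diff(range(g1$density)), 1e-6)
  g23 <- response_density(pr, escort_response(pr, 2 / 3))
  expect_equal(trapz_(g23$r, g23$density), 1, tolerance = 1e-4)
})

test_that("response density matches a sampling histogram", {
  pr <- piecewise_prior()
  h <- escort_response(pr, 2 / 3)
  g <- response_density(pr, h)
  set.seed(7)
  s <- sample_stimuli(pr, 2e5)
  r <- approx(h$s, h$h, s)$y
  brk <- seq(0, 1, by = 0.05)
  hist_d <- hist(r, breaks = brk, plot = FALSE)$density
  pred <- vapply(seq_len(length(brk) - 1L), function(i) {
    seg <- g$r >= brk[i] & g$r <= brk[i + 1]
    mean(g$density[seg])
  }, numeric(1))
  n_bin <- hist(r, breaks = brk, plot = FALSE)$counts
  se <- sqrt(pmax(n_bin, 1)) / (2e5 * 0.05)
  expect_true(all(abs(hist_d - pred) < 3 * se + 0.02))
})
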