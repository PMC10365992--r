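test_that("allocations are normalized and carry a capacity-derived scale", {
  al <- allocation(unit_dom(257), function(s) exp(-2 * s), capacity = 10,
                   beta_cap = 0.5)
  expect_equal(trapz_(al$s, al$f_tilde), 1, tolerance = 1e-6)
  # capacity identity: integral of (k f~)^beta equals the budget
  k <- attr(al, "k")
  expect_equal(trapz_(al$s, (k * al$f_tilde)^0.5), 10, tolerance = 1e-6)
  expect_error(allocation(unit_dom(257), function(s) s - 0.5),
               class = "fitmax_range_error")
})

test_that("relative value peaks at the threshold and is symmetric", {
  expect_equal(relative_value(0.5, 0.5), 0)
  expect_equal(relative_value(0.3, 0.5), relative_value(0.7, 0.5))
  # with tau at the domain maximum, ranking by relative value equals ranking
  # by the decoded stimulus itself
  x <- runif(50)
  expect_equal(order(relative_value(x, 1)), order(x))
})

test_that("scenario loss decreases with capacity and is zero-cost for flat rewards", {
  sc <- scenario_setup(2)
  lo <- power_law_allocation(sc$prior, 4 / 3, capacity = sqrt(2000))
  hi <- power_law_allocation(sc$prior, 4 / 3, capacity = sqrt(2e5))
  l_lo <- suppressWarnings(scenario_loss(lo, sc$prior, sc$reward, "reward"))
  l_hi <- scenario_loss(hi, sc$prior, sc$reward, "reward")
  expect_lt(l_hi, l_lo)
  flat <- reward_map(unit_dom(257), "constant", value = 2)
  expect_equal(scenario_loss(hi, sc$prior, flat, "reward"), 0)
})

test_that("the accuracy objective depends on the reward ordering only", {
  sc <- scenario_setup(1)
  al <- power_law_allocation(sc$prior, 2)
  r1 <- reward_map(unit_dom(257), "linear", intercept = 0, slope = 1)
  r5 <- reward_map(unit_dom(257), "linear", intercept = 3, slope = 5)
  expect_equal(scenario_loss(al, sc$prior, r1, "accuracy"),
               scenario_loss(al, sc$prior, r5, "accuracy"), tolerance = 1e-10)
})

test_that("band quadrature agrees with a brute-force pair grid", {
  sc <- scenario_setup(1)
  al <- power_law_allocation(sc$prior, 2, capacity = sqrt(5000))
  # dense uniform pair quadrature as the independent oracle
  sq <- seq(0, 1, length.out = 1501)
  k <- attr(al, "k")
  f <- fitmax:::prior_density_at(sc$prior, sq)
  w <- fitmax:::trapz_weights(sq) * f
  w <- w / sum(w)
  v <- 1 / (k * pmax(approx(al$s, al$f_tilde, sq)$y, 1e-12))
  tot <- 0
  for (i in seq_along(sq)) {
    zs <- (sq[i] - sq) / sqrt(v[i] + v)
    perr <- ifelse(sq[i] > sq, pnorm(-zs), ifelse(sq[i] < sq, pnorm(zs), 0.5))
    tot <- tot + w[i] * sum(w * perr)
  }
  band <- suppressWarnings(scenario_loss(al, sc$prior, sc$reward, "accuracy"))
  expect_equal(band, tot, tolerance = 0.02)
})

test_that("power-law allocation beats uniform on the monotonic scenarios", {
  for (scn in 1:2) {
    sc <- scenario_setup(scn)
    q <- if (scn == 1) 2 else 4 / 3
    pl <- power_law_allocation(sc$prior, q)
    un <- allocation(unit_dom(257), function(s) rep(1, length(s)))
    expect_lt(scenario_loss(pl, sc$prior, sc$reward, sc$objective),
              scenario_loss(un, sc$prior, sc$reward, sc$objective))
  }
})

test_that("optimizer iterates keep the allocation normalized", {
  sc <- scenario_setup(2)
  sol <- optimize_allocation(sc$prior, sc$reward, "reward", restarts = 1L,
                             maxit = 30L)
  expect_lt(abs(trapz_(sol$allocation$s, sol$allocation$f_tilde) - 1), 1e-6)
  expect_s3_class(sol, "fm_scenario_solution")
  gl <- glance(sol)
  expect_equal(gl$objective, "reward")
})
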