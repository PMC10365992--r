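# small shared cohort: 6 subjects x 250 trials at known parameters
make_cohort <- function(q = 1.5, k = NULL, n_subj = 6, n_trials = 250,
                        lambda = 0, seed = 77) {
  pr <- orient_prior()
  prd <- diag_prior()
  if (is.null(k)) k <- calibrate_k(prd, q = q, separation = 10, target = 0.9)
  dplyr::bind_rows(lapply(seq_len(n_subj), function(j) {
    cfg <- session_config(
      context = "reward", n_decision = n_trials,
      observer = observer_params(k, q),
      behavior = behavior_params(lambda = lambda),
      seed = seed * 100 + j
    )
    simulate_decision_session(cfg, orient_prior(), sprintf("s%02d", j))
  }))
}

test_that("posterior_prob is the two-sided tail probability", {
  expect_equal(posterior_prob(c(1, 2, 3)), 0)
  expect_equal(posterior_prob(c(-1, 1, -2, 2)), 0.5)
  set.seed(1)
  d <- rnorm(3000, -0.29, 0.15)
  expect_lt(abs(posterior_prob(d) - (1 - pnorm(0, -0.29, 0.15))), 0.02)
})

test_that("gelman_rubin flags divergence and passes stationary chains", {
  expect_equal(gelman_rubin(cbind(1:100, 1:100)), 1)
  set.seed(3)
  expect_lt(gelman_rubin(matrix(rnorm(4000), ncol = 4)), 1.05)
  expect_gt(gelman_rubin(cbind(rnorm(300), rnorm(300, 10))), 1.5)
  expect_error(gelman_rubin(matrix(1:10, ncol = 1)), class = "fitmax_range_error")
})

test_that("grid likelihood peaks at the generating cell on dense data", {
  trials <- make_cohort(q = 1.5, n_subj = 2, n_trials = 5000, seed = 31)
  pr <- orient_prior()
  prd <- diag_prior()
  k_true <- calibrate_k(prd, q = 1.5, separation = 10, target = 0.9)
  g <- map_grid_fit(trials, pr,
                    q_grid = c(1, 1.25, 1.5, 1.75, 2),
                    k_grid = k_true * c(0.5, 0.75, 1, 1.5, 2))
  expect_equal(g$pooled$q, 1.5)
  expect_equal(g$pooled$k, k_true)
  # subjects share parameters: each subject's argmax sits within one grid
  # step of the pooled one (finite data moves it at most a cell)
  expect_true(all(abs(g$by_subject$q - g$pooled$q) <= 0.26))
})

test_that("the likelihood is degenerate in (q, k) at full lapse", {
  trials <- make_cohort(n_subj = 2, n_trials = 100, seed = 5)
  pr <- orient_prior()
  g <- map_grid_fit(trials, pr, q_grid = c(1, 2), k_grid = c(2, 20),
                    lambda_grid = 1)
  tt <- trials[trials$subject == trials$subject[1], ]
  a <- attr(pr, "a")
  omega <- attr(diag_prior(), "omega")
  dd <- fitmax:::prep_subject_data(tt$d1, tt$d2, tt$choice, a, omega)
  lls <- c(fitmax:::subject_loglik(dd, 1, 2, 1, 0),
           fitmax:::subject_loglik(dd, 2, 20, 1, 0))
  expect_equal(lls[1], lls[2])
})

test_that("the hierarchical fit recovers parameters and is deterministic", {
  trials <- make_cohort(q = 1.5, n_subj = 6, n_trials = 250, seed = 42)
  pr <- orient_prior()
  cfg <- fit_config(chains = 3, burnin = 250, draws = 250, thin = 1, seed = 7)
  fit1 <- suppressWarnings(fit_hierarchical(trials, pr, cfg))
  expect_equal(fit1$n_retained, 750)
  # truth sits inside the central posterior mass of this small cohort
  qd <- group_draws(fit1, "q")
  expect_lt(quantile(qd, 0.01), 1.5)
  expect_gt(quantile(qd, 0.99), 1.5)
  # lambda generated at zero: the posterior's lower half stays small
  ld <- group_draws(fit1, "lambda")
  expect_lt(quantile(ld, 0.25), 0.05)
  # determinism under the same config
  fit2 <- suppressWarnings(fit_hierarchical(trials, pr, cfg))
  expect_identical(fit1$draws$value, fit2$draws$value)
  # tidiers
  td <- tidy(fit1)
  expect_true(all(c("estimate", "conf.low", "rhat") %in% names(td)))
  gl <- glance(fit1)
  expect_equal(gl$n_subjects, 6L)
})

test_that("sampler agrees with the brute-force grid argmax on dense data", {
  trials <- make_cohort(q = 1.5, n_subj = 3, n_trials = 1500, seed = 55)
  pr <- orient_prior()
  prd <- diag_prior()
  k_true <- calibrate_k(prd, q = 1.5, separation = 10, target = 0.9)
  fit <- suppressWarnings(fit_hierarchical(
    trials, pr, fit_config(chains = 2, burnin = 300, draws = 300, thin = 1,
                           seed = 3)
  ))
  q_grid <- seq(1, 2.2, by = 0.1)
  g <- map_grid_fit(trials, pr, q_grid = q_grid,
                    k_grid = k_true * 2^seq(-1, 1, by = 0.25))
  for (sj in unique(trials$subject)) {
    draws_q <- fit$draws$value[fit$draws$parameter == "q" &
                                 fit$draws$level == sj]
    grid_q <- g$by_subject$q[g$by_subject$subject == sj]
    # the brute-force argmax falls inside the sampled central 95% interval,
    # up to the grid's own half-cell resolution
    expect_lt(quantile(draws_q, 0.025) - 0.05, grid_q)
    expect_gt(quantile(draws_q, 0.975) + 0.05, grid_q)
  }
})

test_that("gelman_rubin agrees with the independent reference implementation", {
  set.seed(11)
  m <- matrix(rnorm(2000), ncol = 2) + rep(c(0, 0.2), each = 1000)
  mine <- gelman_rubin(m)
  ref <- coda::gelman.diag(coda::mcmc.list(coda::mcmc(m[, 1]), coda::mcmc(m[, 2])),
                           autoburnin = FALSE)$psrf[1]
  expect_equal(mine, ref, tolerance = 0.02)
})
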