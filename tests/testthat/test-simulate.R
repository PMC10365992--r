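test_that("staircase arithmetic follows the 3:1 weighted up-down rule", {
  st <- staircase_state(difficulty = 10, step_up = 1.5)
  up <- staircase_update(st, correct = FALSE)
  expect_equal(up$difficulty, 11.5)
  dn <- staircase_update(st, correct = TRUE)
  expect_equal(dn$difficulty, 10 - 0.5)
  # alternating correct/incorrect drifts the separation up by 2/3 step/pair
  s <- st
  for (i in 1:10) { s <- staircase_update(s, TRUE); s <- staircase_update(s, FALSE) }
  expect_equal(s$difficulty, 10 + 10 * (1.5 - 0.5), tolerance = 1e-10)
  # bounds are never violated
  s <- staircase_state(difficulty = 1, step_up = 3, floor = 0.5, ceiling = 5)
  set.seed(1)
  for (i in 1:2000) s <- staircase_update(s, runif(1) < 0.5)
  expect_gte(s$difficulty, 0.5)
  expect_lte(s$difficulty, 5)
})

test_that("stimulus sampling matches the prior distribution", {
  pr <- orient_prior(1024)
  x <- sample_stimuli(pr, 5e4, seed = 3)
  cdf_emp <- stats::ecdf(x)
  cdf_th <- approxfun(pr$s, fitmax:::prior_cdf(pr))
  grid <- seq(1, 179, by = 1)
  expect_lt(max(abs(cdf_emp(grid) - cdf_th(grid))), 0.012)
  expect_identical(sample_stimuli(pr, 100, seed = 9),
                   sample_stimuli(pr, 100, seed = 9))
})

test_that("decision sessions implement the payoff rules", {
  pr <- orient_prior()
  cfg <- session_config(context = "reward", n_decision = 150,
                        observer = observer_params(5, 1.5), seed = 21)
  tab <- simulate_decision_session(cfg, pr)
  d_chosen <- ifelse(tab$choice == 1, tab$d1, tab$d2)
  expect_equal(tab$payoff, 1 + d_chosen)
  expect_true(all(tab$payoff >= 1 & tab$payoff <= 46))
  cfg_a <- session_config(context = "accuracy", n_decision = 150,
                          observer = observer_params(5, 1.5), seed = 21)
  tab_a <- simulate_decision_session(cfg_a, pr)
  expect_equal(sum(tab_a$payoff), 15 * sum(tab_a$correct))
  # near-perfect observer drives the staircase to its floor
  cfg_p <- session_config(context = "accuracy", n_decision = 300,
                          observer = observer_params(1e8, 1), seed = 4)
  tab_p <- simulate_decision_session(cfg_p, pr)
  expect_gt(mean(tab_p$correct), 0.97)
  late_sep <- abs(tab_p$d1 - tab_p$d2)[250:300]
  expect_lt(median(late_sep), 1)
})

test_that("sessions are reproducible and schema-valid", {
  pr <- orient_prior()
  cfg <- session_config(n_decision = 60, observer = observer_params(5, 1.5),
                        seed = 8)
  t1 <- simulate_decision_session(cfg, pr)
  t2 <- simulate_decision_session(cfg, pr)
  expect_identical(t1, t2)
  v <- validate_trial_table(t1)
  expect_true(v$ok)
})

test_that("estimation filtering keeps the 22.5-degree boundary inclusive", {
  tr <- tibble::tibble(error = c(-23, -22.5, 0, 22, 22.5, 23))
  out <- filter_estimation(tr)
  expect_equal(out$kept, c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("signed errors are positive toward the oblique", {
  # report more oblique than truth -> positive
  expect_gt(signed_estimation_error(10, 20), 0)
  expect_lt(signed_estimation_error(40, 20), 0)
  # circular wrap: reported 178 vs true 2 is a small negative (more cardinal
  # side of 2? both near cardinal) magnitude-4 error
  expect_equal(abs(signed_estimation_error(2, 178)), 4)
  expect_true(all(abs(signed_estimation_error(runif(100, 0, 179),
                                              runif(100, 0, 179))) <= 90))
})

test_that("bin summaries use five 9-degree bins with labeled extremes", {
  set.seed(2)
  n <- 500
  tr <- tibble::tibble(
    subject = "s1", phase = rep(c("before", "after"), each = n / 2),
    location = "left", s_true = runif(n, 0, 179),
    s_report = NA_real_, error = rnorm(n, 0, 3)
  )
  out <- bin_summaries(filter_estimation(tr))
  expect_setequal(as.character(unique(out$bin)),
                  c("cardinal", "bin2", "bin3", "bin4", "oblique"))
  # constant-variance generator: change scores center on zero
  expect_lt(abs(mean(out$var_change, na.rm = TRUE)), 4)
})

test_that("trial tables round-trip through delimited text", {
  pr <- orient_prior()
  tab <- simulate_decision_session(
    session_config(n_decision = 40, observer = observer_params(5, 1.5),
                   seed = 2), pr)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trial_table(tab, path)
  back <- read_trial_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-9)
})

test_that("validate_trial_table reports specific problems", {
  pr <- orient_prior()
  tab <- simulate_decision_session(
    session_config(n_decision = 30, observer = observer_params(5, 1.5),
                   seed = 2), pr)
  bad <- tab
  bad$choice[3] <- 3L
  v <- validate_trial_table(bad)
  expect_false(v$ok)
  expect_match(paste(v$problems, collapse = " "), "choice")
  # experiment-2-sized session: 200 early / 160 late
  tab2 <- simulate_decision_session(
    session_config(n_decision = 360, observer = observer_params(5, 1.5),
                   seed = 2), pr)
  sp <- split_phases(tab2)
  expect_equal(nrow(sp$early), 200)
  expect_equal(nrow(sp$late), 160)
  expect_warning(split_phases(tab), class = "fitmax_short_session")
})
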