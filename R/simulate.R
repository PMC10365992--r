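#' Configure a simulated experimental session
#'
#' Bundles everything a simulated subject needs: the stimulus-reward context,
#' trial counts, stimulus locations (with the trained subset), staircase
#' settings, and the observer/behavior parameters. Experiment 1 used 400
#' decision + 240 estimation trials in two lateral locations; experiment 2
#' used 360 decision + 400 estimation trials across four locations of which
#' two were trained.
#'
#' @param context `"accuracy"` or `"reward"`.
#' @param n_decision,n_estimation Trial counts.
#' @param locations Character vector of stimulus locations.
#' @param trained Subset of `locations` trained in the decision task.
#' @param observer An [observer_params()] used in the decision task (on the
#'   diagonality axis).
#' @param behavior A [behavior_params()].
#' @param estimation_observers Named list of per-location [observer_params()]
#'   (orientation axis) for the estimation task; defaults to `observer` for
#'   every location.
#' @param staircase An [staircase_state()].
#' @param motor_sd Estimation motor noise sd, degrees.
#' @param seed Integer seed.
#' @return A list of class `fm_session_config`.
#' @export
session_config <- function(context = c("accuracy", "reward"),
                           n_decision = 400L, n_estimation = 240L,
                           locations = c("left", "right"),
                           trained = locations,
                           observer = observer_params(k = 200, q = 2),
                           behavior = behavior_params(),
                           estimation_observers = NULL,
                           staircase = staircase_state(),
                           motor_sd = 2, seed = 1L) {
  context <- match.arg(context)
  if (!all(trained %in% locations)) {
    stop_fitmax("`trained` must be a subset of `locations`.", "fitmax_range_error")
  }
  if (n_decision <= 0 || n_estimation <= 0) {
    stop_fitmax("Trial counts must be positive.", "fitmax_range_error")
  }
  estimation_observers <- estimation_observers %||%
    setNames(rep(list(observer), length(locations)), locations)
  structure(
    list(context = context, n_decision = as.integer(n_decision),
         n_estimation = as.integer(n_estimation), locations = locations,
         trained = trained, observer = observer, behavior = behavior,
         estimation_observers = estimation_observers, staircase = staircase,
         motor_sd = motor_sd, seed = as.integer(seed)),
    class = "fm_session_config"
  )
}

# realize a diagonality value as an orientation in the same quadrant as a
# reference orientation
orientation_from_diagonality <- function(d, ref_orientation) {
  quadrant <- floor((ref_orientation %% 180) / 45) # 0..3: which 45-deg sector
  base <- c(0, 90, 90, 180)[quadrant + 1L]
  sign <- c(1, -1, 1, -1)[quadrant + 1L]
  (base + sign * d) %% 180
}

#' Simulate one staircase-controlled decision session
#'
#' One reference stimulus per trial is drawn from the orientation prior; the
#' comparison differs from it by the current staircase separation in
#' diagonality (direction randomized, expressed as an orientation in the
#' reference's quadrant). Choices follow the observer's probit rule on the
#' diagonality axis; the payoff is 15 CHF per correct response in the
#' accuracy context, and in the reward context an affine function of the
#' chosen stimulus's diagonality running from 1 CHF at 0 degrees to 46 CHF at
#' 45 degrees. The staircase updates after every trial.
#'
#' @param config A [session_config()].
#' @param prior Orientation prior (degrees, domain `[0, 180)`).
#' @param subject Subject identifier stored in the table.
#' @return A trial tibble (one row per trial) with columns `subject`,
#'   `context`, `trial`, `s1_deg`, `s2_deg`, `d1`, `d2`, `choice`, `correct`,
#'   `payoff`, `phase`, `location`.
#' @export
simulate_decision_session <- function(config, prior, subject = "s01") {
  set.seed(derive_seed(config$seed, paste0("decision/", subject)))
  a <- attr(prior, "a")
  if (!is.finite(a)) a <- 1.85
  prior_diag <- orientation_prior(a, stimulus_domain(0, 45))
  omega_r <- attr(prior_diag, "omega") * 180 / pi # per-radian normalizer
  obs <- config$observer
  beh <- config$behavior
  deg <- 180 / pi
  # closed-form choice probability, scalar arithmetic (the tibble-returning
  # moment helpers are too heavy for a per-trial loop)
  p_choose1 <- function(dd1, dd2) {
    th1 <- 4 * dd1 * pi / 180; th2 <- 4 * dd2 * pi / 180
    f1 <- omega_r / (a - cos(th1)); f2 <- omega_r / (a - cos(th2))
    v1 <- deg^2 * f1^(-obs$q) / obs$k; v2 <- deg^2 * f2^(-obs$q) / obs$k
    bf <- deg * (1 - 1 / obs$q) * 4 * obs$q / (obs$k * omega_r)
    b1 <- bf * sin(th1) * f1^(1 - obs$q)
    b2 <- bf * sin(th2) * f2^(1 - obs$q)
    arg <- ((dd1 + b1) - (dd2 + b2)) / sqrt(v1 + v2)
    beh$lambda / 2 + (1 - beh$lambda) * pnorm(arg + beh$beta0)
  }
  st <- config$staircase
  n <- config$n_decision
  s1 <- s2 <- d1 <- d2 <- payoff <- numeric(n)
  choice <- integer(n)
  correct <- logical(n)
  loc <- sample(config$trained, n, replace = TRUE)
  refs <- sample_stimuli(prior, n)
  for (i in seq_len(n)) {
    s_ref <- refs[i]
    d_ref <- diagonality(s_ref)
    dir <- sample(c(-1, 1), 1L)
    d_cmp <- d_ref + dir * st$difficulty
    if (d_cmp > 45 || d_cmp < 0) d_cmp <- d_ref - dir * st$difficulty
    d_cmp <- min(max(d_cmp, 0), 45)
    s_cmp <- orientation_from_diagonality(d_cmp, s_ref)
    # reference is presented as stimulus 1 or 2 at random
    if (runif(1) < 0.5) {
      s1[i] <- s_ref; s2[i] <- s_cmp; d1[i] <- d_ref; d2[i] <- d_cmp
    } else {
      s1[i] <- s_cmp; s2[i] <- s_ref; d1[i] <- d_cmp; d2[i] <- d_ref
    }
    p1 <- p_choose1(d1[i], d2[i])
    choice[i] <- if (runif(1) < p1) 1L else 2L
    correct[i] <- (choice[i] == 1L) == (d1[i] >= d2[i])
    if (d1[i] == d2[i]) correct[i] <- TRUE
    d_chosen <- if (choice[i] == 1L) d1[i] else d2[i]
    payoff[i] <- if (config$context == "reward") {
      1 + 45 * d_chosen / 45
    } else {
      15 * correct[i]
    }
    st <- staircase_update(st, correct[i])
  }
  tibble::tibble(
    subject = subject, context = config$context, trial = seq_len(n),
    s1_deg = s1, s2_deg = s2, d1 = d1, d2 = d2, choice = choice,
    correct = correct, payoff = payoff,
    phase = ifelse(seq_len(n) <= 200L, "early", "late"), location = loc
  )
}

#' Simulate an estimation session across locations
#'
#' True orientations are uniform on (0, 179) degrees; trials cycle evenly
#' over the configured locations, and each location's reports are generated
#' by its own observer (so training-induced changes of the power-law exponent
#' can be confined to trained locations). Reports come from
#' [simulate_estimation_report()].
#'
#' @inheritParams simulate_decision_session
#' @param phase `"before"` or `"after"` (stored in the table).
#' @return An estimation tibble with columns `subject`, `phase`, `location`,
#'   `s_true`, `s_report`, `error` (signed, positive = reported more oblique
#'   than truth), `kept`.
#' @export
simulate_estimation_session <- function(config, prior, subject = "s01",
                                        phase = c("before", "after")) {
  phase <- match.arg(phase)
  set.seed(derive_seed(config$seed, paste0("estimation/", phase, "/", subject)))
  n <- config$n_estimation
  locs <- rep(config$locations, length.out = n)
  s_true <- runif(n, 0, 179)
  s_report <- numeric(n)
  for (lc in unique(locs)) {
    idx <- which(locs == lc)
    obs <- config$estimation_observers[[lc]]
    s_report[idx] <- simulate_estimation_report(
      s_true[idx], prior, obs, motor_sd = config$motor_sd
    )
  }
  err <- signed_estimation_error(s_true, s_report)
  filter_estimation(tibble::tibble(
    subject = subject, phase = phase, location = locs,
    s_true = s_true, s_report = s_report, error = err
  ))
}

#' Signed estimation error on the circular orientation scale
#'
#' The error magnitude is the circular distance between report and truth
#' (wrapped into `(-90, 90]`); its sign is positive when the report is more
#' oblique (closer to 45 degrees from a cardinal axis) than the truth.
#'
#' @param s_true,s_report Orientations in degrees.
#' @return Signed errors in degrees.
#' @export
signed_estimation_error <- function(s_true, s_report) {
  raw <- (s_report - s_true + 90) %% 180 - 90
  sgn <- ifelse(diagonality(s_report) >= diagonality(s_true), 1, -1)
  sgn * abs(raw)
}

#' Flag estimation trials exceeding the error cutoff
#'
#' Trials whose absolute error exceeds 25% of the maximum possible error (90
#' degrees), i.e. 22.5 degrees, are flagged for discarding; the boundary value
#' itself is kept.
#'
#' @param trials Estimation tibble with an `error` column.
#' @return The same tibble with a logical `kept` column.
#' @export
filter_estimation <- function(trials) {
  dplyr::mutate(trials, kept = abs(.data$error) <= 22.5)
}

#' Per-subject bias and variance in diagonality bins
#'
#' Kept trials are folded to the diagonality axis and grouped into five 9-degree
#' bins (`[0,9)` cardinal ... `[36,45]` oblique). For each subject, location
#' and phase the mean signed error (bias) and the error variance are computed;
#' when both phases are present, after-minus-before change scores are added.
#'
#' @param trials Estimation tibble (with `kept`; see [filter_estimation()]).
#' @return A tibble with one row per subject x location x bin and columns
#'   `bias_before`, `bias_after`, `var_before`, `var_after`, `bias_change`,
#'   `var_change` (missing when a phase or bin is empty).
#' @export
bin_summaries <- function(trials) {
  edges <- seq(0, 45, by = 9)
  labs <- c("cardinal", "bin2", "bin3", "bin4", "oblique")
  per <- trials |>
    dplyr::filter(.data$kept) |>
    dplyr::mutate(
      diag = diagonality(.data$s_true),
      bin = cut(.data$diag, breaks = edges, labels = labs,
                include.lowest = TRUE, right = FALSE)
    ) |>
    dplyr::group_by(.data$subject, .data$location, .data$phase, .data$bin,
                    .drop = FALSE) |>
    dplyr::summarise(
      bias = mean(.data$error), variance = var(.data$error),
      n = dplyr::n(), .groups = "drop"
    )
  wide <- per |>
    tidyr::pivot_wider(
      id_cols = c("subject", "location", "bin"),
      names_from = "phase", values_from = c("bias", "variance", "n")
    )
  for (ph in c("before", "after")) {
    for (v in c("bias", "variance", "n")) {
      nm <- paste0(v, "_", ph)
      if (!nm %in% names(wide)) wide[[nm]] <- NA_real_
    }
  }
  wide |>
    dplyr::rename(var_before = "variance_before", var_after = "variance_after") |>
    dplyr::mutate(
      bias_change = .data$bias_after - .data$bias_before,
      var_change = .data$var_after - .data$var_before
    )
}

#' Read and write trial tables as delimited text
#'
#' @param trials A decision trial tibble.
#' @param path File path (tab-separated).
#' @export
write_trial_table <- function(trials, path) {
  readr::write_tsv(trials, path)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject = "c", context = "c", phase = "c", location = "c"
                  ))
}
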