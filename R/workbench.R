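#' Validate a trial table file or data frame
#'
#' Checks the decision trial-table schema (column names, choice codes,
#' diagonality ranges, contiguous trial indices per subject and context) and
#' reports row counts per subject, context and phase.
#'
#' @param trials A file path or a data frame.
#' @return A list with `ok` (logical), `problems` (character) and `counts`
#'   (tibble of rows per subject x context x phase). Problems report row
#'   numbers.
#' @export
validate_trial_table <- function(trials) {
  if (is.character(trials)) trials <- read_trial_table(trials)
  required <- c("subject", "context", "trial", "s1_deg", "s2_deg", "d1", "d2",
                "choice", "correct", "payoff", "phase", "location")
  problems <- character(0)
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0) {
    problems <- c(problems, sprintf("missing columns: %s",
                                    paste(missing, collapse = ", ")))
  } else {
    bad_choice <- which(!trials$choice %in% c(1L, 2L))
    if (length(bad_choice) > 0) {
      problems <- c(problems, sprintf("invalid choice codes at rows: %s",
                                      paste(head(bad_choice, 10), collapse = ", ")))
    }
    bad_d <- which(trials$d1 < 0 | trials$d1 > 45 | trials$d2 < 0 | trials$d2 > 45)
    if (length(bad_d) > 0) {
      problems <- c(problems, sprintf("diagonality outside [0, 45] at rows: %s",
                                      paste(head(bad_d, 10), collapse = ", ")))
    }
    gaps <- trials |>
      dplyr::group_by(.data$subject, .data$context) |>
      dplyr::summarise(contiguous = all(sort(.data$trial) == seq_along(.data$trial)),
                       .groups = "drop")
    if (any(!gaps$contiguous)) {
      problems <- c(problems, sprintf("non-contiguous trial indices for: %s",
                                      paste(gaps$subject[!gaps$contiguous], collapse = ", ")))
    }
  }
  counts <- if (length(missing) == 0) {
    trials |>
      dplyr::count(.data$subject, .data$context, .data$phase)
  } else {
    tibble::tibble()
  }
  list(ok = length(problems) == 0, problems = problems, counts = counts)
}

#' Run a named end-to-end scenario
#'
#' Orchestrates the package's main computations and writes result files,
#' a resolved-config log and a manifest to `out_dir`. Available scenarios:
#' \describe{
#'   \item{`"escort-exponents"`}{Escort-exponent optimization on the
#'     orientation prior for both objectives.}
#'   \item{`"allocation-scenarios"`}{The three resource-allocation scenarios
#'     (accuracy, linear reward, non-monotonic reward with threshold).}
#'   \item{`"staircase-calibration"`}{Simulated staircase sessions and their
#'     accuracy summary.}
#'   \item{`"recovery-study"`}{Generate one synthetic cohort and refit it,
#'     writing posterior summaries.}
#' }
#'
#' @param scenario Scenario name.
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed; every stochastic stage derives its own seed from
#'   it.
#' @param config Optional list of scenario-specific overrides (e.g.
#'   `n_subjects`, `n_trials`, `chains`).
#' @return Invisibly, the manifest tibble of written files.
#' @export
run_pipeline <- function(scenario, out_dir, seed = 1L, config = list()) {
  known <- c("escort-exponents", "allocation-scenarios",
             "staircase-calibration", "recovery-study")
  if (!scenario %in% known) {
    stop_fitmax(sprintf("Unknown scenario '%s'. Available: %s", scenario,
                        paste(known, collapse = ", ")), "fitmax_range_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(df, path)
    files <<- c(files, name)
    path
  }
  if (scenario == "escort-exponents") {
    pr <- orientation_prior(domain = stimulus_domain(0, 180, TRUE, 512))
    rmap <- reward_map(stimulus_domain(0, 180, TRUE, 512), "linear", 0, 1)
    acc <- optimize_escort_exponent(pr, "accuracy", n = config$n %||% 20)
    rew <- optimize_escort_exponent(pr, "reward", reward = rmap,
                                    n = config$n %||% 20)
    put(dplyr::bind_rows(glance(acc), glance(rew)), "escort_optima.tsv")
    hh <- escort_response(pr, rew$gamma_star)
    put(tibble::as_tibble(hh[, c("s", "h")]), "reward_response.tsv")
  } else if (scenario == "allocation-scenarios") {
    rows <- list()
    for (sc in 1:3) {
      st <- scenario_setup(sc)
      sol <- optimize_allocation(st$prior, st$reward, st$objective,
                                 tau_search = st$tau_search,
                                 restarts = config$restarts %||% 1L,
                                 seed = derive_seed(seed, paste0("alloc", sc)))
      put(tidy(sol), sprintf("allocation_scenario%d.tsv", sc))
      rows[[sc]] <- dplyr::mutate(glance(sol), scenario = sc)
    }
    put(dplyr::bind_rows(rows), "allocation_losses.tsv")
  } else if (scenario == "staircase-calibration") {
    pr <- orientation_prior()
    prd <- orientation_prior(domain = stimulus_domain(0, 45))
    k <- calibrate_k(prd, q = 2, separation = 10, target = 0.9)
    n_subj <- config$n_subjects %||% 30L
    tabs <- lapply(seq_len(n_subj), function(j) {
      cfg <- session_config(
        context = "accuracy", n_decision = config$n_trials %||% 400L,
        observer = observer_params(k, 2),
        seed = derive_seed(seed, paste0("stair", j))
      )
      simulate_decision_session(cfg, pr, subject = sprintf("s%02d", j))
    })
    all_trials <- dplyr::bind_rows(tabs)
    put(all_trials, "staircase_trials.tsv")
    acc <- all_trials |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(accuracy = mean(.data$correct), .groups = "drop")
    put(acc, "staircase_accuracy.tsv")
  } else if (scenario == "recovery-study") {
    pr <- orientation_prior()
    prd <- orientation_prior(domain = stimulus_domain(0, 45))
    k <- calibrate_k(prd, q = config$q %||% 4 / 3, separation = 10, target = 0.9)
    n_subj <- config$n_subjects %||% 10L
    trials <- dplyr::bind_rows(lapply(seq_len(n_subj), function(j) {
      cfg <- session_config(
        context = "reward", n_decision = config$n_trials %||% 200L,
        observer = observer_params(k, config$q %||% 4 / 3),
        seed = derive_seed(seed, paste0("cohort", j))
      )
      simulate_decision_session(cfg, pr, subject = sprintf("s%02d", j))
    }))
    put(trials, "cohort_trials.tsv")
    fit <- fit_hierarchical(trials, pr, fit_config(
      chains = config$chains %||% 3L, burnin = config$burnin %||% 400L,
      draws = config$draws %||% 400L, thin = config$thin %||% 1L,
      seed = derive_seed(seed, "fit")
    ))
    put(tidy(fit, levels = NULL), "posterior_summary.tsv")
    put(fit$draws, "posterior_draws.tsv")
  }
  resolved <- list(scenario = scenario, seed = seed, config = config,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(resolved, file.path(out_dir, "resolved_config.yml"))
  files <- c(files, "resolved_config.yml")
  manifest <- tibble::tibble(file = files)
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}

#' Read a scenario configuration file
#'
#' Configuration files are YAML with nested sections (prior, reward,
#' objective, optimizer settings). An `include` key merges another file
#' first.
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$include)) {
    base <- read_scenario_config(file.path(dirname(path), cfg$include))
    cfg$include <- NULL
    cfg <- utils::modifyList(base, cfg)
  }
  cfg
}
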