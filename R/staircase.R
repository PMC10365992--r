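#' Weighted up-down staircase
#'
#' Adaptive difficulty control for the two-alternative task: the diagonality
#' separation between the two stimuli shrinks after correct responses and
#' grows after errors, with a 3:1 up:down step ratio whose stationary point is
#' 75% accuracy (the separation decreases by `step_up / 3` after a correct
#' response and increases by `step_up` after an error; in equilibrium
#' \eqn{0.75 \cdot step/3 = 0.25 \cdot step}).
#'
#' @param difficulty Starting separation in diagonality degrees (default 10).
#' @param step_up Separation increment after an error, degrees (default 1.5).
#' @param floor,ceiling Bounds on the separation (defaults 0.5 and 30).
#' @return A list of class `fm_staircase`.
#' @export
#' @examples
#' st <- staircase_state()
#' staircase_update(st, correct = TRUE)$difficulty
staircase_state <- function(difficulty = 10, step_up = 1.5, floor = 0.5,
                            ceiling = 30) {
  if (difficulty <= 0) stop_fitmax("`difficulty` must be positive.", "fitmax_range_error")
  structure(
    list(difficulty = difficulty, step_up = step_up, step_down = step_up / 3,
         floor = floor, ceiling = ceiling, trial = 0L),
    class = "fm_staircase"
  )
}

#' @param state An `fm_staircase`.
#' @param correct Was the last response correct?
#' @rdname staircase_state
#' @export
staircase_update <- function(state, correct) {
  d <- state$difficulty + if (isTRUE(correct)) -state$step_down else state$step_up
  state$difficulty <- min(max(d, state$floor), state$ceiling)
  state$trial <- state$trial + 1L
  state
}

#' Draw stimuli from a prior by inverse-CDF sampling
#'
#' @param prior An `fm_prior`.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of stimulus values.
#' @export
sample_stimuli <- function(prior, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cdf <- prior_cdf(prior)
  keep <- c(TRUE, diff(cdf) > 0)
  approx(cdf[keep], prior$s[keep], xout = runif(n), rule = 2,
         ties = "ordered")$y
}

#' Calibrate the capacity scale to a target discrimination level
#'
#' Finds `k` such that an observer with exponent `q` discriminates
#' diagonality pairs separated by `separation` degrees at the target accuracy,
#' averaged over reference stimuli drawn from the prior.
#'
#' @param prior_diag The diagonality-axis prior (domain `[0, 45]`).
#' @param q Power-law exponent.
#' @param separation Baseline separation in degrees (default 10).
#' @param target Target proportion correct at that separation (default 0.9).
#' @return Calibrated `k` (scalar).
#' @export
calibrate_k <- function(prior_diag, q, separation = 10, target = 0.9) {
  dom <- prior_domain(prior_diag)
  d <- seq(dom$lower, dom$upper - separation, length.out = 201)
  w <- prior_density_at(prior_diag, d)
  w <- w / sum(w)
  acc_at <- function(k) {
    obs <- observer_params(k, q)
    p <- choice_probability(d + separation, d, prior_diag, obs)
    sum(w * p)
  }
  stats::uniroot(function(lk) acc_at(exp(lk)) - target,
                 lower = log(1e-2), upper = log(1e8))$root |> exp()
}
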