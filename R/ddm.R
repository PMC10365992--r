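#' Drift-diffusion decision process configuration
#'
#' Decisions and reaction times are generated by a symmetric drift-diffusion
#' process with constant bound `b`, drift equal to the decision evidence and
#' unit diffusion noise (the noise scale is a free normalization of the DDM
#' and is fixed to 1).
#'
#' @param b Decision bound, positive, in evidence units.
#' @param eta Reaction-time cost per time unit, nonnegative.
#' @return A list of class `fm_ddm`.
#' @export
ddm_config <- function(b, eta = 0) {
  if (!is.numeric(b) || b <= 0) stop_fitmax("`b` must be positive.", "fitmax_range_error")
  if (eta < 0) stop_fitmax("`eta` must be nonnegative.", "fitmax_range_error")
  structure(list(b = b, sigma = 1, eta = eta), class = "fm_ddm")
}

#' Decision evidence for a stimulus pair under an allocation
#'
#' \eqn{z(s_1, s_2) = |E[\hat s_1] - E[\hat s_2]| / \sqrt{1/J(s_1) +
#' 1/J(s_2)}} — the standardized mean difference of the two estimators, i.e.
#' the (unsigned) probit argument of the choice rule.
#'
#' @param s1,s2 Stimulus values (vectors of equal length).
#' @param alloc An [allocation()].
#' @return Nonnegative evidence values.
#' @export
ddm_evidence <- function(s1, s2, alloc) {
  j1 <- attr(alloc, "k") * allocation_at(alloc, s1)
  j2 <- attr(alloc, "k") * allocation_at(alloc, s2)
  if (any(j1 <= 0) || any(j2 <= 0)) {
    stop_fitmax("Zero Fisher information at a stimulus: infinite variance.",
                "fitmax_range_error")
  }
  mom <- allocation_moments(alloc, c(s1, s2))
  n <- length(s1)
  abs(mom$mean[seq_len(n)] - mom$mean[n + seq_len(n)]) / sqrt(1 / j1 + 1 / j2)
}

#' DDM error probability
#'
#' Closed form for the constant-bound diffusion: \eqn{P(error) = 1 / (1 +
#' e^{2 b z})}, the logistic counterpart of the probit choice rule.
#'
#' @param z Decision evidence, nonnegative.
#' @param config A [ddm_config()].
#' @return Error probabilities.
#' @export
ddm_error_prob <- function(z, config) {
  1 / (1 + exp(2 * config$b * z))
}

#' DDM mean decision time
#'
#' \eqn{E[RT] = (b/z) \tanh(b z)}, with the analytic limit \eqn{b^2} at
#' \eqn{z = 0}.
#'
#' @inheritParams ddm_error_prob
#' @return Mean first-passage times.
#' @export
ddm_mean_rt <- function(z, config) {
  b <- config$b
  ifelse(z < 1e-12, b^2, (b / z) * tanh(b * z))
}

#' Simulate DDM first passages (simulation oracle)
#'
#' Euler-Maruyama paths of the constant-bound diffusion; used as the
#' independent check of the closed forms. Discrete monitoring systematically
#' misses between-step boundary crossings (an \eqn{O(\sqrt{dt})} first-passage
#' bias), so by default the monitored bound is shrunk by the standard
#' continuity correction \eqn{0.5826 \sigma \sqrt{dt}}.
#'
#' @param z Drift (evidence).
#' @param b Bound.
#' @param n_paths Number of simulated paths.
#' @param dt Time step.
#' @param seed Integer seed.
#' @param t_max Safety cap on path duration.
#' @param correct_discrete Apply the continuity correction (default TRUE).
#' @return List with empirical `p_error`, `mean_rt` and their standard errors.
#' @export
simulate_ddm <- function(z, b, n_paths = 1e5, dt = 1e-3, seed = 1L,
                         t_max = 60, correct_discrete = TRUE) {
  set.seed(derive_seed(seed, "ddm"))
  if (correct_discrete) b <- b - 0.5826 * sqrt(dt)
  x <- numeric(n_paths)
  t_hit <- rep(NA_real_, n_paths)
  hit_lower <- logical(n_paths)
  alive <- seq_len(n_paths)
  sdt <- sqrt(dt)
  t <- 0
  while (length(alive) > 0 && t < t_max) {
    t <- t + dt
    x[alive] <- x[alive] + z * dt + sdt * rnorm(length(alive))
    up <- x[alive] >= b
    dn <- x[alive] <= -b
    done <- up | dn
    if (any(done)) {
      idx <- alive[done]
      t_hit[idx] <- t
      hit_lower[idx] <- dn[done]
      alive <- alive[!done]
    }
  }
  p <- mean(hit_lower, na.rm = TRUE)
  rt <- t_hit[!is.na(t_hit)]
  list(
    p_error = p, se_p = sqrt(p * (1 - p) / n_paths),
    mean_rt = mean(rt), se_rt = sd(rt) / sqrt(length(rt))
  )
}

#' Expected loss with reaction-time costs
#'
#' Pair quadrature of \eqn{f(s_1) f(s_2) [P(error) \cdot cost + \eta \,
#' E[RT]]} under the DDM closed forms, with cost 1 (accuracy context) or the
#' forgone reward difference (reward context).
#'
#' @inheritParams scenario_loss
#' @param config A [ddm_config()] carrying the bound and the RT cost `eta`.
#' @return Expected loss (scalar).
#'
#' Uses the logistic psychometric of the constant-bound diffusion in place of
#' the probit, as appropriate for the DDM closed forms.
#' @export
rt_loss <- function(alloc, config, prior, reward,
                    objective = c("accuracy", "reward"), n_s = 101L,
                    n_band = 41L) {
  objective <- match.arg(objective)
  if (config$eta == 0) {
    warn("With eta = 0 the optimal bound diverges (no time pressure).",
         class = "fitmax_eta_zero")
  }
  expected_pair_loss(alloc, prior, reward, objective, tau = NULL, ddm = config,
                     n_s = n_s, n_band = n_band)
}

#' Jointly optimize allocation shape and decision bound under RT costs
#'
#' Alternates quasi-Newton updates of the allocation knots with a 1-D search
#' over the decision bound, minimizing [rt_loss()] for a given RT cost `eta`.
#'
#' @inheritParams optimize_allocation
#' @param eta RT cost per time unit, positive.
#' @param b_range Search interval for the bound.
#' @param n_rounds Number of alternation rounds.
#' @return An `fm_scenario_solution` with an additional `bound` element (b*).
#' @export
optimize_allocation_rt <- function(prior, reward,
                                   objective = c("accuracy", "reward"),
                                   eta, capacity = sqrt(5000), beta_cap = 0.5,
                                   n_knots = 12L, seed = 1L, maxit = 120L,
                                   b_range = c(0.05, 20), n_rounds = 2L,
                                   n_s = 101L, n_band = 41L) {
  objective <- match.arg(objective)
  if (eta <= 0) stop_fitmax("`eta` must be positive.", "fitmax_range_error")
  dom <- prior_domain(prior)
  obj <- function(v, b) {
    al <- knots_to_allocation(v, dom, capacity, beta_cap)
    rt_loss(al, ddm_config(b, eta), prior, reward, objective, n_s = n_s,
            n_band = n_band)
  }
  v <- rep(0, n_knots)
  b <- 1
  fit <- NULL
  for (r in seq_len(n_rounds)) {
    b <- optimize(function(bb) obj(v, bb), lower = b_range[1],
                  upper = b_range[2], tol = 1e-4)$minimum
    fit <- optim(v, obj, b = b, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-9))
    v <- fit$par
  }
  b <- optimize(function(bb) obj(v, bb), lower = b_range[1],
                upper = b_range[2], tol = 1e-5)$minimum
  al <- knots_to_allocation(v, dom, capacity, beta_cap)
  structure(
    list(
      allocation = al, tau = NULL, bound = b, loss = obj(v, b), knots = v,
      converged = identical(fit$convergence, 0L), objective = objective,
      eta = eta
    ),
    class = "fm_scenario_solution"
  )
}
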