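#' Normalized Fisher-information allocations
#'
#' An allocation describes how encoding precision is spread over the stimulus
#' space: \eqn{J(s) = k \tilde f(s)} with the shape \eqn{\tilde f}
#' normalized to integrate to 1. The scale `k` is derived from a capacity
#' budget \eqn{c = \int J(s)^{\beta} ds} with capacity exponent `beta_cap`
#' (default 0.5, the conventional choice under which the closed-form optima
#' are \eqn{J \propto f^2} for accuracy and \eqn{J \propto f^{4/3}} for
#' linear reward).
#'
#' @param domain An [stimulus_domain()].
#' @param f_tilde Vectorized function or vector of (unnormalized) allocation
#'   values on the domain grid.
#' @param capacity Capacity budget `c` (see above).
#' @param beta_cap Capacity exponent, positive.
#' @return An `fm_allocation`: tibble with columns `s`, `f_tilde`, carrying
#'   `k`, `capacity` and `beta_cap` as attributes.
#' @export
#' @examples
#' al <- allocation(stimulus_domain(0, 1), function(s) exp(-2 * s))
#' attr(al, "k")
allocation <- function(domain, f_tilde, capacity = sqrt(2e5), beta_cap = 0.5) {
  s <- domain_grid(domain)
  v <- if (is.function(f_tilde)) f_tilde(s) else as.numeric(f_tilde)
  if (any(v < 0)) stop_fitmax("Allocation must be nonnegative.", "fitmax_range_error")
  v <- v / trapz(s, v)
  k <- (capacity / trapz(s, v^beta_cap))^(1 / beta_cap)
  out <- tibble::tibble(s = s, f_tilde = v)
  attr(out, "domain") <- domain
  attr(out, "k") <- k
  attr(out, "capacity") <- capacity
  attr(out, "beta_cap") <- beta_cap
  class(out) <- c("fm_allocation", class(out))
  out
}

allocation_at <- function(alloc, s) {
  approx(alloc$s, alloc$f_tilde, xout = s, rule = 2)$y
}

#' A right-skewed scenario prior on the unit interval
#'
#' Monotonically decreasing (truncated-exponential) stimulus prior used by the
#' resource-allocation scenarios, mirroring the cardinal-heavy statistics of
#' the orientation experiments on a generic bounded attribute.
#'
#' @param rate Exponential decay rate (default 2.5).
#' @param domain Domain, default the unit interval.
#' @return An `fm_prior`.
#' @export
skewed_prior <- function(rate = 2.5, domain = stimulus_domain(0, 1)) {
  prior_from_density(domain, function(s) exp(-rate * s))
}

#' Relative decoded value under a categorization threshold
#'
#' With a non-monotonic stimulus-reward map the agent can decode relative to a
#' learned threshold: \eqn{\tilde s = -|\tau - \hat s|}, and choose the
#' alternative with the larger relative value. With the threshold at the
#' domain maximum and a monotonic reward map this ranking coincides with
#' ranking by \eqn{\hat s} itself.
#'
#' @param s_hat Decoded stimulus value(s).
#' @param tau Categorization threshold.
#' @return \eqn{-|\tau - \hat s|}, vectorized.
#' @export
relative_value <- function(s_hat, tau) -abs(tau - s_hat)

# estimator moments induced by an allocation: variance = 1/(k f~) (inverse
# Fisher information). The estimator mean is taken as the true stimulus: the
# generic-prior bias correction, (1/k) d/ds (1/f~), is O(1/k) and negligible
# in the low-noise regime the optimizers run in, and feeding the derivative
# form to an optimizer would let it exploit the approximation outside its
# validity (a steep 1/f~ fakes separation of the decoded means). Set
# `include_bias = TRUE` to evaluate the correction for diagnostics.
allocation_moments <- function(alloc, s, include_bias = FALSE) {
  k <- attr(alloc, "k")
  vr <- 1 / (k * pmax(allocation_at(alloc, s), 1e-12))
  if (!include_bias) {
    return(list(mean = s, var = vr))
  }
  inv <- 1 / pmax(alloc$f_tilde, 1e-12)
  dinv <- c(
    diff(inv[1:2]) / diff(alloc$s[1:2]),
    (inv[-(1:2)] - inv[seq_len(length(inv) - 2L)]) /
      (alloc$s[-(1:2)] - alloc$s[seq_len(length(inv) - 2L)]),
    diff(inv[(length(inv) - 1L):length(inv)]) /
      diff(alloc$s[(length(inv) - 1L):length(inv)])
  )
  bias <- (1 / k) * approx(alloc$s, dinv, xout = s, rule = 2)$y
  list(mean = s + bias, var = vr)
}

# adaptive pair quadrature: outer trapezoid over s1, inner trapezoid over s2
# on a union of (i) a band around s2 = s1 scaled to the local discrimination
# sd, (ii) a mirror band around s2 = 2 tau - s1 when a threshold rule is in
# play (pairs straddling the threshold are confusable however far apart), and
# (iii) a coarse global grid when a DDM time cost is present (mean RT decays
# only like 1/z, so distant pairs still contribute). Outside these regions the
# integrand is numerically zero and the sparse global points carry it.
expected_pair_loss <- function(alloc, prior, reward, objective, tau = NULL,
                               ddm = NULL, n_s = 101L, n_band = 41L) {
  dom <- attr(alloc, "domain")
  lo <- dom$lower; hi <- dom$upper
  k <- attr(alloc, "k")
  fa <- approxfun(alloc$s, pmax(alloc$f_tilde, 1e-12), rule = 2)
  pf <- approxfun(prior$s, prior$density, rule = 2)
  rf <- approxfun(reward$s, reward$reward, rule = 2)
  # outer grid: uniform, plus refinement inside the boundary layers (the
  # inner error integral drops over a width of one discrimination sd at the
  # domain ends, which a uniform outer grid would smear into a spurious
  # O(grid-step) edge region)
  sd_lo <- sqrt(1 / (k * fa(lo)))
  sd_hi <- sqrt(1 / (k * fa(hi)))
  s1 <- sort(unique(c(
    seq(lo, hi, length.out = n_s),
    lo + sd_lo * seq(0.25, 8, length.out = 16),
    hi - sd_hi * seq(0.25, 8, length.out = 16)
  )))
  s1 <- s1[s1 >= lo & s1 <= hi]
  n_s_eff <- length(s1)
  w1 <- trapz_weights(s1) * pf(s1)
  w1 <- w1 / sum(w1)
  v1 <- 1 / (k * fa(s1))
  # band half-widths from the local (and band-edge) estimator sd
  wd <- 6 * sqrt(2 * v1)
  for (rep_ in 1:2) {
    ve <- pmax(1 / (k * fa(pmin(s1 + wd, hi))), 1 / (k * fa(pmax(s1 - wd, lo))))
    wd <- 6 * sqrt(v1 + ve)
  }
  offs <- seq(-1, 1, length.out = n_band)
  gmat <- outer(s1, rep(1, n_band)) + outer(wd, offs)
  if (!is.null(tau)) {
    mir <- 2 * tau - s1
    overlap <- abs(s1 - mir) <= 2 * wd
    a1 <- s1 - wd; b1 <- s1 + wd
    a2 <- mir - wd; b2 <- mir + wd
    # merged, abutting halves where the direct and mirror bands overlap
    cen <- (pmin(a1, a2) + pmax(b1, b2)) / 2
    a1 <- ifelse(overlap, pmin(s1, mir) - wd, a1)
    b1 <- ifelse(overlap, cen, b1)
    a2 <- ifelse(overlap, cen, a2)
    b2 <- ifelse(overlap, pmax(s1, mir) + wd, b2)
    half <- function(a, b) outer(a, 1 - (offs + 1) / 2) + outer(b, (offs + 1) / 2)
    gmat <- cbind(half(a1, b1), half(a2, b2))
  }
  if (!is.null(ddm)) {
    gmat <- cbind(gmat, matrix(seq(lo, hi, length.out = n_band), n_s_eff,
                               n_band, byrow = TRUE))
  }
  if (!is.null(tau) || !is.null(ddm)) gmat <- t(apply(gmat, 1L, sort))
  gmat <- pmin(pmax(gmat, lo), hi)
  nb <- ncol(gmat)
  v2 <- 1 / (k * fa(gmat))
  dim(v2) <- dim(gmat)
  if (is.null(tau)) {
    dm <- s1 - gmat
  } else {
    dm <- -abs(tau - s1) + abs(tau - gmat)
    dim(dm) <- dim(gmat)
  }
  zs <- dm / sqrt(v1 + v2)
  p1 <- if (!is.null(ddm)) 1 / (1 + exp(-2 * ddm$b * zs)) else pnorm(zs)
  rdif <- rf(s1) - rf(gmat)
  dim(rdif) <- dim(gmat)
  # reward ties take the fair-coin limit 0.5: the diagonal s1 = s2 has
  # measure zero but its neighbourhood carries real error mass, and zeroing
  # the tie point would punch an O(h) hole at the error kernel's peak
  perr <- (rdif > 0) * (1 - p1) + (rdif < 0) * p1 + (rdif == 0) * 0.5
  # the accuracy objective charges every error equally; reward magnitudes
  # only define the ordering (assumed strict except on the tie set)
  cost <- if (objective == "accuracy") 1 else abs(rdif)
  integrand <- perr * cost
  if (!is.null(ddm)) {
    z <- abs(zs)
    bz <- ddm$b * z
    ert <- ifelse(z < 1e-12, ddm$b^2, (ddm$b / z) * tanh(bz))
    integrand <- integrand + ddm$eta * ert
  }
  y <- pf(gmat) * integrand
  dim(y) <- dim(gmat)
  dx <- gmat[, -1L, drop = FALSE] - gmat[, -nb, drop = FALSE]
  inner <- rowSums(dx * (y[, -1L, drop = FALSE] + y[, -nb, drop = FALSE]) / 2)
  sum(w1 * inner)
}

#' Expected decision loss of an allocation
#'
#' Quadrature over i.i.d. stimulus pairs of the probability of choosing the
#' lower-valued alternative times its cost: 1 per error for the accuracy
#' objective, the forgone reward difference \eqn{|R(s_1) - R(s_2)|} for the
#' reward objective. Choices follow the probit rule induced by the
#' allocation's estimator moments; when a threshold `tau` is given, decoded
#' values are compared through [relative_value()]. The pair integral is
#' evaluated by an adaptive band quadrature that resolves the local
#' discrimination scale.
#'
#' @param alloc An [allocation()].
#' @param prior An `fm_prior` on the same domain.
#' @param reward An `fm_reward_map`.
#' @param objective `"accuracy"` or `"reward"`.
#' @param tau Optional categorization threshold.
#' @param n_s Number of outer quadrature nodes.
#' @param n_band Number of inner band nodes.
#' @return Expected loss (scalar).
#' @export
scenario_loss <- function(alloc, prior, reward,
                          objective = c("accuracy", "reward"), tau = NULL,
                          n_s = 101L, n_band = 41L) {
  objective <- match.arg(objective)
  k <- attr(alloc, "k")
  dom <- attr(alloc, "domain")
  # high-SNR sanity: sparsest-point discrimination sd vs domain width
  sd_max <- sqrt(1 / (k * max(min(alloc$f_tilde), 1e-12)))
  if (sd_max > 0.2 * (dom$upper - dom$lower)) {
    warn("Allocation scale is low for the high-SNR approximation.",
         class = "fitmax_low_snr")
  }
  expected_pair_loss(alloc, prior, reward, objective, tau = tau,
                     n_s = n_s, n_band = n_band)
}

# build an allocation from knot log-values via a natural cubic interpolant
knots_to_allocation <- function(v, domain, capacity, beta_cap, n_grid = 257L) {
  kx <- seq(domain$lower, domain$upper, length.out = length(v))
  fn <- splinefun(kx, v, method = "natural")
  g <- seq(domain$lower, domain$upper, length.out = n_grid)
  dom2 <- stimulus_domain(domain$lower, domain$upper, domain$circular,
                          n_grid = n_grid)
  allocation(dom2, exp(fn(g) - max(v)), capacity = capacity,
             beta_cap = beta_cap)
}

#' Numerically optimize the Fisher-information allocation
#'
#' Minimizes [scenario_loss()] over allocation shapes parameterized as the
#' normalized exponential of a natural-cubic interpolant through `n_knots`
#' values, under the capacity budget. Optimization is quasi-Newton (BFGS with
#' numerical gradients) from a flat start plus seeded random restarts. When
#' `tau_search = TRUE` the categorization threshold is optimized jointly by
#' alternating golden-section threshold updates with allocation updates.
#'
#' @inheritParams scenario_loss
#' @param capacity,beta_cap Capacity budget and exponent (see [allocation()]).
#' @param tau_search Jointly optimize the threshold?
#' @param n_knots Number of shape knots (default 12).
#' @param restarts Number of seeded random restarts (default 3).
#' @param seed Integer seed for the restarts.
#' @param maxit BFGS iteration cap per start.
#'
#' The default capacity puts the optimizer deep in the low-noise regime
#' (discrimination sd well below the prior's variation scale), where the
#' monotonic-scenario optima approach the power-law closed forms.
#' @return An `fm_scenario_solution`: list with the optimal `allocation`,
#'   `tau` (or `NULL`), achieved `loss`, `converged` flag and the knot values.
#' @export
optimize_allocation <- function(prior, reward,
                                objective = c("accuracy", "reward"),
                                capacity = sqrt(2e5), beta_cap = 0.5,
                                tau_search = FALSE, n_knots = 12L,
                                restarts = 3L, seed = 1L, maxit = 200L,
                                n_s = 101L, n_band = 41L) {
  objective <- match.arg(objective)
  dom <- prior_domain(prior)
  obj <- function(v, tau) {
    al <- knots_to_allocation(v, dom, capacity, beta_cap)
    suppressWarnings(scenario_loss(al, prior, reward, objective, tau = tau,
                                   n_s = n_s, n_band = n_band))
  }
  run_bfgs <- function(v0, tau) {
    optim(v0, obj, tau = tau, method = "BFGS",
          control = list(maxit = maxit, reltol = 1e-9))
  }
  tau <- if (tau_search) (dom$lower + dom$upper) / 2 else NULL
  best <- NULL
  set.seed(derive_seed(seed, "optimize_allocation"))
  # multi-start: flat, power-law-family shapes (log f at the knots times a
  # few exponents), and seeded random perturbations; the objective alone
  # selects among the polished candidates
  kx <- seq(dom$lower, dom$upper, length.out = n_knots)
  lf <- log(pmax(prior_density_at(prior, kx), 1e-12))
  starts <- c(list(rep(0, n_knots)),
              lapply(c(1, 4 / 3, 2), function(qq) qq * (lf - mean(lf))),
              lapply(seq_len(max(0L, restarts - 1L)),
                     function(i) rnorm(n_knots, 0, 0.5)))
  for (v0 in starts) {
    v <- v0
    fit <- NULL
    rounds <- if (tau_search) 3L else 1L
    for (r in seq_len(rounds)) {
      fit <- run_bfgs(v, tau)
      v <- fit$par
      if (tau_search) {
        tau <- golden_section(function(tt) obj(v, tt), dom$lower, dom$upper,
                              tol = 1e-4)$minimum
      }
    }
    cand <- list(par = v, value = obj(v, tau), tau = tau,
                 convergence = fit$convergence)
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  al <- knots_to_allocation(best$par, dom, capacity, beta_cap)
  structure(
    list(
      allocation = al, tau = if (tau_search) best$tau else NULL,
      loss = best$value, knots = best$par,
      converged = identical(best$convergence, 0L),
      objective = objective
    ),
    class = "fm_scenario_solution"
  )
}

#' @export
print.fm_scenario_solution <- function(x, ...) {
  cat(sprintf(
    "<allocation solution: %s objective, loss = %.5g%s%s>\n",
    x$objective, x$loss,
    if (!is.null(x$tau)) sprintf(", tau = %.3f", x$tau) else "",
    if (!is.null(x$bound)) sprintf(", b* = %.3f", x$bound) else ""
  ))
  invisible(x)
}

#' Closed-form power-law allocation for a prior
#'
#' The analytic optimum for monotonic objectives: shape proportional to
#' \eqn{f(s)^q}. Used as the oracle the numerical optimizer is checked
#' against.
#'
#' @param prior An `fm_prior`.
#' @param q Power-law exponent.
#' @inheritParams allocation
#' @return An `fm_allocation` on the prior's grid.
#' @export
power_law_allocation <- function(prior, q, capacity = sqrt(2e5),
                                 beta_cap = 0.5) {
  allocation(prior_domain(prior), prior$density^q, capacity = capacity,
             beta_cap = beta_cap)
}

#' Standard resource-allocation scenarios
#'
#' Bundles the three study scenarios on the unit domain with the right-skewed
#' prior: (1) accuracy maximization, (2) reward maximization with a linear
#' stimulus-reward map, (3) reward maximization with a symmetric raised-cosine
#' map peaking mid-domain (non-monotonic), where a categorization threshold is
#' optimized jointly with the allocation.
#'
#' @param scenario 1, 2 or 3.
#' @param n_grid Grid size of the shared domain.
#' @return A list with `prior`, `reward`, `objective` and `tau_search`.
#' @export
#' @examples
#' sc <- scenario_setup(2)
#' sc$objective
scenario_setup <- function(scenario, n_grid = 257L) {
  dom <- stimulus_domain(0, 1, n_grid = n_grid)
  pr <- skewed_prior(2.5, dom)
  sg <- seq(0, 1, by = 0.005)
  switch(as.character(scenario),
    "1" = list(prior = pr,
               reward = reward_map(dom, "linear", intercept = 0, slope = 1),
               objective = "accuracy", tau_search = FALSE),
    "2" = list(prior = pr,
               reward = reward_map(dom, "linear", intercept = 0, slope = 1),
               objective = "reward", tau_search = FALSE),
    "3" = list(prior = pr,
               reward = reward_map(dom, "tabulated", s = sg,
                                   reward = 0.5 * (1 - cos(2 * pi * sg))),
               objective = "reward", tau_search = TRUE),
    stop_fitmax("`scenario` must be 1, 2 or 3.", "fitmax_range_error")
  )
}
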