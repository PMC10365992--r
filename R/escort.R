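#' Escort-distribution response function
#'
#' The candidate neural response functions studied here are cumulative escort
#' distributions of the stimulus prior: \eqn{h(s) = \int_{lower}^s f^\gamma /
#' \int_{domain} f^\gamma}. At \eqn{\gamma = 1} the response equals the prior
#' CDF (the infomax solution); smaller \eqn{\gamma} spreads response resolution
#' toward rare stimuli. \eqn{\gamma} relates to the \eqn{L_p} reconstruction
#' penalty through \eqn{\gamma = 1/(1+p)}.
#'
#' @param prior An `fm_prior`.
#' @param gamma Escort exponent, positive.
#'
#' @return An `fm_response`: tibble with columns `s` and `h` (`h` nondecreasing
#'   from 0 to 1), with the prior and `gamma` attached as attributes.
#' @export
#' @examples
#' h <- escort_response(orientation_prior(), gamma = 2 / 3)
#' range(h$h)
escort_response <- function(prior, gamma) {
  if (!is.numeric(gamma) || gamma <= 0) {
    stop_fitmax("`gamma` must be positive.", "fitmax_range_error")
  }
  check_normalized(prior)
  g <- prior$density^gamma
  h <- cumtrapz(prior$s, g)
  h <- h / h[length(h)]
  out <- tibble::tibble(s = prior$s, h = h)
  attr(out, "prior") <- prior
  attr(out, "gamma") <- gamma
  class(out) <- c("fm_response", class(out))
  out
}

#' Exponent algebra of power-law efficient codes
#'
#' Links the four exponents of the framework: the \eqn{L_p} penalty exponent
#' `p`, the escort exponent `gamma` (\eqn{\gamma = 1/(1+p)}), the
#' capacity-constraint exponent `beta_cap` and the power-law Fisher exponent
#' `q`. Under a capacity bound on \eqn{\int J^{\beta}} and objective exponent
#' \eqn{\alpha}, the optimal Fisher allocation is \eqn{J \propto f^q} with
#' \eqn{q = 1/(\beta+\alpha)} and \eqn{\gamma = \beta/(\beta+\alpha)}, hence
#' \eqn{q = \gamma/\beta}. With the conventional `beta_cap = 0.5`, the
#' accuracy-maximizing code (`gamma = 1`) gives `q = 2` and the linear-reward
#' code (`gamma = 2/3`) gives `q = 4/3`.
#'
#' @param p \eqn{L_p} exponent, nonnegative. Supply exactly one of `p`, `gamma`.
#' @param gamma Escort exponent in (0, 1].
#' @param beta_cap Capacity exponent, positive; defaults to 0.5.
#'
#' @return A list of class `fm_exponents` with fields `p`, `gamma`, `q`,
#'   `beta_cap` and `alpha_obj`.
#' @export
#' @examples
#' exponent_set(gamma = 2 / 3)$q # 4/3
exponent_set <- function(p = NULL, gamma = NULL, beta_cap = 0.5) {
  if (is.null(p) == is.null(gamma)) {
    stop_fitmax("Supply exactly one of `p` or `gamma`.", "fitmax_range_error")
  }
  if (!is.numeric(beta_cap) || beta_cap <= 0) {
    stop_fitmax("`beta_cap` must be positive.", "fitmax_range_error")
  }
  if (is.null(gamma)) {
    if (p < 0) stop_fitmax("`p` must be nonnegative.", "fitmax_range_error")
    gamma <- 1 / (1 + p)
  } else {
    if (gamma <= 0 || gamma > 1) {
      stop_fitmax("`gamma` must lie in (0, 1].", "fitmax_range_error")
    }
    p <- 1 / gamma - 1
  }
  structure(
    list(
      p = p, gamma = gamma, beta_cap = beta_cap,
      q = gamma / beta_cap,
      alpha_obj = beta_cap * (1 / gamma - 1)
    ),
    class = "fm_exponents"
  )
}

#' @export
print.fm_exponents <- function(x, ...) {
  cat(sprintf(
    "<power-law code exponents: p = %.4g, gamma = %.4g, q = %.4g (beta = %.4g, alpha = %.4g)>\n",
    x$p, x$gamma, x$q, x$beta_cap, x$alpha_obj
  ))
  invisible(x)
}

#' Quantize a response function into n discrete levels
#'
#' A channel limited to `n` response levels is modelled as a step function
#' climbing by 1/n at each boundary; stimuli falling in the same level are
#' indistinguishable downstream. Boundaries are the stimuli at which the
#' continuous response crosses i/n, found by monotone interpolation.
#'
#' @param response An `fm_response`.
#' @param n Number of levels, at least 2.
#'
#' @return An `fm_code`: list with `n`, `boundaries` (n - 1 interior cut
#'   points) and the generating response.
#' @export
quantize_code <- function(response, n) {
  n <- as.integer(n)
  if (n < 2L) stop_fitmax("`n` must be at least 2.", "fitmax_range_error")
  h <- response$h
  s <- response$s
  targets <- seq_len(n - 1L) / n
  # a plateau of h at a needed crossing level makes the boundary ill-defined
  span <- diff(range(s)) / length(s)
  for (tg in targets) {
    at <- s[abs(h - tg) < 1e-9]
    if (length(at) > 1L && diff(range(at)) > 3 * span) {
      stop_fitmax(
        sprintf("Response has a degenerate plateau near s in [%.4g, %.4g].",
                min(at), max(at)),
        "fitmax_plateau_error"
      )
    }
  }
  keep <- c(TRUE, diff(h) > 0)
  hs <- h[keep]; ss <- s[keep]
  b <- approx(hs, ss, xout = targets, ties = "ordered")$y
  structure(list(n = n, boundaries = b, response = response), class = "fm_code")
}

#' Stimulus-reward mapping
#'
#' @param domain An [stimulus_domain()].
#' @param kind One of `"constant"`, `"linear"`, `"tabulated"`.
#' @param value Constant reward level (for `"constant"`).
#' @param intercept,slope Affine coefficients (for `"linear"`).
#' @param s,reward Tabulated support points (for `"tabulated"`); values between
#'   points are linearly interpolated.
#'
#' @return An `fm_reward_map`: tibble with columns `s` and `reward` on the
#'   domain grid.
#' @export
#' @examples
#' reward_map(stimulus_domain(0, 45), "linear", intercept = 1, slope = 1)
reward_map <- function(domain, kind = c("constant", "linear", "tabulated"),
                       value = 1, intercept = 0, slope = 1, s = NULL,
                       reward = NULL) {
  kind <- match.arg(kind)
  grid <- domain_grid(domain)
  r <- switch(kind,
    constant = rep(value, length(grid)),
    linear = intercept + slope * grid,
    tabulated = {
      if (is.null(s) || is.null(reward)) {
        stop_fitmax("Tabulated reward maps need `s` and `reward`.", "fitmax_range_error")
      }
      approx(s, reward, xout = grid, rule = 2)$y
    }
  )
  out <- tibble::tibble(s = grid, reward = r)
  attr(out, "kind") <- kind
  attr(out, "domain") <- domain
  class(out) <- c("fm_reward_map", class(out))
  out
}

#' Evaluate a reward map at stimulus values
#'
#' @param map An `fm_reward_map`.
#' @param s Stimulus value(s).
#' @return Interpolated reward values.
#' @export
reward_at <- function(map, s) approx(map$s, map$reward, xout = s, rule = 2)$y

# per-level prior masses of a quantized code
level_masses <- function(prior, code) {
  edges <- c(prior$s[1], code$boundaries, prior$s[length(prior$s)])
  cdf <- cumtrapz(prior$s, prior$density)
  cdf <- cdf / cdf[length(cdf)]
  at <- approx(prior$s, cdf, xout = edges, ties = "ordered")$y
  diff(at)
}

#' Expected probability of an erroneous discrimination
#'
#' Two stimuli are drawn i.i.d. from the prior; the agent can only compare
#' their quantized responses, and resolves within-level ties by a fair coin.
#' The expected error probability is \eqn{\tfrac12 \sum_i m_i^2} where
#' \eqn{m_i} is the prior mass of level i.
#'
#' @param prior An `fm_prior`.
#' @param code An `fm_code`.
#' @return Expected error probability (scalar).
#' @export
prob_error_loss <- function(prior, code) {
  m <- level_masses(prior, code)
  sum(m^2) / 2
}

#' Expected reward loss of a quantized code
#'
#' For two i.i.d. stimuli falling in the same level, the fair-coin tie-break
#' forfeits on average half the absolute reward difference. The loss is
#' \eqn{\sum_i \tfrac12 \iint_{level_i^2} f(s_1) f(s_2) |R(s_1) - R(s_2)|},
#' computed by iterated trapezoid quadrature on each level's sub-grid.
#'
#' @inheritParams prob_error_loss
#' @param reward An `fm_reward_map` on the same domain.
#' @return Expected reward loss per decision (scalar, reward units).
#' @export
reward_loss <- function(prior, code, reward) {
  s <- prior$s
  edges <- c(s[1], code$boundaries, s[length(s)])
  total <- 0
  for (i in seq_len(code$n)) {
    lo <- edges[i]; hi <- edges[i + 1]
    if (hi - lo <= 0) next
    # refined sub-grid within the level so narrow levels keep resolution
    sub <- unique(sort(c(lo, hi, s[s > lo & s < hi])))
    if (length(sub) < 2L) next
    while (length(sub) < 9L) { # refine very narrow levels
      sub <- sort(unique(c(sub, (head(sub, -1) + tail(sub, -1)) / 2)))
    }
    f <- prior_density_at(prior, sub)
    r <- reward_at(reward, sub)
    w <- trapz_weights(sub) * f
    dif <- abs(outer(r, r, "-"))
    total <- total + 0.5 * drop(t(w) %*% dif %*% w)
  }
  total
}

#' Find the fitness-optimal escort exponent for a quantized channel
#'
#' Scans escort response functions \eqn{h_\gamma} quantized to `n` levels and
#' returns the exponent minimizing either the expected error probability
#' (accuracy objective) or the expected reward loss under a reward map. A
#' coarse grid scan is refined by golden-section search around the best grid
#' point.
#'
#' @param prior An `fm_prior` (must not be uniform: with a flat prior all
#'   escort codes coincide and the objective is flat in `gamma`).
#' @param objective `"accuracy"` or `"reward"`.
#' @param reward An `fm_reward_map`, required for the reward objective.
#' @param n Number of response levels.
#' @param gamma_grid Coarse search grid for `gamma`.
#' @param refine_tol Width tolerance of the golden-section refinement.
#'
#' @return A list of class `fm_escort_opt` with `gamma_star`, `loss`,
#'   `objective`, `n` and the scanned `profile` (a tibble of gamma, loss).
#' @export
#' @examples
#' pr <- orientation_prior(domain = stimulus_domain(0, 180, TRUE, 512))
#' optimize_escort_exponent(pr, "accuracy", n = 20)$gamma_star
optimize_escort_exponent <- function(prior, objective = c("accuracy", "reward"),
                                     reward = NULL, n = 20,
                                     gamma_grid = seq(0.3, 1.5, by = 0.02),
                                     refine_tol = 5e-4) {
  objective <- match.arg(objective)
  if (objective == "reward" && is.null(reward)) {
    stop_fitmax("The reward objective needs a reward map.", "fitmax_range_error")
  }
  rng <- range(prior$density)
  if (diff(rng) / max(rng) < 1e-8) {
    warn(paste(
      "Prior is (near-)uniform: all escort codes coincide and the",
      "optimal exponent is undefined."
    ), class = "fitmax_flat_objective")
  }
  loss_at <- function(g) {
    code <- quantize_code(escort_response(prior, g), n)
    if (objective == "accuracy") prob_error_loss(prior, code)
    else reward_loss(prior, code, reward)
  }
  losses <- vapply(gamma_grid, loss_at, numeric(1))
  i <- which.min(losses)
  lo <- gamma_grid[max(1L, i - 1L)]
  hi <- gamma_grid[min(length(gamma_grid), i + 1L)]
  ref <- golden_section(loss_at, lo, hi, tol = refine_tol)
  structure(
    list(
      gamma_star = round(ref$minimum, 3), loss = ref$objective,
      objective = objective, n = n,
      profile = tibble::tibble(gamma = gamma_grid, loss = losses)
    ),
    class = "fm_escort_opt"
  )
}

#' @export
print.fm_escort_opt <- function(x, ...) {
  cat(sprintf("<escort exponent optimum: gamma* = %.3f (%s objective, n = %d, loss = %.4g)>\n",
              x$gamma_star, x$objective, x$n, x$loss))
  invisible(x)
}

#' Push-forward density of the neural response
#'
#' Given a strictly increasing response function, the density of the response
#' r = h(s) when s follows the prior is \eqn{g(r) = f(h^{-1}(r)) /
#' h'(h^{-1}(r))}. Infomax (\eqn{\gamma = 1}) equalizes the response histogram;
#' fitness-maximizing codes deviate from uniformity.
#'
#' @param prior An `fm_prior`.
#' @param response An `fm_response` on the same grid.
#' @param n_r Number of points of the uniform response grid.
#' @return A tibble with columns `r` and `density`, integrating to 1.
#' @export
response_density <- function(prior, response, n_r = 512L) {
  gamma <- attr(response, "gamma")
  # h' = f^gamma / Z on the grid; g(r) = Z * f^{1-gamma} at s = h^{-1}(r)
  fg <- prior$density^gamma
  z <- trapz(prior$s, fg)
  supp <- prior$density > 0
  if (any(fg[supp] <= 0)) {
    stop_fitmax("Response has zero derivative inside the prior support.",
                "fitmax_plateau_error")
  }
  r <- seq(0, 1, length.out = n_r)
  keep <- c(TRUE, diff(response$h) > 0)
  s_of_r <- approx(response$h[keep], response$s[keep], xout = r, rule = 2,
                   ties = "ordered")$y
  f <- prior_density_at(prior, s_of_r)
  g <- z * f^(1 - gamma)
  g <- g / trapz(r, g)
  tibble::tibble(r = r, density = g)
}
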