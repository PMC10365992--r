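#' Observer encoding parameters
#'
#' The encoding channel allocates Fisher information as a power law of the
#' prior: \eqn{J(s) = k f(s)^q}. `k` is the overall capacity (resource) scale
#' and `q` controls how strongly precision follows the prior: `q = 2` is the
#' infomax allocation (under the conventional capacity exponent 0.5) and
#' `q = 4/3` the linear-reward-maximizing one.
#'
#' @param k Capacity scale, positive; `1 / (k f(s)^q)` is the encoding
#'   variance in squared radians, with `f` the per-radian prior density
#'   (user-facing stimuli and moments are in degrees).
#' @param q Power-law exponent, nonnegative.
#' @return A list of class `fm_observer`.
#' @export
observer_params <- function(k, q) {
  if (!is.numeric(k) || k <= 0) stop_fitmax("`k` must be positive.", "fitmax_range_error")
  if (!is.numeric(q) || q < 0) stop_fitmax("`q` must be nonnegative.", "fitmax_range_error")
  structure(list(k = k, q = q), class = "fm_observer")
}

#' Behavioral nuisance parameters of the choice rule
#'
#' @param lambda Lapse rate in `[0, 1]`: probability of a stimulus-independent
#'   random response.
#' @param beta0 Side bias, a dimensionless shift of the probit argument.
#' @return A list of class `fm_behavior`.
#' @export
behavior_params <- function(lambda = 0, beta0 = 0) {
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
    stop_fitmax("`lambda` must lie in [0, 1].", "fitmax_range_error")
  }
  structure(list(lambda = lambda, beta0 = beta0), class = "fm_behavior")
}

#' Fisher information of the power-law code
#'
#' The density entering the power law is normalized per radian (so that the
#' cardinal peaks exceed 1 and the obliques fall below 1, giving the
#' characteristic crossover when `q` changes at fixed `k`); the stimulus
#' axis itself is in degrees.
#'
#' @param s Stimulus value(s), degrees.
#' @param prior An `fm_prior`.
#' @param obs An [observer_params()].
#' @return \eqn{J(s) = k f(s)^q} (precision per squared radian), vectorized.
#' @export
fisher_information <- function(s, prior, obs) {
  obs$k * (prior_density_at(prior, s) * 180 / pi)^obs$q
}

#' Draw noisy internal responses for stimuli
#'
#' The internal response is Gaussian around the true stimulus with variance
#' equal to the inverse Fisher information, \eqn{r \sim N(s, 1/(k f(s)^q))}.
#'
#' @inheritParams fisher_information
#' @param seed Optional integer seed for reproducible draws.
#' @return Numeric vector of internal responses, one per element of `s`.
#' @export
encode_stimulus <- function(s, prior, obs, seed = NULL) {
  dom <- prior_domain(prior)
  if (any(s < dom$lower - 1e-9 | s > dom$upper + 1e-9)) {
    stop_fitmax("Stimulus outside the prior domain.", "fitmax_domain_error")
  }
  if (!is.null(seed)) set.seed(seed)
  sdv <- (180 / pi) / sqrt(fisher_information(s, prior, obs))
  rnorm(length(s), mean = s, sd = sdv)
}

#' Posterior-mean decoding of internal responses
#'
#' Computes the Bayesian posterior over the stimulus grid for each internal
#' response, using the full stimulus-dependent Gaussian likelihood (including
#' its \eqn{\sqrt{k f(s)^q}} normalization), and returns the posterior mean.
#' This grid decoder is the numerical reference for the closed-form moment
#' approximations in [estimate_moments()].
#'
#' @param r Internal response(s).
#' @inheritParams fisher_information
#' @param n_grid Number of decoding grid points (default 2048).
#' @return Posterior-mean estimates, one per response. Responses so far
#'   outside the domain that the posterior mass underflows decode to `NA`
#'   with a warning.
#' @export
decode_posterior_mean <- function(r, prior, obs, n_grid = 2048L) {
  dom <- prior_domain(prior)
  g <- seq(dom$lower, dom$upper, length.out = n_grid)
  f <- prior_density_at(prior, g)
  # precision per squared degree under the radian-normalized power law
  jg <- obs$k * (f * 180 / pi)^obs$q * (pi / 180)^2
  log_pref <- 0.5 * log(jg) + log(pmax(f, 1e-300))
  out <- numeric(length(r))
  chunk <- 4000L
  for (i0 in seq(1L, length(r), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, length(r))
    # log-likelihood matrix: responses in rows, grid in columns
    ll <- -0.5 * outer(r[idx], g, "-")^2 * rep(jg, each = length(idx)) +
      rep(log_pref, each = length(idx))
    ll <- ll - apply(ll, 1L, max)
    w <- exp(ll)
    tot <- rowSums(w)
    bad <- !is.finite(tot) | tot <= 0
    est <- as.numeric(w %*% g) / tot
    est[bad] <- NA_real_
    if (any(bad)) {
      warn("Posterior mass underflow for some responses; returning NA.",
           class = "fitmax_underflow")
    }
    out[idx] <- est
  }
  out
}

#' Closed-form bias and variance of the posterior-mean estimator
#'
#' High signal-to-noise approximations for the power-law Gaussian channel.
#' The estimator mean is \eqn{s_0 + b(s_0)} with
#' \eqn{b(s_0) = (1 - 1/q) (1/k) \, d/ds [f(s)^{-q}]} and the variance follows
#' the Cramer-Rao expression \eqn{1/(k f(s_0)^q)}. For the parametric
#' orientation prior these are evaluated analytically in terms of the
#' steepness `a` and normalizer `omega`; generic priors use a numerical
#' derivative of \eqn{f^{-q}} on the grid.
#'
#' The bias vanishes identically at `q = 1` and, for the orientation prior, at
#' the cardinal and oblique axes where \eqn{\sin 4s = 0}. `q = 0` is rejected:
#' the high-SNR bias approximation is singular there.
#'
#' @param s0 Stimulus value(s), degrees.
#' @inheritParams fisher_information
#' @return A tibble of class `fm_moments` with columns `s0`, `bias`, `mean`
#'   and `var` (degrees and squared degrees).
#' @export
#' @examples
#' pr <- orientation_prior()
#' estimate_moments(c(0, 22.5, 45), pr, observer_params(k = 3000, q = 4 / 3))
estimate_moments <- function(s0, prior, obs) {
  if (obs$q == 0) {
    stop_fitmax(paste(
      "The high-SNR bias approximation is undefined at q = 0",
      "(the (1 - 1/q) factor is singular)."
    ), "fitmax_range_error")
  }
  k <- obs$k; q <- obs$q
  a <- attr(prior, "a")
  deg <- 180 / pi
  if (identical(attr(prior, "kind"), "orientation") && is.finite(a)) {
    omega_r <- attr(prior, "omega") * deg # per-radian normalizer
    th <- 4 * s0 * pi / 180
    dfmq_rad <- 4 * q * sin(th) * (omega_r / (a - cos(th)))^(1 - q) / omega_r
    bias <- (1 - 1 / q) * (1 / k) * dfmq_rad * deg
    vr <- (1 / k) * ((a - cos(th)) / omega_r)^q * deg^2
  } else {
    check_normalized(prior)
    f_rad <- prior$density * deg
    fmq <- f_rad^(-q)
    dnum <- c(
      (fmq[2] - fmq[1]) / (prior$s[2] - prior$s[1]),
      (fmq[-(1:2)] - fmq[seq_len(length(fmq) - 2L)]) /
        (prior$s[-(1:2)] - prior$s[seq_len(length(fmq) - 2L)]),
      (fmq[length(fmq)] - fmq[length(fmq) - 1L]) /
        (prior$s[length(fmq)] - prior$s[length(fmq) - 1L])
    ) * deg # derivative with respect to radians
    dd <- approx(prior$s, dnum, xout = s0, rule = 2)$y
    bias <- (1 - 1 / q) * (1 / k) * dd * deg
    vr <- deg^2 / (k * f_rad^q)
    vr <- approx(prior$s, vr, xout = s0, rule = 2)$y
  }
  out <- tibble::tibble(s0 = s0, bias = bias, mean = s0 + bias, var = vr)
  class(out) <- c("fm_moments", class(out))
  out
}

#' The two forms of the bias proportionality constant
#'
#' The analytical high-SNR derivation gives \eqn{(1 - 1/q)/k}; an earlier
#' simulation-based parametric study proposed \eqn{\log(q)/(k \sqrt q)}. The
#' two agree closely over the exponent range relevant here (roughly
#' \eqn{q \in [0.5, 2]}); both are returned for comparison.
#'
#' @param q Power-law exponent, positive.
#' @param k Capacity scale, positive.
#' @return Named numeric vector with elements `simulation` and `analytic`.
#' @export
bias_constant_pair <- function(q, k) {
  if (q <= 0 || k <= 0) stop_fitmax("`q` and `k` must be positive.", "fitmax_range_error")
  c(simulation = log(q) / (k * sqrt(q)), analytic = (1 - 1 / q) / k)
}

#' Probability of choosing the first of two alternatives
#'
#' Assuming normally distributed estimators with the closed-form moments, the
#' probability of judging stimulus 1 larger (more diagonal, on the folded
#' decision axis) than stimulus 2 is a probit in the standardized mean
#' difference, mixed with a lapse and shifted by a side bias:
#' \deqn{P = \lambda/2 + (1-\lambda)\,\Phi\!\left(\frac{E[\hat s_1]-E[\hat
#' s_2]}{\sqrt{Var_1+Var_2}} + \beta_0\right).}
#'
#' @param s1,s2 Stimuli on the decision axis (vectors of equal length).
#' @inheritParams fisher_information
#' @param behavior A [behavior_params()].
#' @return Vector of probabilities of choosing alternative 1.
#' @export
choice_probability <- function(s1, s2, prior, obs,
                               behavior = behavior_params()) {
  m1 <- estimate_moments(s1, prior, obs)
  m2 <- estimate_moments(s2, prior, obs)
  tv <- m1$var + m2$var
  arg <- ifelse(tv > 0, (m1$mean - m2$mean) / sqrt(tv),
                sign(m1$mean - m2$mean) * Inf)
  arg[tv <= 0 & m1$mean == m2$mean] <- 0
  behavior$lambda / 2 + (1 - behavior$lambda) * pnorm(arg + behavior$beta0)
}

#' Simulate single-trial estimation reports
#'
#' A report is the posterior-mean decode of a noisy encoding of the true
#' stimulus, plus independent zero-mean Gaussian motor noise from the
#' adjustment response, wrapped back into the (circular) domain.
#'
#' @param s0 True stimulus value(s), degrees.
#' @inheritParams fisher_information
#' @param motor_sd Motor noise standard deviation in degrees (default 2).
#' @param seed Optional integer seed.
#' @param n_grid Decoding grid size.
#' @return Numeric vector of reported values, one per element of `s0`.
#' @export
simulate_estimation_report <- function(s0, prior, obs, motor_sd = 2,
                                       seed = NULL, n_grid = 2048L) {
  if (motor_sd < 0) stop_fitmax("`motor_sd` must be nonnegative.", "fitmax_range_error")
  if (!is.null(seed)) set.seed(seed)
  r <- encode_stimulus(s0, prior, obs)
  est <- decode_posterior_mean(r, prior, obs, n_grid = n_grid)
  rep_ <- est + rnorm(length(est), 0, motor_sd)
  dom <- prior_domain(prior)
  if (dom$circular) {
    width <- dom$upper - dom$lower
    rep_ <- ((rep_ - dom$lower) %% width) + dom$lower
  } else {
    rep_ <- pmin(pmax(rep_, dom$lower), dom$upper)
  }
  rep_
}
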