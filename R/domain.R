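#' Define a bounded one-dimensional stimulus domain
#'
#' All coding-theory and observer computations run on a fixed evaluation grid
#' over a bounded stimulus interval. The domain may be flagged circular (as for
#' edge orientation, which wraps at 180 degrees).
#'
#' @param lower,upper Domain bounds, in stimulus units (`lower < upper`).
#' @param circular Logical; does the stimulus wrap around at the bounds?
#' @param n_grid Number of evaluation points (at least 64).
#'
#' @return An object of class `fm_domain`.
#' @export
#' @examples
#' stimulus_domain(0, 180, circular = TRUE)
stimulus_domain <- function(lower, upper, circular = FALSE, n_grid = 1024L) {
  if (!is.numeric(lower) || !is.numeric(upper) || lower >= upper) {
    stop_fitmax("`lower` must be strictly smaller than `upper`.", "fitmax_domain_error")
  }
  n_grid <- as.integer(n_grid)
  if (n_grid < 64L) {
    stop_fitmax("`n_grid` must be at least 64.", "fitmax_domain_error")
  }
  structure(
    list(lower = lower, upper = upper, circular = isTRUE(circular), n_grid = n_grid),
    class = "fm_domain"
  )
}

domain_grid <- function(domain) {
  seq(domain$lower, domain$upper, length.out = domain$n_grid)
}

#' @export
print.fm_domain <- function(x, ...) {
  cat(sprintf(
    "<stimulus domain [%g, %g]%s, %d grid points>\n",
    x$lower, x$upper, if (x$circular) ", circular" else "", x$n_grid
  ))
  invisible(x)
}

new_prior <- function(s, density, domain, kind = "tabulated", a = NA_real_,
                      omega = NA_real_) {
  out <- tibble::tibble(s = s, density = density)
  attr(out, "domain") <- domain
  attr(out, "kind") <- kind
  attr(out, "a") <- a
  attr(out, "omega") <- omega
  class(out) <- c("fm_prior", class(out))
  out
}

prior_domain <- function(prior) attr(prior, "domain")

#' The natural-scene orientation prior
#'
#' Constructs the parametric prior over edge orientation used throughout the
#' package: density proportional to \eqn{1/(a - \cos 4s)} with \eqn{a > 1}
#' setting the steepness of the cardinal peaks and \eqn{\omega} the normalizing
#' constant. With the default steepness the prior has maxima at the cardinal
#' axes (0 and 90 degrees) and minima at the obliques (45 and 135 degrees),
#' matching the distribution of edges in natural scenes. Orientations are in
#' degrees; the cosine is evaluated in radians internally, giving the density
#' its 90-degree period.
#'
#' The same functional form serves on the folded diagonality axis
#' (0 = cardinal, 45 = oblique): folding \eqn{s \mapsto 45 - |45 - (s \bmod
#' 90)|} leaves \eqn{\cos 4s} unchanged, so a domain of \eqn{[0, 45]} simply
#' renormalizes the density there, now decreasing from cardinal to oblique.
#'
#' @param a Steepness parameter, dimensionless, must exceed 1 (the density is
#'   unbounded at `a = 1`). Default 1.85.
#' @param domain An [stimulus_domain()]; defaults to orientation in degrees on
#'   `[0, 180)`. Use `stimulus_domain(0, 45)` for the diagonality axis.
#'
#' @return An `fm_prior`: a tibble with columns `s` (degrees) and `density`
#'   (probability per degree), normalized by the trapezoid rule, carrying the
#'   domain and the parameters `a` and `omega` as attributes.
#' @export
#' @examples
#' pr <- orientation_prior()
#' pr$s[which.max(pr$density)] # cardinal peak
orientation_prior <- function(a = 1.85,
                              domain = stimulus_domain(0, 180, circular = TRUE)) {
  if (!is.numeric(a) || length(a) != 1L || a <= 1) {
    stop_fitmax("Steepness `a` must exceed 1 (the density is unbounded otherwise).",
                "fitmax_steepness_error")
  }
  s <- domain_grid(domain)
  raw <- 1 / (a - cos(4 * s * pi / 180))
  z <- trapz(s, raw)
  omega <- 1 / z
  new_prior(s, raw / z, domain, kind = "orientation", a = a, omega = omega)
}

#' Build a prior from a density function or tabulated values
#'
#' @param domain An [stimulus_domain()].
#' @param f Either a vectorized density function of the stimulus or a numeric
#'   vector of (possibly unnormalized) density values on the domain grid.
#'
#' @return A normalized `fm_prior`.
#' @export
prior_from_density <- function(domain, f) {
  s <- domain_grid(domain)
  dens <- if (is.function(f)) f(s) else as.numeric(f)
  if (length(dens) != length(s)) {
    stop_fitmax("Density values must match the domain grid length.", "fitmax_prior_error")
  }
  if (any(!is.finite(dens)) || any(dens < 0)) {
    stop_fitmax("Density must be finite and non-negative.", "fitmax_prior_error")
  }
  new_prior(s, dens / trapz(s, dens), domain)
}

#' Reconstruct a prior density from sampled points of its CDF
#'
#' Fits a monotone interpolant through supplied (stimulus, cumulative
#' probability) pairs, differentiates it on the domain grid and renormalizes.
#' This is how a prior is recovered when only cumulative measurements are
#' published (for example, a measured contrast CDF).
#'
#' @param s Stimulus values of the CDF samples (increasing).
#' @param cdf Cumulative probabilities at `s`, non-decreasing, within `[0, 1]`.
#' @param domain Optional [stimulus_domain()]; defaults to the range of `s`.
#'
#' @return An `fm_prior` on the domain grid.
#' @export
prior_from_cdf <- function(s, cdf, domain = NULL) {
  if (length(s) < 5L || length(cdf) != length(s)) {
    stop_fitmax("At least 5 (stimulus, cdf) pairs are required.", "fitmax_cdf_error")
  }
  if (any(diff(cdf) < 0) || any(cdf < -1e-12) || any(cdf > 1 + 1e-12)) {
    stop_fitmax("CDF values must be non-decreasing and within [0, 1].",
                "fitmax_cdf_error")
  }
  domain <- domain %||% stimulus_domain(min(s), max(s))
  fn <- splinefun(s, cdf, method = "hyman")
  grid <- domain_grid(domain)
  dens <- pmax(fn(grid, deriv = 1L), 0)
  new_prior(grid, dens / trapz(grid, dens), domain)
}

# density, evaluated off-grid by interpolation (analytic for the
# parametric orientation prior)
prior_density_at <- function(prior, s) {
  a <- attr(prior, "a")
  if (identical(attr(prior, "kind"), "orientation") && is.finite(a)) {
    omega <- attr(prior, "omega")
    return(omega / (a - cos(4 * s * pi / 180)))
  }
  approx(prior$s, prior$density, xout = s, rule = 2)$y
}

prior_cdf <- function(prior) {
  h <- cumtrapz(prior$s, prior$density)
  h / h[length(h)]
}

check_normalized <- function(prior, tol = 1e-6) {
  if (abs(trapz(prior$s, prior$density) - 1) > tol) {
    stop_fitmax("Prior density is not normalized on its grid.",
                "fitmax_prior_error")
  }
  invisible(TRUE)
}

#' Map orientation to diagonality
#'
#' Diagonality is the distance of an orientation from the nearest cardinal
#' axis: 0 degrees for cardinal stimuli, 45 for perfectly oblique ones. It is
#' the decision-relevant axis of the two-alternative task ("which stimulus is
#' more diagonal?").
#'
#' @param s Orientation(s) in degrees.
#' @return Diagonality in `[0, 45]` degrees.
#' @export
#' @examples
#' diagonality(c(0, 30, 45, 90, 135))
diagonality <- function(s) {
  m <- s %% 90
  45 - abs(45 - m)
}

#' Serialize priors and reward maps as two-column text
#'
#' @param x An `fm_prior` or `fm_reward_map`.
#' @param path File path.
#' @name fitmax-io
#' @export
write_prior <- function(x, path) {
  readr::write_tsv(tibble::tibble(s = x$s, value = x[[2]]), path)
  invisible(path)
}

#' @param domain Domain for the object being read (defaults to the file range).
#' @rdname fitmax-io
#' @export
read_prior <- function(path, domain = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  domain <- domain %||% stimulus_domain(min(tab$s), max(tab$s))
  f <- approxfun(tab$s, tab[[2]], rule = 2)
  prior_from_density(domain, f)
}
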