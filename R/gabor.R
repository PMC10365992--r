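#' Gabor patch rendering specification
#'
#' @param size Image side length in pixels.
#' @param sf Spatial frequency, cycles per image.
#' @param envelope Gaussian envelope sd as a fraction of the image side.
#' @param phase `"random"` (a fresh phase per render, so many images map to
#'   the same orientation) or `"fixed"` (phase 0).
#' @param contrast Grating contrast in `[0, 1]`.
#' @return A list of class `fm_gabor_spec`.
#' @export
gabor_spec <- function(size = 16L, sf = 2, envelope = 0.3,
                       phase = c("random", "fixed"), contrast = 1) {
  phase <- match.arg(phase)
  if (sf <= 0) stop_fitmax("`sf` must be positive.", "fitmax_range_error")
  if (envelope <= 0 || envelope > 0.5) {
    stop_fitmax("`envelope` must lie in (0, 0.5].", "fitmax_range_error")
  }
  structure(list(size = as.integer(size), sf = sf, envelope = envelope,
                 phase = phase, contrast = contrast),
            class = "fm_gabor_spec")
}

#' Render oriented Gabor patches
#'
#' An oriented sinusoid multiplied by a centred circular Gaussian envelope,
#' intensities in `[0, 1]`. With a symmetric grid and phase 0, the 0- and
#' 90-degree renders are transposes of each other.
#'
#' @param spec A [gabor_spec()].
#' @param angles Orientation(s) in degrees.
#' @param seed Optional integer seed (controls random phases).
#' @return A matrix with one column per angle (`size^2` rows, column-major
#'   pixels); for a single angle, a `size x size` matrix.
#' @export
render_gabor <- function(spec, angles, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(angles)
  cs <- seq(-0.5, 0.5, length.out = spec$size)
  x <- rep(cs, times = spec$size)   # row coordinate, column-major
  y <- rep(cs, each = spec$size)
  env <- exp(-(x^2 + y^2) / (2 * spec$envelope^2))
  th <- angles * pi / 180
  ph <- if (spec$phase == "random") runif(n, 0, 2 * pi) else rep(0, n)
  u <- outer(x, cos(th)) + outer(y, sin(th))
  img <- 0.5 + 0.5 * spec$contrast *
    cos(2 * pi * spec$sf * u + rep(ph, each = spec$size^2)) * env
  if (n == 1L) matrix(img, spec$size, spec$size) else img
}
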