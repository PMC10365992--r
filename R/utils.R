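#' @importFrom rlang abort warn .data
#' @importFrom stats approx approxfun dnorm pnorm qnorm rnorm runif rbinom
#'   splinefun var sd median optim optimize quantile setNames rgamma rbeta
#' @importFrom utils head tail
NULL

# trapezoid weights for an arbitrary strictly increasing grid
trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-(n - 1)] + dx[-1]) / 2
  w
}

trapz <- function(x, y) sum(trapz_weights(x) * y)

cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))
}

# golden-section minimization of a univariate function on [lo, hi]
golden_section <- function(f, lo, hi, tol = 1e-4, maxit = 200L) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a)
  c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  it <- 0L
  while (abs(b - a) > tol && it < maxit) {
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    }
    it <- it + 1L
  }
  x <- (a + b) / 2
  list(minimum = x, objective = f(x))
}

# deterministic seed derived from a parent seed and a character path,
# kept well below .Machine$integer.max
derive_seed <- function(seed, path) {
  h <- sum(utf8ToInt(paste0(path, collapse = "/")) *
             seq_along(utf8ToInt(paste0(path, collapse = "/"))))
  as.integer((as.numeric(seed) * 48271 + h) %% 214748329)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fitmax <- function(msg, class) {
  abort(msg, class = c(class, "fitmax_error"))
}
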