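#' Wrap phase to the principal interval
#'
#' Maps arbitrary phase values into \eqn{[-\pi, \pi)}.
#'
#' @param x Numeric vector/array of phases in radians.
#' @return Object of the same shape with values in \eqn{[-\pi, \pi)}.
#' @export
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # %% can return 2*pi for values within rounding of the upper edge
  y[y >= pi] <- -pi
  y
}

#' Circular mean of phase values
#'
#' @param x Phases in radians.
#' @param w Optional non-negative weights.
#' @return Circular mean in \eqn{[-\pi, \pi)}.
#' @export
circular_mean <- function(x, w = NULL) {
  if (is.null(w)) {
    atan2(mean(sin(x)), mean(cos(x)))
  } else {
    atan2(sum(w * sin(x)), sum(w * cos(x)))
  }
}

#' Analytic signal via one-sided spectral filtering
#'
#' Returns the complex analytic signal whose real part equals the input and
#' whose spectrum is zero at negative frequencies (DC and Nyquist retained at
#' unit weight). Used for instantaneous-phase extraction from calibration
#' fringes and for applying complex phase corrections to real spectra.
#'
#' @param x Real numeric vector, or a matrix whose columns are transformed
#'   independently.
#' @return Complex vector/matrix of the same dimensions.
#' @export
analytic_signal <- function(x) {
  if (is.matrix(x)) {
    n <- nrow(x)
    X <- stats::mvfft(x)
    h <- analytic_filter(n)
    X <- X * h
    stats::mvfft(X, inverse = TRUE) / n
  } else {
    n <- length(x)
    X <- stats::fft(x)
    X <- X * analytic_filter(n)
    stats::fft(X, inverse = TRUE) / n
  }
}

analytic_filter <- function(n) {
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  h
}

#' Unwrap a phase sequence
#'
#' Cumulative removal of 2-pi jumps between consecutive samples.
#'
#' @param p Numeric vector of wrapped phases (radians).
#' @return Unwrapped phase vector.
#' @export
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d))
}

# Full-width at half maximum of a sampled peak, with linear interpolation at
# the half-maximum crossings. `x` gives sample positions (default indices).
fwhm_of_peak <- function(y, x = seq_along(y)) {
  i0 <- which.max(y)
  half <- y[i0] / 2
  # walk left
  il <- i0
  while (il > 1 && y[il - 1] > half) il <- il - 1
  if (il == 1) {
    xl <- x[1]
  } else {
    f <- (y[il] - half) / (y[il] - y[il - 1])
    xl <- x[il] - f * (x[il] - x[il - 1])
  }
  ir <- i0
  n <- length(y)
  while (ir < n && y[ir + 1] > half) ir <- ir + 1
  if (ir == n) {
    xr <- x[n]
  } else {
    f <- (y[ir] - half) / (y[ir] - y[ir + 1])
    xr <- x[ir] + f * (x[ir + 1] - x[ir])
  }
  xr - xl
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
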