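#' Butterworth low-pass design
#'
#' Designs digital low-pass Butterworth coefficients by the bilinear transform
#' of the analog prototype (all zeros at z = -1, exact unit DC gain).  The
#' squared magnitude response is `1 / (1 + (tan(pi*f/fs)/tan(pi*fc/fs))^(2n))`,
#' so a single pass attenuates a sinusoid at `fc` by exactly -3 dB.
#'
#' @param order filter order `n`.
#' @param fc cutoff frequency (Hz).
#' @param fs sampling rate (Hz).
#' @return List with numerator `b` and denominator `a` (length `order + 1`,
#'   `a[1] == 1`).
#' @export
butter_lowpass <- function(order, fc, fs) {
  if (fc <= 0 || fc >= fs / 2)
    stop("butter_lowpass: cutoff must satisfy 0 < fc < fs/2", call. = FALSE)
  wa <- tan(pi * fc / fs)                       # pre-warped analog cutoff
  kk <- seq_len(order)
  pa <- wa * exp(1i * pi * (2 * kk + order - 1) / (2 * order))  # LHP poles
  pz <- (1 + pa) / (1 - pa)                     # bilinear transform
  a <- Re(poly_from_roots(pz))
  b <- choose(order, 0:order)                   # zeros at z = -1
  b <- b * sum(a) / sum(b)                      # unit DC gain
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# Steady-state filter state for a step input of unit height (direct form II
# transposed), so that filtering a constant is exact from the first sample.
lfilter_zi <- function(b, a) {
  n <- length(a) - 1L
  if (n == 0L) return(numeric(0))
  A <- matrix(0, n, n)
  A[, 1] <- -a[-1]
  if (n > 1) A[cbind(1:(n - 1), 2:n)] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n) - A, B)
}

#' Zero-phase low-pass Butterworth filter
#'
#' Filters forward and backward (so the squared magnitude response applies and
#' no phase shift is introduced — event timings are preserved), with
#' odd-reflection padding and steady-state initial conditions at both ends.
#' A constant signal is returned unchanged to round-off.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param fc cutoff frequency (Hz); must be below the Nyquist rate.
#' @param order filter order (default 5).
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_filter <- function(x, fs, fc, order = 5L) {
  coefs <- butter_lowpass(order, fc, fs)
  filtfilt_1d(x, coefs$b, coefs$a)
}

# Causal single-pass Butterworth (steady-state initialized): used for the
# synthetic sensor front end, where acausal pre-ringing would be unphysical.
lowpass_causal <- function(x, fs, fc, order = 4L) {
  coefs <- butter_lowpass(order, fc, fs)
  zi <- lfilter_zi(coefs$b, coefs$a)
  cpp_iir_filter(x, coefs$b, coefs$a, zi * x[1])
}

filtfilt_1d <- function(x, b, a) {
  n <- length(x)
  npad <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L) * 4L)
  if (npad < 1L) return(x)
  pre <- 2 * x[1] - x[seq(npad + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - npad)]
  xx <- c(pre, x, post)
  zi <- lfilter_zi(b, a)
  y <- cpp_iir_filter(xx, b, a, zi * xx[1])
  y <- rev(y)
  y <- cpp_iir_filter(y, b, a, zi * y[1])
  y <- rev(y)
  y[seq(npad + 1, npad + n)]
}

#' Cumulative trapezoidal integration
#'
#' @param t time grid (uniform or not), or a scalar step when `x` is sampled
#'   uniformly.
#' @param x integrand samples.
#' @return Vector of the running integral, starting at 0.
#' @export
cumtrapz <- function(t, x) {
  if (length(t) == 1L) t <- seq(0, by = t, length.out = length(x))
  stopifnot(length(t) == length(x))
  c(0, cumsum(0.5 * diff(t) * (head(x, -1) + tail(x, -1))))
}

#' Resample a signal onto a fixed number of points by linear interpolation
#'
#' Maps the input onto `n` equally spaced points of normalized phase
#' `[0, 1]`; an input already of length `n` is returned unchanged.
#'
#' @param x signal samples (assumed equally spaced in phase).
#' @param n number of output points.
#' @return Numeric vector of length `n`.
#' @export
resample_linear <- function(x, n) {
  m <- length(x)
  if (m == n) return(x)
  if (m < 2L) stop("resample_linear: need at least two samples", call. = FALSE)
  approx(seq(0, 1, length.out = m), x, xout = seq(0, 1, length.out = n))$y
}
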