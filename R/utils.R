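# Internal numerical helpers shared across modules.

#' Quadrature companion of a real signal via the discrete analytic signal
#'
#' Returns the imaginary part of the discrete analytic signal of `x`
#' (FFT-based Hilbert transform). For any real input the returned sequence
#' is numerically orthogonal to `x`: the positive- and negative-frequency
#' halves of the cross-spectrum cancel exactly, so the inner product is zero
#' up to floating-point round-off.
#'
#' @param x numeric vector, finite.
#' @return numeric vector of the same length.
#' @examples
#' t <- seq(0, 1, by = 1 / 200)
#' q <- analytic_quadrature(cos(2 * pi * 10 * t))
#' # quadrature of a cosine is (approximately) the sine at the same frequency
#' @export
analytic_quadrature <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort("`x` must be a finite numeric vector.")
  }
  n <- length(x)
  if (n < 2L) abort("`x` must have length >= 2.")
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[n / 2L + 1L] <- 1
    if (n > 2L) h[2:(n / 2L)] <- 2
  } else {
    h[2:((n + 1L) / 2L)] <- 2
  }
  z <- fft(fft(x) * h, inverse = TRUE) / n
  Im(z)
}

# Unit-peak Tukey (tapered cosine) window of length n with taper fraction
# alpha: alpha = 0 is rectangular, alpha = 1 is a Hann window.
tukey_window <- function(n, alpha = 0.5) {
  stopifnot(n >= 1L, alpha >= 0, alpha <= 1)
  if (n == 1L) return(1)
  if (alpha <= 0) return(rep(1, n))
  k <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- k < alpha / 2
  hi <- k >= 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * k[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * k[hi] / alpha - 2 / alpha + 1)))
  w
}

# Unit-peak Gaussian window of length n centred at sample `center`
# (1-based), standard deviation `sigma` in samples.
gaussian_window <- function(n, center, sigma) {
  exp(-0.5 * ((seq_len(n) - center) / sigma)^2)
}

# Zero-phase Butterworth band-pass; order is the per-pass order.
bandpass <- function(x, fs, band, order = 3L) {
  ny <- fs / 2
  band <- pmin(pmax(band, 1e-6), ny * 0.99)
  bf <- signal::butter(order, band / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Centred moving average of width w samples (w >= 1), edges renormalised.
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  kern <- rep(1, w)
  num <- stats::filter(x, kern, sides = 2)
  den <- stats::filter(rep(1, length(x)), kern, sides = 2)
  out <- as.numeric(num / den)
  # stats::filter leaves NA at the edges; fall back to shrinking windows
  bad <- which(is.na(out))
  for (i in bad) {
    j <- max(1L, i - w %/% 2L):min(length(x), i + w %/% 2L)
    out[i] <- mean(x[j])
  }
  out
}

# Indices of strict local maxima (plateaus resolved to their first sample).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(diff(sign(diff(x))) < 0) + 1L
}

# Greedy refractory enforcement: keep the larger of any two events closer
# than `min_dist` (in the units of `times`).
enforce_refractory <- function(times, amplitudes, min_dist) {
  if (length(times) == 0L) return(integer(0))
  ord <- order(amplitudes, decreasing = TRUE)
  kept <- logical(length(times))
  for (i in ord) {
    if (!any(kept & abs(times - times[i]) < min_dist)) kept[i] <- TRUE
  }
  which(kept)
}

# Convert a time in seconds to a 1-based sample index at rate fs.
time_to_index <- function(t, fs) as.integer(round(t * fs)) + 1L

index_to_time <- function(i, fs) (i - 1L) / fs

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; thin wrapper so all module-level determinism funnels through one
# place.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}
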