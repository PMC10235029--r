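#' Rayleigh envelope signal-to-noise ratio
#'
#' The envelope SNR (mean / standard deviation of the envelope) of fully
#' developed speckle, whose envelope is Rayleigh distributed, equals
#' `sqrt(pi / (4 - pi))`, approximately 1.913.  Values below this limit
#' indicate structural heterogeneity in the resolution cell population.
#'
#' @return The theoretical Rayleigh envelope SNR (dimensionless).
#' @export
#' @examples
#' rayleigh_snr()
rayleigh_snr <- function() sqrt(pi / (4 - pi))

#' Nepers to decibels conversion factor
#'
#' Attenuation is carried internally in Np cm^-1 MHz^-1; multiply by this
#' factor (20 / ln 10 = 8.686) to report dB cm^-1 MHz^-1.
#'
#' @return The scalar conversion factor dB/Np.
#' @export
np_to_db <- function() 20 / log(10)

#' Acoustic wavelength
#'
#' @param frequency_hz Frequency in Hz.
#' @param sound_speed Speed of sound in m/s (default soft tissue, 1540).
#' @return Wavelength in mm.
#' @export
#' @examples
#' wavelength_mm(11e6) # ~0.14 mm, the block-definition wavelength
wavelength_mm <- function(frequency_hz, sound_speed = 1540) {
  stopifnot(frequency_hz > 0, sound_speed > 0)
  sound_speed / frequency_hz * 1e3
}

#' Tukey (tapered cosine) window
#'
#' @param n Window length in samples.
#' @param ratio Taper ratio in \[0, 1\]; 0 is rectangular, 1 is Hann.
#' @return Numeric vector of length `n`.
#' @export
tukey_window <- function(n, ratio = 0.25) {
  stopifnot(n >= 1, ratio >= 0, ratio <= 1)
  if (n == 1) return(1)
  k <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  if (ratio > 0) {
    edge <- ratio / 2
    lo <- k < edge
    hi <- k > 1 - edge
    w[lo] <- 0.5 * (1 + cos(pi * (2 * k[lo] / ratio - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * (2 * k[hi] / ratio - 2 / ratio + 1)))
  }
  w
}

# Analytic signal of each column of a real matrix, via the frequency-domain
# construction (positive frequencies doubled, negative zeroed).  Columns
# are zero-padded to an FFT-friendly length (factors 2/3/5) and truncated
# back; the padding only perturbs a few samples at the far edge.
analytic_signal <- function(x) {
  x <- as.matrix(x)
  n0 <- nrow(x)
  n <- stats::nextn(n0, c(2, 3, 5))
  if (n > n0) x <- rbind(x, matrix(0, n - n0, ncol(x)))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(x)
  out <- stats::mvfft(X * h, inverse = TRUE) / n
  out[seq_len(n0), , drop = FALSE]
}

# Envelope SNR of a sample: mean over population standard deviation.
# Returns NA for (near-)constant input rather than Inf.
envelope_snr <- function(e) {
  m <- mean(e)
  v <- mean((e - m)^2)
  if (v <= .Machine$double.eps * max(m^2, 1)) return(NA_real_)
  m / sqrt(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
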