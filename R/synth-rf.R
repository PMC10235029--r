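#' Simulate radiofrequency speckle volumes
#'
#' Convolution speckle model: a white Gaussian scatterer field, scaled by
#' the square root of the local backscatter-amplitude ratio, is filtered
#' per depth segment in the frequency domain by a Gaussian-modulated pulse
#' `P(f)`, a backscatter frequency filter `f^(delta_n/2)` and amplitude
#' attenuation `exp(-2 * alpha_cum * f * z)` (two-way travel).  Depth
#' variation is handled by filtering each ground-truth row's segment with
#' its local filter and summing, so homogeneous regions are stationary
#' Gaussian processes whose envelope is Rayleigh distributed (envelope
#' SNR ~ 1.913).  No diffraction or elevational effects are modeled.
#'
#' @param truth A [make_ground_truth()] object; its rows are mapped to
#'   consecutive axial sample segments.
#' @param sampling_frequency_hz RF sampling rate (default 120 MHz, i.e.
#'   8 x the 15 MHz center frequency).
#' @param center_frequency_hz Pulse center frequency (default 15 MHz).
#' @param pulse_bandwidth_frac Fractional -6 dB two-sided bandwidth of the
#'   Gaussian pulse spectrum (default 0.8, covering the 4-18 MHz band).
#' @param n_lines Lateral lines per ground-truth column.
#' @param n_frames Number of statistically independent frames (default 1).
#' @param scatterer_density Variance scale of the scatterer field; 0 gives
#'   an all-zero volume.
#' @param sound_speed Speed of sound (m/s) mapping samples to depth.
#' @param seed Optional RNG seed.
#' @return An object of class `rf_volume`: array `samples` of dimension
#'   (axial sample, lateral line, frame) plus sampling metadata.
#' @export
simulate_rf <- function(truth,
                        sampling_frequency_hz = 120e6,
                        center_frequency_hz = 15e6,
                        pulse_bandwidth_frac = 0.8,
                        n_lines = 4,
                        n_frames = 1,
                        scatterer_density = 1,
                        sound_speed = 1540,
                        seed = NULL) {
  stopifnot(inherits(truth, "tissue_ground_truth"),
            n_frames >= 1, n_lines >= 1, scatterer_density >= 0)
  f0 <- center_frequency_hz
  fs <- sampling_frequency_hz
  if (f0 * (1 + pulse_bandwidth_frac) >= fs / 2)
    stop("pulse band outside sampling constraints (exceeds Nyquist)",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  axial_sample_mm <- sound_speed / (2 * fs) * 1e3
  seg_len <- max(1L, round(truth$axial_spacing_mm / axial_sample_mm))
  n_rows <- nrow(truth$delta_b_true)
  n_cols <- ncol(truth$delta_b_true)
  n_ax <- seg_len * n_rows
  n_lat <- n_lines * n_cols

  # frequency axis of the (FFT-friendly, zero-padded) transform length
  nfft <- stats::nextn(n_ax, c(2, 3, 5))
  f <- (seq_len(nfft) - 1) / nfft * fs
  f <- ifelse(f > fs / 2, f - fs, f)
  af <- abs(f)
  sigma_p <- pulse_bandwidth_frac * f0 / (2 * sqrt(2 * log(2)))
  pulse <- exp(-(af - f0)^2 / (2 * sigma_p^2))

  dz_cm <- truth$axial_spacing_mm / 10
  a_cum <- cumulative_attenuation(truth$delta_alpha_true, dz_cm) # Np/MHz
  f_mhz <- af / 1e6

  out <- array(0, dim = c(n_ax, n_lat, n_frames))
  for (k in seq_len(n_frames)) {
    for (jc in seq_len(n_cols)) {
      scat <- matrix(stats::rnorm(n_ax * n_lines,
                                  sd = sqrt(scatterer_density)),
                     n_ax, n_lines)
      acc <- matrix(0 + 0i, nfft, n_lines)
      for (ir in seq_len(n_rows)) {
        idx <- ((ir - 1) * seg_len + 1):(ir * seg_len)
        seg <- matrix(0, nfft, n_lines)
        seg[idx, ] <- scat[idx, ] * sqrt(truth$delta_b_true[ir, jc])
        # backscatter power-law filter floored below the analysis band so
        # the f^(n/2) singularity at DC cannot leak through the pulse tail
        H <- pulse *
          pmax(f_mhz, 2)^(truth$delta_n_true[ir, jc] / 2) *
          exp(-2 * a_cum[ir, jc] * f_mhz)
        acc <- acc + stats::mvfft(seg) * H
      }
      lines <- Re(stats::mvfft(acc, inverse = TRUE)) / nfft
      cols <- (jc - 1) * n_lines + seq_len(n_lines)
      out[, cols, k] <- lines[seq_len(n_ax), ]
    }
  }
  structure(list(samples = out,
                 sampling_frequency_hz = fs,
                 center_frequency_hz = f0,
                 axial_spacing_mm = axial_sample_mm,
                 lateral_spacing_mm = truth$lateral_spacing_mm / n_lines,
                 n_frames = n_frames,
                 sound_speed = sound_speed),
            class = "rf_volume")
}
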