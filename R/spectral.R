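#' Convert quadrature (IQ) data to radiofrequency data
#'
#' Band-limited upsampling of the complex baseband signal (zero-insertion
#' in the frequency domain) followed by remodulation at the carrier:
#' `rf(t) = Re[ iq_up(t) * exp(2i pi f0 t) ]`.  A constant-amplitude
#' single-tone IQ signal therefore maps to a pure tone at the carrier with
#' matched amplitude.
#'
#' @param iq Complex matrix (axial sample x lateral line) of baseband
#'   samples, or a vector.
#' @param carrier_frequency_hz Demodulation carrier (required).
#' @param iq_sampling_frequency_hz Sampling rate of the IQ data.
#' @param upsample_factor Integer upsampling factor (default 8).
#' @return An `rf_volume`-like list with `samples` ( (upsample_factor * N)
#'   x lines x 1 ), the RF sampling rate and carrier metadata.
#' @export
iq_to_rf <- function(iq, carrier_frequency_hz,
                     iq_sampling_frequency_hz,
                     upsample_factor = 8) {
  if (missing(carrier_frequency_hz) || is.null(carrier_frequency_hz))
    stop("missing carrier frequency", call. = FALSE)
  stopifnot(upsample_factor >= 1, iq_sampling_frequency_hz > 0)
  iq <- as.matrix(iq)
  n <- nrow(iq)
  m <- n * upsample_factor
  fs_rf <- iq_sampling_frequency_hz * upsample_factor

  up <- matrix(0 + 0i, m, ncol(iq))
  for (j in seq_len(ncol(iq))) {
    X <- stats::fft(iq[, j])
    Xu <- complex(m)
    half <- floor(n / 2)
    Xu[1:(half + 1)] <- X[1:(half + 1)]
    if (half >= 1) Xu[(m - (n - half - 1) + 1):m] <- X[(half + 2):n]
    up[, j] <- stats::fft(Xu, inverse = TRUE) / n
  }
  t <- (seq_len(m) - 1) / fs_rf
  rf <- Re(up * exp(2i * pi * carrier_frequency_hz * t))
  structure(list(samples = array(rf, dim = c(m, ncol(iq), 1)),
                 sampling_frequency_hz = fs_rf,
                 center_frequency_hz = carrier_frequency_hz,
                 n_frames = 1L),
            class = "rf_volume")
}

#' Envelope of an RF volume
#'
#' Magnitude of the per-line analytic signal (Hilbert-transform
#' quadrature) of the unfiltered RF data; this is the signal B-mode images
#' and the envelope SNR are computed from.
#'
#' @param rf An `rf_volume` or a real matrix (axial x lateral).
#' @return Array of non-negative envelope values with the input shape.
#' @export
compute_envelope <- function(rf) {
  x <- if (inherits(rf, "rf_volume")) rf$samples else rf
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1))
  stopifnot(is.numeric(x), length(dim(x)) == 3)
  out <- array(0, dim = dim(x))
  for (k in seq_len(dim(x)[3])) {
    out[, , k] <- abs(analytic_signal(x[, , k]))
  }
  if (dim(out)[3] == 1) out <- out[, , 1, drop = TRUE]
  out
}

#' Block decomposition of a frame
#'
#' Lays out square-in-physical-units analysis blocks of side 20 lambda
#' with 80% overlap between neighbours.  Side lengths are rounded to
#' pixels; steps are `floor(0.2 * side)` (at least 1).  Origins are
#' 0-based and intervals half-open; every block lies fully inside the
#' frame.
#'
#' @param frame_shape Integer `c(n_axial, n_lateral)` in pixels.
#' @param wavelength_mm Acoustic wavelength lambda (default 0.14 mm).
#' @param axial_spacing_mm,lateral_spacing_mm Pixel spacings.
#' @param block_wavelengths Block side in wavelengths (default 20).
#' @param overlap Fractional overlap between adjacent blocks (default 0.8).
#' @return An object of class `block_grid`.
#' @export
#' @examples
#' g <- block_grid(c(1000, 300), 0.14, 0.014, 0.05)
#' c(g$block_axial_px, g$step_axial_px)
block_grid <- function(frame_shape, wavelength_mm = 0.14,
                       axial_spacing_mm, lateral_spacing_mm,
                       block_wavelengths = 20, overlap = 0.8) {
  stopifnot(length(frame_shape) == 2, wavelength_mm > 0,
            axial_spacing_mm > 0, lateral_spacing_mm > 0,
            overlap >= 0, overlap < 1)
  side_mm <- block_wavelengths * wavelength_mm
  side_ax <- round(side_mm / axial_spacing_mm)
  side_lat <- round(side_mm / lateral_spacing_mm)
  if (side_ax < 1 || side_lat < 1 ||
      side_ax > frame_shape[1] || side_lat > frame_shape[2])
    stop("frame smaller than one analysis block", call. = FALSE)
  step_ax <- max(1L, floor((1 - overlap) * side_ax + 1e-9))
  step_lat <- max(1L, floor((1 - overlap) * side_lat + 1e-9))
  ax_org <- seq(0L, frame_shape[1] - side_ax, by = step_ax)
  lat_org <- seq(0L, frame_shape[2] - side_lat, by = step_lat)
  structure(list(block_axial_px = side_ax,
                 block_lateral_px = side_lat,
                 step_axial_px = step_ax,
                 step_lateral_px = step_lat,
                 axial_origins = as.integer(ax_org),
                 lateral_origins = as.integer(lat_org),
                 wavelength_mm = wavelength_mm,
                 axial_spacing_mm = axial_spacing_mm,
                 lateral_spacing_mm = lateral_spacing_mm),
            class = "block_grid")
}

#' Block-wise averaged power spectra
#'
#' For each block, each lateral line's axial segment is tapered with a
#' Tukey window (ratio 0.25), zero-padded, and its periodogram averaged
#' over the block's lines (Welch-style averaging without axial
#' sub-segmentation).  The averaged periodogram is then sampled on the
#' requested frequency grid by linear interpolation.
#'
#' @param rf An `rf_volume` or real matrix (single frame).
#' @param grid A [block_grid()].
#' @param freq_mhz Analysis frequencies (MHz); must lie within Nyquist.
#' @param tukey_ratio Taper ratio of the Tukey window.
#' @param sampling_frequency_hz Required if `rf` is a bare matrix.
#' @return Object of class `spectrum_map`: array `spectra` of dimension
#'   (frequency, axial block, lateral block, frame) plus the grid.
#' @export
compute_power_spectrum_map <- function(rf, grid, freq_mhz,
                                       tukey_ratio = 0.25,
                                       sampling_frequency_hz = NULL) {
  if (inherits(rf, "rf_volume")) {
    fs <- rf$sampling_frequency_hz
    x <- rf$samples
  } else {
    fs <- sampling_frequency_hz
    if (is.null(fs)) stop("sampling_frequency_hz required", call. = FALSE)
    x <- if (is.matrix(rf)) array(rf, dim = c(dim(rf), 1)) else rf
  }
  stopifnot(inherits(grid, "block_grid"), length(freq_mhz) >= 1)
  if (any(freq_mhz * 1e6 >= fs / 2) || any(freq_mhz <= 0))
    stop("freq_mhz outside (0, Nyquist)", call. = FALSE)

  side <- grid$block_axial_px
  win <- tukey_window(side, tukey_ratio)
  nfft <- 2^ceiling(log2(max(side * 2, 64)))
  f_bins <- (0:(nfft / 2)) * fs / nfft / 1e6
  nax <- length(grid$axial_origins)
  nlat <- length(grid$lateral_origins)
  nfr <- dim(x)[3]
  out <- array(0, dim = c(length(freq_mhz), nax, nlat, nfr))

  for (k in seq_len(nfr)) {
    for (j in seq_len(nlat)) {
      cols <- (grid$lateral_origins[j] + 1):
        (grid$lateral_origins[j] + grid$block_lateral_px)
      for (i in seq_len(nax)) {
        rows <- (grid$axial_origins[i] + 1):
          (grid$axial_origins[i] + side)
        seg <- x[rows, cols, k, drop = FALSE]
        dim(seg) <- c(side, length(cols))
        seg <- seg * win
        padded <- rbind(seg, matrix(0, nfft - side, ncol(seg)))
        P <- abs(stats::mvfft(padded))^2 / (sum(win^2) * fs)
        pavg <- rowMeans(P)[1:(nfft / 2 + 1)]
        out[, i, j, k] <- stats::approx(f_bins, pavg, xout = freq_mhz,
                                        rule = 2)$y
      }
    }
  }
  structure(list(spectra = out, freq_mhz = freq_mhz, grid = grid,
                 n_frames = nfr),
            class = "spectrum_map")
}

#' Block-wise envelope SNR map
#'
#' Per block, the ratio of the envelope mean to its population standard
#' deviation.  Fully developed (Rayleigh) speckle gives values near 1.913;
#' structured or degenerate blocks fall below.  Constant blocks yield `NA`
#' (undefined) and are excluded from ROI search rather than raising.
#'
#' @param envelope Non-negative envelope matrix or (axial, lateral, frame)
#'   array.
#' @param grid A [block_grid()].
#' @return Object of class `snr_map`: array `snr` (axial block x lateral
#'   block x frame) plus the grid.
#' @export
compute_snr_map <- function(envelope, grid) {
  stopifnot(inherits(grid, "block_grid"))
  x <- envelope
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1))
  if (any(x < 0)) stop("envelope must be non-negative", call. = FALSE)
  nax <- length(grid$axial_origins)
  nlat <- length(grid$lateral_origins)
  nfr <- dim(x)[3]
  out <- array(NA_real_, dim = c(nax, nlat, nfr))
  for (k in seq_len(nfr)) {
    for (j in seq_len(nlat)) {
      cols <- (grid$lateral_origins[j] + 1):
        (grid$lateral_origins[j] + grid$block_lateral_px)
      for (i in seq_len(nax)) {
        rows <- (grid$axial_origins[i] + 1):
          (grid$axial_origins[i] + grid$block_axial_px)
        out[i, j, k] <- envelope_snr(x[rows, cols, k])
      }
    }
  }
  structure(list(snr = out, grid = grid, n_frames = nfr),
            class = "snr_map")
}

#' Log spectral ratio of sample to reference
#'
#' `Y = ln(S_s / S_r) + ln(T_m)`, the quantity the power-law model is
#' fitted to.  `T_m` compensates the reference phantom's protective
#' membrane transmission.
#'
#' @param sample,reference `spectrum_map` objects on identical grids.
#' @param t_m Membrane compensation: scalar, vector over frequency, or
#'   function of frequency (MHz).  Default 1.
#' @return Object of class `log_ratio_volume` (array `Y` with the
#'   spectrum-map geometry).
#' @export
compute_log_spectral_ratio <- function(sample, reference, t_m = 1) {
  stopifnot(inherits(sample, "spectrum_map"),
            inherits(reference, "spectrum_map"))
  if (!isTRUE(all.equal(sample$freq_mhz, reference$freq_mhz)) ||
      !identical(dim(sample$spectra)[1:3], dim(reference$spectra)[1:3]))
    stop("sample and reference maps must share grid and frequencies",
         call. = FALSE)
  if (any(reference$spectra <= 0))
    stop("zero or negative reference power on the analysis band",
         call. = FALSE)
  tm <- if (is.function(t_m)) t_m(sample$freq_mhz) else t_m
  if (any(tm <= 0)) stop("t_m must be positive", call. = FALSE)
  nfr <- min(dim(sample$spectra)[4], dim(reference$spectra)[4])
  Y <- log(sample$spectra[, , , seq_len(nfr), drop = FALSE] /
             reference$spectra[, , , seq_len(nfr), drop = FALSE]) +
    log(tm)
  step_mm <- sample$grid$step_axial_px * sample$grid$axial_spacing_mm
  structure(list(Y = Y, freq_mhz = sample$freq_mhz,
                 axial_step_cm = step_mm / 10,
                 n_frames = nfr, t_m_applied = TRUE,
                 grid = sample$grid),
            class = "log_ratio_volume")
}

#' Usable analysis bandwidth above a noise floor
#'
#' Finds the largest contiguous frequency band on which the mean block
#' spectrum stays within `noise_floor_db` of its peak, then clips it to
#' the nominal analysis band.
#'
#' @param spectrum A `spectrum_map`.
#' @param noise_floor_db Threshold below the spectral peak (default -20).
#' @param band Clipping band in MHz (default `c(4, 18)`).
#' @return Numeric `c(f_low, f_high)` in MHz.
#' @export
usable_bandwidth <- function(spectrum, noise_floor_db = -20,
                             band = c(4, 18)) {
  stopifnot(inherits(spectrum, "spectrum_map"), noise_floor_db < 0)
  f <- spectrum$freq_mhz
  s <- apply(spectrum$spectra, 1, mean)
  s_db <- 10 * log10(s / max(s))
  ok <- s_db >= noise_floor_db & f >= band[1] & f <= band[2]
  if (!any(ok)) stop("no usable band above the noise floor", call. = FALSE)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ix <- which(runs$values)
  best <- ix[which.max(runs$lengths[ix])]
  c(f[starts[best]], f[ends[best]])
}

#' Select the analysis ROI by envelope-SNR proximity to the Rayleigh value
#'
#' Scans every sub-window of the given size inside a fixed search region
#' of the SNR map and returns the window whose mean SNR is closest to the
#' fully-developed-speckle value; ties are broken by the smallest axial,
#' then lateral, origin.  Blocks with undefined SNR are ignored in the
#' means; all-NA windows are skipped.
#'
#' @param snr_map An `snr_map` (first frame is used) or numeric matrix of
#'   block SNR values.
#' @param fixed_region Optional list with 1-based inclusive index ranges
#'   `axial` and `lateral` delimiting the search region (default: the
#'   whole map, standing in for the fixed 22 mm x 8 mm parenchyma window).
#' @param subroi_size Window size `c(axial, lateral)` in blocks; default
#'   half the fixed region per axis.
#' @param snr_target Target SNR (default `rayleigh_snr()`).
#' @return List with `axial`/`lateral` index ranges (1-based, inclusive),
#'   the achieved `mean_snr` and the `target`.
#' @export
select_roi <- function(snr_map, fixed_region = NULL, subroi_size = NULL,
                       snr_target = rayleigh_snr()) {
  s <- if (inherits(snr_map, "snr_map")) snr_map$snr else snr_map
  if (length(dim(s)) == 3) s <- s[, , 1]
  s <- as.matrix(s)
  fr <- fixed_region %||% list(axial = c(1, nrow(s)),
                               lateral = c(1, ncol(s)))
  stopifnot(fr$axial[1] >= 1, fr$axial[2] <= nrow(s),
            fr$lateral[1] >= 1, fr$lateral[2] <= ncol(s))
  region <- s[fr$axial[1]:fr$axial[2], fr$lateral[1]:fr$lateral[2],
              drop = FALSE]
  sz <- subroi_size %||% pmax(1, floor(dim(region) / 2))
  if (sz[1] > nrow(region) || sz[2] > ncol(region))
    stop("subroi larger than the fixed region", call. = FALSE)

  best <- NULL
  best_dev <- Inf
  means <- c()
  for (i in seq_len(nrow(region) - sz[1] + 1)) {
    for (j in seq_len(ncol(region) - sz[2] + 1)) {
      w <- region[i:(i + sz[1] - 1), j:(j + sz[2] - 1)]
      if (all(is.na(w))) next
      m <- mean(w, na.rm = TRUE)
      means <- c(means, m)
      dev <- abs(m - snr_target)
      if (dev < best_dev - 1e-12) {
        best_dev <- dev
        best <- list(i = i, j = j, mean = m)
      }
    }
  }
  if (is.null(best))
    stop("no window with defined SNR in the fixed region", call. = FALSE)
  if (max(means) < snr_target)
    warning("all candidate windows fall below the Rayleigh SNR target",
            call. = FALSE)
  list(axial = c(fr$axial[1] + best$i - 1,
                 fr$axial[1] + best$i + sz[1] - 2),
       lateral = c(fr$lateral[1] + best$j - 1,
                   fr$lateral[1] + best$j + sz[2] - 2),
       mean_snr = best$mean,
       target = snr_target)
}
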