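test_that("IQ-to-RF conversion upsamples and remodulates correctly", {
  # zero in, zero out
  z <- iq_to_rf(matrix(0 + 0i, 32, 2), 15e6, 15e6)
  expect_true(all(z$samples == 0))
  expect_equal(dim(z$samples)[1], 32 * 8)

  # constant-amplitude IQ becomes a pure carrier tone of the same amplitude
  iq <- matrix(complex(real = 2, imaginary = 0), 64, 1)
  rf <- iq_to_rf(iq, 15e6, 15e6, upsample_factor = 8)
  t <- (seq_len(512) - 1) / rf$sampling_frequency_hz
  expect_equal(as.vector(rf$samples[, 1, 1]), 2 * cos(2 * pi * 15e6 * t),
               tolerance = 1e-10)

  expect_error(iq_to_rf(iq, iq_sampling_frequency_hz = 15e6), "carrier")
})

test_that("envelope equals tone amplitude and vanishes for zero input", {
  t <- seq(0, 2e-5, by = 1 / 120e6)
  x <- matrix(3 * cos(2 * pi * 15e6 * t), ncol = 1)
  e <- compute_envelope(x)
  core <- e[100:(length(e) - 100)]
  expect_equal(median(core), 3, tolerance = 1e-3)
  expect_true(all(compute_envelope(matrix(0, 128, 4)) == 0))
})

test_that("block grid follows the 20-wavelength, 80%-overlap geometry", {
  # lambda = 0.14 mm, axial spacing 0.014 mm: side 200 px, step 40 px
  g <- block_grid(c(1000, 300), 0.14, 0.014, 0.05)
  expect_equal(g$block_axial_px, 200)
  expect_equal(g$step_axial_px, 40)
  expect_equal(g$block_lateral_px, round(2.8 / 0.05))
  # 20 lambda = 2.8 mm physical side
  expect_equal(g$block_axial_px * 0.014, 2.8)

  # frame of exactly one block: single origin at 0
  g1 <- block_grid(c(200, 56), 0.14, 0.014, 0.05)
  expect_equal(g1$axial_origins, 0L)
  expect_equal(g1$lateral_origins, 0L)
  expect_error(block_grid(c(100, 56), 0.14, 0.014, 0.05), "smaller")
})

test_that("power spectra locate tones, are flat for white noise, scale as power", {
  fs <- 100e6
  gw <- block_grid(c(400, 60), 0.14, 0.014, 0.05)
  freq <- seq(4, 18, 1)

  tt <- (0:399) / fs
  tone <- matrix(sin(2 * pi * 10e6 * tt), 400, 60)
  st <- compute_power_spectrum_map(tone, gw, freq,
                                   sampling_frequency_hz = fs)
  expect_equal(freq[which.max(st$spectra[, 1, 1, 1])], 10)

  # amplitude doubling quadruples power at every frequency
  st2 <- compute_power_spectrum_map(2 * tone, gw, freq,
                                    sampling_frequency_hz = fs)
  expect_equal(st2$spectra, 4 * st$spectra, tolerance = 1e-10)

  # phase invariance of the tone's block power
  tone_ph <- matrix(sin(2 * pi * 10e6 * tt + 1.1), 400, 60)
  sp <- compute_power_spectrum_map(tone_ph, gw, freq,
                                   sampling_frequency_hz = fs)
  expect_equal(max(sp$spectra[, 1, 1, 1]), max(st$spectra[, 1, 1, 1]),
               tolerance = 0.05)

  set.seed(2)
  wn <- matrix(rnorm(400 * 60), 400, 60)
  sw <- compute_power_spectrum_map(wn, gw, freq,
                                   sampling_frequency_hz = fs)
  sdb <- 10 * log10(apply(sw$spectra, 1, mean))
  expect_lt(max(sdb) - min(sdb), 3)

  expect_error(compute_power_spectrum_map(wn, gw, c(10, 60),
                                          sampling_frequency_hz = fs),
               "Nyquist")
})

test_that("envelope SNR map matches distributional expectations", {
  g <- block_grid(c(100, 100), 0.14, 0.028, 0.028)

  # {1, 3} pattern: mean 2, population sd 1, SNR 2
  snr <- compute_snr_map(matrix(c(1, 3), 100, 100), g)
  expect_equal(snr$snr[1, 1, 1], 2)

  # Rayleigh block at large n approaches 1.913
  set.seed(4)
  ray <- matrix(sqrt(rexp(300 * 300)), 300, 300)
  gr <- block_grid(c(300, 300), 0.14, 0.014, 0.014)
  sr <- compute_snr_map(ray, gr)
  expect_equal(mean(sr$snr), 1.91, tolerance = 0.05 / 1.91)

  # exponential envelope: mean equals sd, SNR tends to 1
  set.seed(5)
  ex <- matrix(rexp(300 * 300), 300, 300)
  se <- compute_snr_map(ex, gr)
  expect_equal(mean(se$snr), 1, tolerance = 0.05)

  # constant block is undefined, not an error
  sc <- compute_snr_map(matrix(1, 100, 100), g)
  expect_true(all(is.na(sc$snr)))
})

test_that("log spectral ratio obeys its algebra", {
  gt <- make_ground_truth(c(3, 1), "constant", axial_spacing_mm = 6,
                          lateral_spacing_mm = 3)
  rf <- simulate_rf(gt, n_lines = 48, seed = 1)
  gr <- block_grid(dim(rf$samples)[1:2], 0.14, rf$axial_spacing_mm,
                   rf$lateral_spacing_mm)
  sp <- compute_power_spectrum_map(rf, gr, seq(5, 15, 1))

  # identical maps: Y == 0; scaled sample: Y == 1; t_m direction
  expect_equal(max(abs(compute_log_spectral_ratio(sp, sp)$Y)), 0)
  sp_e <- sp
  sp_e$spectra <- exp(1) * sp$spectra
  expect_equal(range(compute_log_spectral_ratio(sp_e, sp)$Y), c(1, 1))
  expect_equal(range(compute_log_spectral_ratio(sp, sp, t_m = exp(2))$Y),
               c(2, 2))

  # antisymmetry under sample/reference swap
  rf2 <- simulate_rf(gt, n_lines = 48, seed = 2)
  sp2 <- compute_power_spectrum_map(rf2, gr, seq(5, 15, 1))
  Yab <- compute_log_spectral_ratio(sp, sp2)$Y
  Yba <- compute_log_spectral_ratio(sp2, sp)$Y
  expect_equal(Yab, -Yba, tolerance = 1e-12)

  sp_bad <- sp
  sp_bad$spectra[1] <- 0
  expect_error(compute_log_spectral_ratio(sp, sp_bad), "reference")
})

test_that("usable bandwidth finds the -20 dB band", {
  gr <- block_grid(c(100, 100), 0.14, 0.028, 0.028)
  f <- seq(4, 18, 0.25)
  mk <- function(vals) {
    structure(list(spectra = array(rep(vals, 4),
                                   dim = c(length(f), 2, 2, 1)),
                   freq_mhz = f, grid = gr, n_frames = 1),
              class = "spectrum_map")
  }
  # flat spectrum: the full clipped band
  expect_equal(usable_bandwidth(mk(rep(1, length(f)))), c(4, 18))

  # Gaussian spectrum whose -20 dB points are solved analytically:
  # S(f) = exp(-(f - 10.5)^2 / (2 s^2)) crosses peak - 20 dB at
  # 10.5 +/- s * sqrt(2 * log(100)); s chosen so the crossings are 5, 16
  s <- 5.5 / sqrt(2 * log(100))
  gauss <- exp(-(f - 10.5)^2 / (2 * s^2))
  expect_equal(usable_bandwidth(mk(gauss)), c(5, 16), tolerance = 0.3)

  # all-noise case: the spectral peak sits below the analysis band and
  # everything inside [4, 18] MHz is more than 20 dB down
  f2 <- seq(1, 18, 0.25)
  mk2 <- function(vals) {
    structure(list(spectra = array(rep(vals, 4),
                                   dim = c(length(f2), 2, 2, 1)),
                   freq_mhz = f2, grid = gr, n_frames = 1),
              class = "spectrum_map")
  }
  noise <- 1e-6 + exp(-(f2 - 2)^2 / (2 * 0.3^2))
  expect_error(usable_bandwidth(mk2(noise)), "usable")
})

test_that("ROI selection matches an exhaustive scan and breaks ties low", {
  # uniform map at the Rayleigh value: tie broken at the smallest origin
  u <- matrix(1.9131, 8, 8)
  r <- select_roi(u, subroi_size = c(3, 3), snr_target = 1.9131)
  expect_equal(r$axial, c(1, 3))
  expect_equal(r$lateral, c(1, 3))

  # a single good window among low values is found
  m <- matrix(1.2, 10, 10)
  m[4:6, 5:7] <- 1.91
  r2 <- suppressWarnings(select_roi(m, subroi_size = c(3, 3)))
  expect_equal(r2$axial, c(4, 6))
  expect_equal(r2$lateral, c(5, 7))

  # all windows below target: argmin still returned, with a warning
  low <- matrix(1.2, 6, 6)
  low[1:2, 1:2] <- 1.5
  expect_warning(r3 <- select_roi(low, subroi_size = c(2, 2)),
                 "below")
  expect_equal(r3$axial, c(1, 2))

  # brute-force oracle agreement on random maps
  set.seed(7)
  for (rep in 1:5) {
    mm <- matrix(runif(20 * 15, 1, 2), 20, 15)
    sz <- c(4, 5)
    got <- suppressWarnings(select_roi(mm, subroi_size = sz))
    best <- Inf; best_ij <- NULL
    for (i in 1:(20 - sz[1] + 1)) for (j in 1:(15 - sz[2] + 1)) {
      dev <- abs(mean(mm[i:(i + sz[1] - 1), j:(j + sz[2] - 1)]) -
                   rayleigh_snr())
      if (dev < best - 1e-12) { best <- dev; best_ij <- c(i, j) }
    }
    expect_equal(got$axial[1], best_ij[1])
    expect_equal(got$lateral[1], best_ij[2])
  }

  expect_error(select_roi(matrix(1.5, 4, 4), subroi_size = c(5, 5)),
               "larger")
})
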