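#' Specification of a synthetic rat cohort
#'
#' Describes, per Brunt steatosis grade, the number of subjects, the
#' central values and spreads of the QUS features (median backscatter
#' amplitude ratio in dB, frequency dependence, attenuation-slope
#' difference in Np cm^-1 MHz^-1, envelope SNR and relative BSC at
#' 11 MHz) and the fat-fraction mean and standard deviation.  Defaults
#' reproduce the study conditions of a 55-rat steatosis cohort: group
#' sizes 24/15/16 for grades 0/1/2 and grade-wise feature summaries from
#' its published distribution table.
#'
#' Each subject's fat fraction is drawn from the grade's normal
#' distribution truncated to the grade's Brunt interval; features are then
#' drawn around a piecewise-linear trend linking the grade anchor points
#' (grade fat-fraction mean, grade feature median), so that features carry
#' within-grade information about fat fraction, as acoustic parameters of
#' a continuously fat-infiltrated tissue do.  Spreads are the normal /
#' lognormal scales matching the grade interquartile ranges.  `delta_n`
#' is generated independently of grade (frequency dependence of
#' sub-wavelength Rayleigh scatterers shows no steatosis trend).
#'
#' @param group_sizes Named or ordered integer vector of subjects for
#'   grades 0, 1, 2.
#' @param fat_mean,fat_sd Per-grade fat-fraction mean and sd (%).
#' @param medians List of per-grade feature medians: `delta_b_db`,
#'   `delta_alpha`, `snr`, `delta_bsc_11mhz` (each length 3), plus scalar
#'   `delta_n`.
#' @param iqrs Per-grade interquartile ranges for the same features and
#'   for `delta_n`.
#' @param noise_scale Global multiplier on all spreads; 0 collapses every
#'   subject onto its grade's central values.
#' @param seed RNG seed used by [make_cohort()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(24, 15, 16),
                        fat_mean = c(1.28, 20.36, 45.23),
                        fat_sd = c(1.26, 7.36, 9.74),
                        medians = list(
                          delta_b_db = c(26.72, 27.41, 37.55),
                          delta_alpha = c(0.12, 0.26, 0.65),
                          snr = c(1.42, 1.63, 1.70),
                          delta_bsc_11mhz = c(2.35e-4, 1.60e-4, 41.95e-4),
                          delta_n = -6.17),
                        iqrs = list(
                          delta_b_db = c(6.05, 9.76, 8.18),
                          delta_alpha = c(0.20, 0.14, 0.37),
                          snr = c(0.09, 0.12, 0.08),
                          delta_bsc_11mhz = c(5.42e-4, 7.83e-4, 48.62e-4),
                          delta_n = 0.85),
                        noise_scale = 1,
                        seed = NULL) {
  stopifnot(length(group_sizes) == 3, all(group_sizes >= 0),
            length(fat_mean) == 3, length(fat_sd) == 3,
            all(fat_sd >= 0), noise_scale >= 0)
  intervals <- brunt_intervals()[1:3, ]
  ok <- fat_mean >= intervals$lower & fat_mean <= intervals$upper
  if (!all(ok))
    stop("fat-fraction means must lie in their grade's Brunt interval",
         call. = FALSE)
  structure(list(group_sizes = group_sizes, fat_mean = fat_mean,
                 fat_sd = fat_sd, medians = medians, iqrs = iqrs,
                 noise_scale = noise_scale, seed = seed),
            class = "cohort_spec")
}

# normal scale with the given IQR
iqr_to_sd <- function(iqr) iqr / (2 * stats::qnorm(0.75))

# lognormal log-scale whose IQR/median ratio matches; solves
# IQR = median * 2 sinh(z0 * sigma), z0 = qnorm(0.75)
iqr_to_lnorm_sdlog <- function(iqr, median) {
  asinh(iqr / (2 * median)) / stats::qnorm(0.75)
}

rtruncnorm1 <- function(mean, sd, lower, upper) {
  if (sd == 0) return(min(max(mean, lower), upper))
  for (i in 1:10000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  stop("truncated-normal rejection sampling failed", call. = FALSE)
}

#' Generate a synthetic cohort feature table
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame with columns `subject_id`, `grade_true`,
#'   `fat_fraction_true`, `delta_b_db`, `delta_n`, `delta_alpha`, `snr`,
#'   `delta_bsc_11mhz`; bitwise reproducible under the spec's seed.
#' @export
#' @examples
#' coh <- make_cohort(cohort_spec(seed = 1))
#' aggregate(delta_alpha ~ grade_true, coh, median)
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  grades <- 0:2
  iv <- brunt_intervals()[1:3, ]
  ns <- spec$noise_scale

  # piecewise-linear trend through (grade fat mean, grade feature median),
  # flat beyond the outer anchors
  trend <- function(anchors_y, ff) {
    stats::approx(spec$fat_mean, anchors_y, xout = ff, rule = 2)$y
  }
  # local trend slope seen by each grade (anchor segment its fat-fraction
  # mass spans); grade 1 straddles its anchor, so both segments contribute
  local_slope <- function(anchors_y) {
    s12 <- (anchors_y[2] - anchors_y[1]) / (spec$fat_mean[2] - spec$fat_mean[1])
    s23 <- (anchors_y[3] - anchors_y[2]) / (spec$fat_mean[3] - spec$fat_mean[2])
    c(s12, (s12 + s23) / 2, s23)
  }
  # the grade IQR of a feature reflects both the trend carried by the
  # within-grade fat-fraction spread and residual noise; the generator
  # draws only the residual part so the marginal per-grade IQR matches
  # the requested one (floored at 30% so features are never noiseless)
  residual_sd <- function(iqr_g, slope_g, g) {
    tot <- iqr_to_sd(iqr_g)
    trend_sd <- abs(slope_g) * spec$fat_sd[g + 1] * ns
    sqrt(max(tot^2 - trend_sd^2, (0.3 * tot)^2))
  }

  rows <- list()
  sid <- 0
  for (g in grades) {
    n_g <- spec$group_sizes[g + 1]
    if (n_g == 0) next
    for (i in seq_len(n_g)) {
      sid <- sid + 1
      ff <- rtruncnorm1(spec$fat_mean[g + 1], spec$fat_sd[g + 1] * ns,
                        iv$lower[g + 1], iv$upper[g + 1])
      db <- trend(spec$medians$delta_b_db, ff) +
        stats::rnorm(1, 0, residual_sd(spec$iqrs$delta_b_db[g + 1],
                                       local_slope(spec$medians$delta_b_db)[g + 1],
                                       g) * ns)
      da <- trend(spec$medians$delta_alpha, ff) +
        stats::rnorm(1, 0, residual_sd(spec$iqrs$delta_alpha[g + 1],
                                       local_slope(spec$medians$delta_alpha)[g + 1],
                                       g) * ns)
      sn <- trend(spec$medians$snr, ff) +
        stats::rnorm(1, 0, residual_sd(spec$iqrs$snr[g + 1],
                                       local_slope(spec$medians$snr)[g + 1],
                                       g) * ns)
      dn <- spec$medians$delta_n +
        stats::rnorm(1, 0, iqr_to_sd(spec$iqrs$delta_n) * ns)
      # relative BSC is lognormal; decompose on the log scale
      sdlog <- iqr_to_lnorm_sdlog(spec$iqrs$delta_bsc_11mhz[g + 1],
                                  spec$medians$delta_bsc_11mhz[g + 1])
      logslope <- local_slope(log(spec$medians$delta_bsc_11mhz))[g + 1]
      sdlog_res <- sqrt(max(sdlog^2 -
                              (logslope * spec$fat_sd[g + 1] * ns)^2,
                            (0.3 * sdlog)^2))
      bsc <- exp(trend(log(spec$medians$delta_bsc_11mhz), ff) +
                   stats::rnorm(1, 0, sdlog_res * ns))
      rows[[sid]] <- data.frame(
        subject_id = sprintf("S%03d", sid),
        grade_true = g,
        fat_fraction_true = ff,
        delta_b_db = db,
        delta_n = dn,
        delta_alpha = da,
        snr = sn,
        delta_bsc_11mhz = bsc)
    }
  }
  if (length(rows) == 0)
    stop("cohort spec requests zero subjects in every grade", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
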