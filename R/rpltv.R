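#' Solver configuration for the TV-regularized power-law inversion
#'
#' The inversion minimizes, over maps `beta = ln(delta_b)`, `n = delta_n`
#' and `a = delta_a` on the block grid,
#'
#' `sum_blocks sum_f (Y - [beta + n ln f - 4 f a])^2
#'   + mu_b TV(beta) + mu_n TV(n) + mu_a TV(a)`
#'
#' with isotropic two-dimensional total variation on each map.  The
#' default weights `mu_b = 1, mu_n = 1e3, mu_a = 1e3` are the fixed
#' hyperparameters of the liver study; they are dimensionless weights on
#' natural-log-scale maps.
#'
#' @param mu_b,mu_n,mu_a Non-negative TV weights.
#' @param max_iterations Iteration cap of the majorize-minimize solver.
#' @param tol Relative objective-change stopping tolerance.
#' @param epsilon TV smoothing parameter (gradient-magnitude floor) of the
#'   lagged-diffusivity majorizer.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(mu_b = 1, mu_n = 1e3, mu_a = 1e3,
                          max_iterations = 500, tol = 1e-6,
                          epsilon = 1e-3) {
  stopifnot(mu_b >= 0, mu_n >= 0, mu_a >= 0,
            max_iterations >= 1, tol > 0, epsilon > 0)
  structure(list(mu_b = mu_b, mu_n = mu_n, mu_a = mu_a,
                 max_iterations = max_iterations, tol = tol,
                 epsilon = epsilon),
            class = "solver_config")
}

# sparse forward-difference operators (Neumann boundary: zero last row/col)
# for an nax x nlat grid vectorized column-major
difference_operators <- function(nax, nlat) {
  N <- nax * nlat
  idx <- matrix(seq_len(N), nax, nlat)
  # axial differences
  i1 <- as.vector(idx[-nax, , drop = FALSE])
  i2 <- as.vector(idx[-1, , drop = FALSE])
  Dx <- Matrix::sparseMatrix(i = c(seq_along(i1), seq_along(i1)),
                             j = c(i1, i2),
                             x = c(rep(-1, length(i1)), rep(1, length(i1))),
                             dims = c(length(i1), N))
  # lateral differences
  j1 <- as.vector(idx[, -nlat, drop = FALSE])
  j2 <- as.vector(idx[, -1, drop = FALSE])
  Dy <- Matrix::sparseMatrix(i = c(seq_along(j1), seq_along(j1)),
                             j = c(j1, j2),
                             x = c(rep(-1, length(j1)), rep(1, length(j1))),
                             dims = c(length(j1), N))
  list(Dx = Dx, Dy = Dy, pix_x = i1, pix_y = j1, N = N)
}

# isotropic smoothed TV and per-pixel gradient magnitudes of one map;
# row r of Dx differentiates at pixel pix_x[r], row r of Dy at pix_y[r]
tv_terms <- function(x, ops, eps) {
  gx <- as.numeric(ops$Dx %*% x)
  gy <- as.numeric(ops$Dy %*% x)
  g2 <- numeric(ops$N)
  g2[ops$pix_x] <- gx^2
  tmp <- numeric(ops$N)
  tmp[ops$pix_y] <- gy^2
  g2 <- g2 + tmp
  r <- sqrt(g2 + eps^2)
  list(tv = sum(r), r = r)
}

#' Fit the TV-regularized power-law model to a log-ratio volume
#'
#' Jointly estimates the relative backscatter amplitude, frequency
#' dependence and cumulative attenuation maps of every frame by
#' majorize-minimize (lagged-diffusivity) iterations: the smoothed
#' isotropic TV terms are majorized by weighted quadratics, and each
#' iteration solves one sparse symmetric positive-definite system that
#' couples the three maps through the per-block least-squares term.
#' Optimizing `beta = ln(delta_b)` keeps the data term linear and makes
#' `delta_b = exp(beta)` positive by construction.  With all TV weights
#' zero the fit reduces exactly to independent per-block ordinary least
#' squares.
#'
#' @param Y A `log_ratio_volume` (from [simulate_spectra()] or
#'   [compute_log_spectral_ratio()]) or an array (frequency, axial,
#'   lateral\[, frame\]).
#' @param config A [solver_config()].
#' @param freq_mhz Frequency grid; taken from `Y` when it is a volume.
#' @param axial_step_cm Axial block step (cm) used to differentiate the
#'   cumulative attenuation; taken from `Y` when available.
#' @return Object of class `coefficient_maps` with arrays `delta_b`
#'   (linear ratio), `delta_n`, `delta_a` (Np/MHz), `delta_alpha`
#'   (Np cm^-1 MHz^-1, forward difference of `delta_a`), each (axial x
#'   lateral x frame), a `converged` flag and the per-frame objective
#'   traces.
#' @export
fit_rpl_tv <- function(Y, config = solver_config(), freq_mhz = NULL,
                       axial_step_cm = NULL) {
  stopifnot(inherits(config, "solver_config"))
  if (inherits(Y, "log_ratio_volume")) {
    freq_mhz <- Y$freq_mhz
    axial_step_cm <- axial_step_cm %||% Y$axial_step_cm
    Y <- Y$Y
  }
  if (is.null(freq_mhz)) stop("freq_mhz required", call. = FALSE)
  if (length(dim(Y)) == 3) Y <- array(Y, dim = c(dim(Y), 1))
  if (length(freq_mhz) < 3)
    stop("at least 3 frequencies per block are required", call. = FALSE)
  if (any(!is.finite(Y))) stop("Y must be finite", call. = FALSE)
  nax <- dim(Y)[2]; nlat <- dim(Y)[3]; nfr <- dim(Y)[4]
  N <- nax * nlat

  G <- cbind(1, log(freq_mhz), -4 * freq_mhz)
  H <- crossprod(G)                         # 3 x 3
  ops <- difference_operators(nax, nlat)
  I_N <- Matrix::Diagonal(N)
  M_data <- rbind(
    cbind(H[1, 1] * I_N, H[1, 2] * I_N, H[1, 3] * I_N),
    cbind(H[2, 1] * I_N, H[2, 2] * I_N, H[2, 3] * I_N),
    cbind(H[3, 1] * I_N, H[3, 2] * I_N, H[3, 3] * I_N))
  mu <- c(config$mu_b, config$mu_n, config$mu_a)

  delta_b <- delta_n <- delta_a <- array(0, dim = c(nax, nlat, nfr))
  objectives <- vector("list", nfr)
  converged <- logical(nfr)

  for (k in seq_len(nfr)) {
    Ymat <- matrix(Y[, , , k], nrow = length(freq_mhz))   # F x N
    B <- crossprod(G, Ymat)                               # 3 x N
    b_vec <- as.numeric(t(B))                             # stack beta,n,a
    # initialization: per-block OLS (exact solution when mu == 0)
    theta0 <- solve(H, B)
    x <- as.numeric(t(theta0))

    obj_of <- function(x) {
      theta <- matrix(x, N, 3)
      resid <- Ymat - G %*% t(theta)
      val <- sum(resid^2)
      for (m in 1:3) {
        if (mu[m] > 0)
          val <- val + mu[m] * tv_terms(theta[, m], ops, config$epsilon)$tv
      }
      val
    }

    obj <- obj_of(x)
    trace <- obj
    conv <- all(mu == 0)  # OLS init is already the exact minimizer
    if (!conv) {
      for (it in seq_len(config$max_iterations)) {
        theta <- matrix(x, N, 3)
        penalty <- vector("list", 3)
        for (m in 1:3) {
          if (mu[m] > 0) {
            r <- tv_terms(theta[, m], ops, config$epsilon)$r
            wx <- 1 / r[ops$pix_x]
            wy <- 1 / r[ops$pix_y]
            L <- Matrix::crossprod(sqrt(wx) * ops$Dx) +
              Matrix::crossprod(sqrt(wy) * ops$Dy)
            penalty[[m]] <- (mu[m] / 2) * L
          } else {
            penalty[[m]] <- Matrix::sparseMatrix(i = integer(0),
                                                 j = integer(0),
                                                 dims = c(N, N))
          }
        }
        M <- M_data + Matrix::bdiag(penalty)
        x_new <- as.numeric(Matrix::solve(M, b_vec))
        obj_new <- obj_of(x_new)
        trace <- c(trace, obj_new)
        rel <- abs(obj - obj_new) / max(abs(obj), .Machine$double.eps)
        x <- x_new
        obj <- obj_new
        if (rel < config$tol) { conv <- TRUE; break }
      }
    }
    theta <- matrix(x, N, 3)
    delta_b[, , k] <- matrix(exp(theta[, 1]), nax, nlat)
    delta_n[, , k] <- matrix(theta[, 2], nax, nlat)
    delta_a[, , k] <- matrix(theta[, 3], nax, nlat)
    objectives[[k]] <- trace
    converged[k] <- conv
  }

  delta_alpha <- if (!is.null(axial_step_cm))
    attenuation_from_cumulative(delta_a, axial_step_cm) else NULL
  structure(list(delta_b = delta_b, delta_n = delta_n, delta_a = delta_a,
                 delta_alpha = delta_alpha,
                 axial_step_cm = axial_step_cm,
                 freq_mhz = freq_mhz,
                 converged = all(converged),
                 objective_trace = objectives,
                 config = config),
            class = "coefficient_maps")
}

#' Per-block ordinary least squares fit of the power-law model
#'
#' Independent least squares of `Y` on the regressors `[1, ln f, -4 f]`
#' for every block; the unregularized limit of [fit_rpl_tv()] and the
#' oracle it is validated against.
#'
#' @inheritParams fit_rpl_tv
#' @return A `coefficient_maps` object.
#' @export
per_block_ols <- function(Y, freq_mhz = NULL, axial_step_cm = NULL) {
  if (inherits(Y, "log_ratio_volume")) {
    freq_mhz <- Y$freq_mhz
    axial_step_cm <- axial_step_cm %||% Y$axial_step_cm
    Y <- Y$Y
  }
  if (length(freq_mhz %||% numeric(0)) < 3 ||
      length(unique(freq_mhz)) < 3)
    stop("rank-deficient design: need >= 3 distinct frequencies",
         call. = FALSE)
  fit_rpl_tv(Y, solver_config(0, 0, 0), freq_mhz = freq_mhz,
             axial_step_cm = axial_step_cm)
}

#' Attenuation-slope map from cumulative attenuation
#'
#' `delta_alpha(z) = d/dz delta_a(z)`, implemented as the forward finite
#' difference along the axial direction divided by the axial block step,
#' with the last row replicated so the output keeps the grid shape.
#'
#' @param delta_a Matrix or (axial x lateral x frame) array of cumulative
#'   attenuation (Np/MHz).
#' @param axial_step_cm Axial block step in cm.
#' @return Map(s) of `delta_alpha` in Np cm^-1 MHz^-1, same shape.
#' @export
attenuation_from_cumulative <- function(delta_a, axial_step_cm) {
  stopifnot(axial_step_cm > 0)
  one <- function(m) {
    if (nrow(m) < 2)
      stop("cannot differentiate a single-row map", call. = FALSE)
    d <- diff(m) / axial_step_cm
    rbind(d, d[nrow(d), , drop = FALSE])
  }
  if (length(dim(delta_a)) == 3) {
    out <- delta_a
    for (k in seq_len(dim(delta_a)[3])) out[, , k] <- one(delta_a[, , k])
    out
  } else one(as.matrix(delta_a))
}

#' Relative backscatter coefficient at a frequency
#'
#' `deltaBSC(f) = delta_b * f^delta_n`, evaluated pointwise on the maps.
#' The study's reporting frequency is 11 MHz.
#'
#' @param maps A `coefficient_maps` object (or list with `delta_b`,
#'   `delta_n`).
#' @param f_mhz Evaluation frequency in MHz (> 0), default 11.
#' @return Array of relative BSC values with the map shape.
#' @export
compute_relative_bsc <- function(maps, f_mhz = 11) {
  if (f_mhz <= 0) stop("frequency must be positive", call. = FALSE)
  maps$delta_b * f_mhz^maps$delta_n
}

#' Per-subject QUS features from coefficient and SNR maps
#'
#' For each frame, takes the ROI median of the backscatter ratio in dB
#' (10 log10 delta_b), delta_n, delta_alpha, relative BSC at the
#' reporting frequency and envelope SNR, then averages the per-frame
#' medians across frames (the study uses sequences of 20 frames).
#'
#' @param maps A `coefficient_maps` object with a frame dimension.
#' @param snr SNR array (axial x lateral x frame) on the same grid.
#' @param roi Optional list of index ranges `axial`, `lateral` (1-based,
#'   inclusive), e.g. from [select_roi()]; default is the whole map.
#' @param f_bsc_mhz Reporting frequency for relative BSC (default 11).
#' @return One-row data.frame with `delta_b_db`, `delta_n`, `delta_alpha`,
#'   `delta_bsc_11mhz`, `snr` and `n_frames`.
#' @export
extract_features <- function(maps, snr, roi = NULL, f_bsc_mhz = 11) {
  stopifnot(inherits(maps, "coefficient_maps"))
  if (is.matrix(snr)) snr <- array(snr, dim = c(dim(snr), 1))
  dims <- dim(maps$delta_b)
  roi <- roi %||% list(axial = c(1, dims[1]), lateral = c(1, dims[2]))
  if (roi$axial[2] < roi$axial[1] || roi$lateral[2] < roi$lateral[1])
    stop("empty ROI", call. = FALSE)
  ai <- roi$axial[1]:roi$axial[2]
  li <- roi$lateral[1]:roi$lateral[2]
  nfr <- dims[3]
  bsc <- compute_relative_bsc(maps, f_bsc_mhz)
  per_frame <- sapply(seq_len(nfr), function(k) {
    c(delta_b_db = stats::median(10 * log10(maps$delta_b[ai, li, k])),
      delta_n = stats::median(maps$delta_n[ai, li, k]),
      delta_alpha = stats::median(maps$delta_alpha[ai, li, k]),
      delta_bsc_11mhz = stats::median(bsc[ai, li, k]),
      snr = stats::median(snr[ai, li, min(k, dim(snr)[3])]))
  })
  out <- as.data.frame(t(rowMeans(per_frame)))
  out$n_frames <- nfr
  out
}
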