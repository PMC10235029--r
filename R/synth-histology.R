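#' Specification for a synthetic H&E-like histology image
#'
#' Describes a stained-tissue background carrying bright, circular fat
#' vacuoles (the structures the segmentation must keep) and optional
#' elongated bright distractors emulating vessels, sinusoids and tissue
#' cracks (the structures it must reject).  Gray levels are 8-bit; the
#' vacuole level sits above and the background below the default
#' binarization threshold of 180.
#'
#' @param image_shape Integer vector `c(height, width)` in pixels.
#' @param target_fat_fraction_pct Target vacuole area percentage in
#'   \[0, 90).
#' @param vacuole_radius_px Length-2 sampling range of vacuole radii (px).
#' @param n_distractors Number of elongated bright non-vacuole structures.
#' @param background_gray_level,vacuole_gray_level 8-bit intensities of
#'   stained tissue and vacuole interior.
#' @param noise_sd Gaussian texture noise on the background (gray levels).
#' @param seed RNG seed.
#' @return A list of class `histology_spec`.
#' @export
histology_spec <- function(image_shape = c(512, 512),
                           target_fat_fraction_pct = 20,
                           vacuole_radius_px = c(6, 16),
                           n_distractors = 0,
                           background_gray_level = 120,
                           vacuole_gray_level = 235,
                           noise_sd = 8,
                           seed = NULL) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 32),
            target_fat_fraction_pct >= 0, target_fat_fraction_pct < 90,
            length(vacuole_radius_px) == 2,
            vacuole_radius_px[1] >= 2,
            vacuole_radius_px[2] >= vacuole_radius_px[1],
            n_distractors >= 0)
  if (!(vacuole_gray_level > 180 && background_gray_level < 180))
    stop("gray levels must straddle the binarization threshold (180)",
         call. = FALSE)
  structure(list(image_shape = image_shape,
                 target_fat_fraction_pct = target_fat_fraction_pct,
                 vacuole_radius_px = vacuole_radius_px,
                 n_distractors = n_distractors,
                 background_gray_level = background_gray_level,
                 vacuole_gray_level = vacuole_gray_level,
                 noise_sd = noise_sd,
                 seed = seed),
            class = "histology_spec")
}

# disc pixel mask centered at (cy, cx) with radius r, clipped to the image
disc_pixels <- function(cy, cx, r, h, w) {
  yy <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
  xx <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
  g <- expand.grid(y = yy, x = xx)
  g <- g[(g$y - cy)^2 + (g$x - cx)^2 <= r^2, , drop = FALSE]
  cbind(g$y, g$x)
}

#' Generate a synthetic histology image with known vacuole mask
#'
#' Places non-overlapping bright discs by random sequential adsorption
#' until the disc area fraction reaches the target within +/- 0.5
#' percentage points, then adds the requested number of elongated (aspect
#' ratio >= 3) bright distractor structures that do not touch any vacuole
#' and are excluded from the true mask.  Placement failure at infeasible
#' targets raises an error.
#'
#' @param spec A [histology_spec()].
#' @return A list of class `histology_image`: `image` (8-bit RGB array,
#'   height x width x 3), `true_mask` (logical matrix of vacuole pixels),
#'   `achieved_fat_fraction_pct` and the spec.
#' @export
make_histology_image <- function(spec = histology_spec()) {
  stopifnot(inherits(spec, "histology_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  total_px <- h * w
  target <- spec$target_fat_fraction_pct

  mask <- matrix(FALSE, h, w)
  centers <- matrix(numeric(0), 0, 3) # cy, cx, r
  placed_px <- 0
  rmin <- spec$vacuole_radius_px[1]; rmax <- spec$vacuole_radius_px[2]
  r_hi <- rmax
  attempts <- 0
  max_attempts <- 2e5

  while (target > 0 &&
         placed_px / total_px * 100 < target - 0.5) {
    attempts <- attempts + 1
    if (attempts > max_attempts)
      stop(sprintf(
        "could not place vacuoles to reach %.1f%% (reached %.2f%%): target infeasible",
        target, placed_px / total_px * 100), call. = FALSE)
    # shrink the sampling range as the image fills up
    if (attempts %% 2000 == 0 && r_hi > rmin) r_hi <- max(rmin, r_hi - 1)
    r <- stats::runif(1, rmin, r_hi)
    # do not overshoot past the upper tolerance edge
    max_r <- sqrt((target + 0.45) / 100 * total_px / pi -
                    placed_px / pi)
    if (is.finite(max_r) && max_r < r) r <- max_r
    if (r < rmin) r <- rmin
    cy <- stats::runif(1, r + 1, h - r)
    cx <- stats::runif(1, r + 1, w - r)
    if (nrow(centers) > 0) {
      d2 <- (centers[, 1] - cy)^2 + (centers[, 2] - cx)^2
      if (any(d2 <= (centers[, 3] + r + 2)^2)) next
    }
    px <- disc_pixels(cy, cx, r, h, w)
    new_total <- placed_px + nrow(px)
    if (new_total / total_px * 100 > target + 0.5) next
    centers <- rbind(centers, c(cy, cx, r))
    mask[px] <- TRUE
    placed_px <- new_total
  }

  gray <- matrix(stats::rnorm(total_px, spec$background_gray_level,
                              spec$noise_sd), h, w)
  gray[mask] <- stats::rnorm(sum(mask), spec$vacuole_gray_level, 3)

  # elongated bright distractors (vessel-like), kept off the vacuoles
  if (spec$n_distractors > 0) {
    for (i in seq_len(spec$n_distractors)) {
      for (try in seq_len(200)) {
        len <- stats::runif(1, 30, 60)        # semi-major axis
        wid <- len / stats::runif(1, 4, 7)    # aspect ratio >= 4
        th <- stats::runif(1, 0, pi)
        cy <- stats::runif(1, len + 1, h - len)
        cx <- stats::runif(1, len + 1, w - len)
        yy <- max(1, floor(cy - len)):min(h, ceiling(cy + len))
        xx <- max(1, floor(cx - len)):min(w, ceiling(cx + len))
        g <- expand.grid(y = yy, x = xx)
        u <- (g$y - cy) * cos(th) + (g$x - cx) * sin(th)
        v <- -(g$y - cy) * sin(th) + (g$x - cx) * cos(th)
        inside <- (u / len)^2 + (v / wid)^2 <= 1
        # keep a small guard band so dilation cannot fuse a distractor
        # onto a neighbouring vacuole
        guard <- (u / (len + 4))^2 + (v / (wid + 4))^2 <= 1
        if (!any(inside)) next
        if (any(mask[cbind(g$y[guard], g$x[guard])])) next
        gray[cbind(g$y[inside], g$x[inside])] <-
          stats::rnorm(sum(inside), spec$vacuole_gray_level, 3)
        break
      }
    }
  }

  gray <- pmin(pmax(round(gray), 0), 255)
  # H&E-like tint: stained tissue pink, bright structures near white
  img <- array(0, dim = c(h, w, 3))
  t_ <- gray / 255
  img[, , 1] <- round(pmin(255, gray * 1.08))
  img[, , 2] <- round(gray * (0.75 + 0.25 * t_))
  img[, , 3] <- round(gray * (0.85 + 0.15 * t_))
  storage.mode(img) <- "integer"

  structure(list(image = img,
                 true_mask = mask,
                 achieved_fat_fraction_pct = placed_px / total_px * 100,
                 spec = spec),
            class = "histology_image")
}
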