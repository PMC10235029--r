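#' Brunt steatosis grade intervals
#'
#' Fat-fraction intervals of the Brunt grading of hepatic steatosis:
#' grade 0 below 5%, grade 1 from 5 to 33% (both ends included), grade 2
#' above 33 up to 66%, grade 3 above 66%.  The 5% lower bound is the
#' minimum operative definition of histological NAFLD.
#'
#' @return A data.frame with columns `grade`, `lower`, `upper`.
#' @export
brunt_intervals <- function() {
  data.frame(grade = 0:3,
             lower = c(0, 5, 33, 66),
             upper = c(5, 33, 66, 100))
}

#' Assign a Brunt steatosis grade from a fat fraction
#'
#' Grade 0 if the fat fraction is below 5%, grade 1 in \[5, 33\], grade 2
#' in (33, 66\], grade 3 above 66%.
#'
#' @param fat_fraction_pct Numeric vector of fat fractions in \[0, 100\].
#' @return Integer vector of grades 0-3.
#' @export
#' @examples
#' brunt_grade(c(1.28, 20.36, 45.23, 70))
brunt_grade <- function(fat_fraction_pct) {
  x <- fat_fraction_pct
  if (any(!is.finite(x)) || any(x < 0) || any(x > 100))
    stop("fat fraction must lie in [0, 100]", call. = FALSE)
  g <- integer(length(x))
  g[x >= 5] <- 1L
  g[x > 33] <- 2L
  g[x > 66] <- 3L
  g
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels
# touching diagonally are merged by union-find over the two diagonal
# pixel-pair shifts.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n == 0) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -w]), as.vector(lab[-h, -1])))   # up-right
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) > 0) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) union_(pairs[r, 1], pairs[r, 2])
  }
  root <- vapply(seq_len(n), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Segment fat vacuoles in an H&E histology image
#'
#' Six-step fat-vacuole quantification: (1) the 8-bit RGB image is
#' converted to grayscale by the standard luminance weights; (2) the gray
#' image is binarized at a global threshold (default 180; optionally
#' Otsu's automatic threshold); (3) binary erosion then dilation with a
#' radius-5 disc removes speckle-scale noise and smooths outlines; (4)
#' connected components are labeled with 8-connectivity; (5) components
#' whose shape is incompatible with a fat vacuole - circularity
#' `4 pi A / P^2` below `min_circularity` or axis aspect ratio above
#' `max_aspect` - are removed, a deterministic stand-in for expert removal
#' of vessels, sinusoids, bile ducts and cracks; (6) the fat fraction is
#' the retained vacuole area as a percentage of the image area.
#'
#' @param image 8-bit RGB array (height x width x 3, values 0-255) or a
#'   `histology_image`.
#' @param threshold Global gray-level binarization threshold (default 180).
#' @param auto_threshold If `TRUE`, use Otsu's threshold instead.
#' @param struct_radius Radius (px) of the disc structuring element.
#' @param min_circularity,max_aspect Shape-filter limits of step (5).
#' @return Object of class `segmentation_result`: logical `mask`,
#'   data.frame `components` (area, perimeter, centroid, circularity,
#'   aspect), `removed` (the audit list of discarded components),
#'   `fat_fraction_pct` and the threshold used.
#' @export
segment_fat_vacuoles <- function(image, threshold = 180,
                                 auto_threshold = FALSE,
                                 struct_radius = 5,
                                 min_circularity = 0.4,
                                 max_aspect = 3) {
  if (inherits(image, "histology_image")) image <- image$image
  if (!(is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3))
    stop("input must be an RGB image (height x width x 3)", call. = FALSE)
  if (any(image < 0) || any(image > 255) ||
      any(abs(image - round(image)) > 1e-8))
    stop("input must be 8-bit (integer values 0-255)", call. = FALSE)

  gray <- 0.2989 * image[, , 1] + 0.5870 * image[, , 2] +
    0.1140 * image[, , 3]
  if (auto_threshold)
    threshold <- EBImage::otsu(EBImage::Image(gray / 255), range = c(0, 1),
                               levels = 256) * 255
  bw <- gray > threshold

  brush <- EBImage::makeBrush(2 * struct_radius + 1, shape = "disc")
  bw_img <- EBImage::Image(bw * 1)
  opened <- EBImage::dilate(EBImage::erode(bw_img, brush), brush)
  mask0 <- EBImage::imageData(opened) > 0.5

  lab <- label_components_8(mask0)
  n <- max(lab)
  total <- length(mask0)
  if (n == 0) {
    return(structure(list(mask = matrix(FALSE, nrow(mask0), ncol(mask0)),
                          components = data.frame(),
                          removed = data.frame(),
                          fat_fraction_pct = 0,
                          threshold = threshold),
                     class = "segmentation_result"))
  }

  sh <- EBImage::computeFeatures.shape(lab)
  mo <- EBImage::computeFeatures.moment(lab)
  area <- sh[, "s.area"]
  perim <- pmax(sh[, "s.perimeter"], 1)
  circ <- pmin(4 * pi * area / perim^2, 1.5)
  minor <- mo[, "m.majoraxis"] * sqrt(1 - pmin(mo[, "m.eccentricity"], 1)^2)
  aspect <- mo[, "m.majoraxis"] / pmax(minor, 1e-6)
  comp <- data.frame(label = seq_len(n), area = area, perimeter = perim,
                     centroid_x = mo[, "m.cx"], centroid_y = mo[, "m.cy"],
                     circularity = circ, aspect = aspect)
  keep <- circ >= min_circularity & aspect <= max_aspect
  mask <- matrix(lab %in% comp$label[keep], nrow(lab), ncol(lab))

  structure(list(mask = mask,
                 components = comp[keep, , drop = FALSE],
                 removed = comp[!keep, , drop = FALSE],
                 fat_fraction_pct = 100 * sum(mask) / total,
                 threshold = threshold),
            class = "segmentation_result")
}

#' Subject-level fat fraction from several histology images
#'
#' Sampling error of a single section is reduced by averaging the fat
#' fractions measured on several images of the same liver.
#'
#' @param fractions Numeric vector of per-image fat fractions (%) or a
#'   list of `segmentation_result` objects.
#' @return The mean fat fraction (%).
#' @export
subject_fat_fraction <- function(fractions) {
  if (is.list(fractions) && !is.data.frame(fractions))
    fractions <- vapply(fractions, function(r) r$fat_fraction_pct,
                        numeric(1))
  stopifnot(is.numeric(fractions), length(fractions) >= 1)
  mean(fractions)
}

#' Read and write histology images as 8-bit PNG
#'
#' `write_histology_png()` stores a synthetic histology image (and
#' optionally its true vacuole mask as a single-channel PNG);
#' `read_histology_png()` loads an RGB PNG back as the 8-bit array
#' [segment_fat_vacuoles()] expects.
#'
#' @param image A `histology_image` or 8-bit RGB array.
#' @param path Output path for the RGB image.
#' @param mask_path Optional output path for the true mask.
#' @return `write_histology_png()` returns `path` invisibly;
#'   `read_histology_png()` returns an 8-bit RGB array.
#' @export
write_histology_png <- function(image, path, mask_path = NULL) {
  mask <- NULL
  if (inherits(image, "histology_image")) {
    mask <- image$true_mask
    image <- image$image
  }
  png::writePNG(image / 255, path)
  if (!is.null(mask_path)) {
    if (is.null(mask)) stop("no true mask to write", call. = FALSE)
    png::writePNG(mask * 1, mask_path)
  }
  invisible(path)
}

#' @rdname write_histology_png
#' @export
read_histology_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3 && dim(x)[3] == 4) x <- x[, , 1:3]
  if (length(dim(x)) != 3 || dim(x)[3] != 3)
    stop("expected an RGB PNG", call. = FALSE)
  round(x * 255)
}
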