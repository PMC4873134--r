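#' Cage-bioassay image
#'
#' An 8-bit grayscale frame from a camera facing the treated or untreated
#' area of a bioassay cage, with an optional region of interest and an
#' optional ground-truth fly count (known for synthetic frames, or from
#' manual counting).
#'
#' @param pixels integer matrix of intensities in \[0, 255\] (rows = y,
#'   columns = x).
#' @param roi region of interest as `c(x0, x1, y0, y1)` in 0-based,
#'   half-open pixel coordinates (`[x0, x1) x [y0, y1)`); default the
#'   whole image.
#' @param ground_truth_count optional non-negative integer.
#' @return An object of class `"cage_image"`.
#' @export
cage_image <- function(pixels, roi = NULL, ground_truth_count = NULL) {
  pixels <- as.matrix(pixels)
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 255))
    lv_stop("pixel intensities must lie in [0, 255]", "lurevp_parameter_error")
  w <- ncol(pixels); h <- nrow(pixels)
  if (is.null(roi)) roi <- c(0L, w, 0L, h)
  if (length(roi) != 4L || roi[1] < 0 || roi[3] < 0 ||
      roi[2] > w || roi[4] > h || roi[1] >= roi[2] || roi[3] >= roi[4])
    lv_stop("ROI must be a non-empty rectangle within image bounds",
            "lurevp_parameter_error")
  if (!is.null(ground_truth_count) &&
      (ground_truth_count < 0 || ground_truth_count %% 1 != 0))
    lv_stop("ground_truth_count must be a non-negative integer",
            "lurevp_parameter_error")
  structure(list(pixels = pixels, roi = as.numeric(roi),
                 ground_truth_count = ground_truth_count),
            class = "cage_image")
}

#' @export
print.cage_image <- function(x, ...) {
  cat(sprintf("cage image %d x %d px, ROI [%g,%g) x [%g,%g)%s\n",
              ncol(x$pixels), nrow(x$pixels),
              x$roi[1], x$roi[2], x$roi[3], x$roi[4],
              if (is.null(x$ground_truth_count)) ""
              else sprintf(", truth = %d flies", x$ground_truth_count)))
  invisible(x)
}

roi_pixels <- function(image) {
  r <- image$roi
  image$pixels[(r[3] + 1):r[4], (r[1] + 1):r[2], drop = FALSE]
}

## inter-class-variance maximisation (Otsu) on the ROI histogram
auto_threshold <- function(sub) {
  EBImage::otsu(sub / 255, range = c(0, 1), levels = 256) * 255
}

#' Count flies in a frame by threshold segmentation
#'
#' Binarises the region of interest (flies are dark on a light mesh
#' ceiling by default), takes the total foreground area in pixels, and
#' divides it by the area representing one fly. Fractional counts are
#' rounded to the nearest integer (ties to even).
#'
#' @param image a [cage_image()].
#' @param threshold an intensity cut in \[0, 255\], or `"auto"` to select
#'   it by inter-class-variance maximisation on the ROI histogram.
#' @param per_fly_area area of one fly in pixels (see
#'   [estimate_per_fly_area()]).
#' @param invert set `TRUE` for light flies on a dark background.
#' @return An object of class `"count_result"`: list with
#'   `foreground_area`, `per_fly_area`, `count` and `threshold_used`.
#' @examples
#' frames <- render_cage_frames(10, seed = 1)
#' count_flies_threshold(frames[[1]], threshold = 128, per_fly_area = 25)
#' @export
count_flies_threshold <- function(image, threshold = "auto", per_fly_area,
                                  invert = FALSE) {
  stopifnot(inherits(image, "cage_image"))
  if (!is.numeric(per_fly_area) || per_fly_area <= 0)
    lv_stop("per_fly_area must be positive", "lurevp_parameter_error")
  sub <- roi_pixels(image)
  if (length(sub) == 0L)
    lv_stop("empty ROI", "lurevp_parameter_error")
  thr <- if (identical(threshold, "auto")) auto_threshold(sub)
         else as.numeric(threshold)
  fg <- if (invert) sub > thr else sub < thr
  area <- sum(fg)
  structure(
    list(foreground_area = area,
         per_fly_area = per_fly_area,
         count = round(area / per_fly_area),
         threshold_used = thr),
    class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("count %d (foreground %d px / %.4g px per fly, threshold %.4g)\n",
              x$count, x$foreground_area, x$per_fly_area, x$threshold_used))
  invisible(x)
}

#' Calibrate the per-fly area from frames with known counts
#'
#' For each calibration frame the segmented foreground area is divided by
#' the known fly count; the estimate is the median of those per-image
#' ratios, robust to the occasional frame with touching flies.
#'
#' @param calibration list of [cage_image()]s with positive
#'   `ground_truth_count`.
#' @inheritParams count_flies_threshold
#' @return per-fly area in pixels.
#' @export
estimate_per_fly_area <- function(calibration, threshold = "auto",
                                  invert = FALSE) {
  if (inherits(calibration, "cage_image")) calibration <- list(calibration)
  counts <- vapply(calibration, function(im) {
    if (is.null(im$ground_truth_count)) 0 else im$ground_truth_count
  }, numeric(1))
  keep <- counts > 0
  if (!any(keep))
    lv_stop("need at least one calibration image with a positive fly count",
            "lurevp_insufficient_data")
  ratios <- vapply(calibration[keep], function(im) {
    sub <- roi_pixels(im)
    thr <- if (identical(threshold, "auto")) auto_threshold(sub)
           else as.numeric(threshold)
    fg <- if (invert) sub > thr else sub < thr
    sum(fg) / im$ground_truth_count
  }, numeric(1))
  stats::median(ratios)
}

#' Rank concordance between automated and manual counts
#'
#' Spearman rank correlation between two count series (mid-ranks for
#' ties), as used to validate image-based counting against counting by
#' eye. Reports both the correlation `rho` and `S`, the sum of squared
#' rank differences; for untied ranks
#' `rho = 1 - 6 S / (n (n^2 - 1))`.
#'
#' @param counts_auto,counts_manual equal-length numeric vectors,
#'   `n >= 3`.
#' @return An object of class `"concordance_result"`: list with `rho`,
#'   `S` and `n`.
#' @examples
#' concordance(c(3, 8, 15, 21, 30), c(3, 9, 14, 22, 31))
#' @export
concordance <- function(counts_auto, counts_manual) {
  if (length(counts_auto) != length(counts_manual))
    lv_stop("count vectors must have equal length", "lurevp_parameter_error")
  n <- length(counts_auto)
  if (n < 3L)
    lv_stop("need at least 3 paired counts", "lurevp_parameter_error")
  ra <- rank(counts_auto)   # mid-ranks for ties
  rb <- rank(counts_manual)
  structure(
    list(rho = stats::cor(ra, rb),
         S = sum((ra - rb)^2),
         n = n),
    class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Spearman concordance: rho = %.4f, S = %.4g, n = %d\n",
              x$rho, x$S, x$n))
  invisible(x)
}

#' Read / write cage images as 8-bit grayscale PNG (or TIFF)
#'
#' @param path file path ending in `.png` (or `.tif`/`.tiff`, which
#'   requires the `tiff` package).
#' @param roi,ground_truth_count passed to [cage_image()] on read.
#' @return [read_cage_image()] returns a [cage_image()];
#'   [write_cage_image()] invisibly returns `path`.
#' @export
read_cage_image <- function(path, roi = NULL, ground_truth_count = NULL) {
  m <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      lv_stop("reading TIFF requires the 'tiff' package", "lurevp_config_error")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(m)) == 3L) m <- m[, , 1L]   # collapse grayscale-with-alpha
  cage_image(round(m * 255), roi = roi,
             ground_truth_count = ground_truth_count)
}

#' @rdname read_cage_image
#' @param image a [cage_image()] to write.
#' @export
write_cage_image <- function(image, path) {
  stopifnot(inherits(image, "cage_image"))
  m <- image$pixels / 255
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      lv_stop("writing TIFF requires the 'tiff' package", "lurevp_config_error")
    tiff::writeTIFF(m, path, bits.per.sample = 8L)
  } else {
    png::writePNG(m, path)
  }
  invisible(path)
}
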