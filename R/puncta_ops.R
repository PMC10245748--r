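#' Detection parameters for puncta and dendrite segmentation
#'
#' Collects the tunable parameters of the segmentation stage. Defaults
#' reproduce the reference configuration for 50 nm/px sampling:
#' rolling-ball radius 4 px (protected zone 9 px = 450 nm), 3x3 median
#' filter, intensity threshold at the 45th percentile of the pixel
#' distribution (deliberately below the commonly used mean intensity),
#' puncta grown by 2 px into 5-px-wide (250 nm) discs, and the dendrite
#' mask dilated by 2 px to capture puncta lying on and next to dendrites.
#'
#' @param rollball_radius_px rolling-ball radius for background subtraction.
#' @param median_size_px median filter window (odd, >= 3).
#' @param puncta_threshold_fraction quantile (in (0,1)) of the intensity
#'   distribution used as the maxima threshold.
#' @param puncta_dilation_px radius by which detected maxima are expanded
#'   into circular puncta objects.
#' @param dendrite_dilation_px dilation radius applied to the dendrite mask.
#' @return A validated list of class `detection_params`.
#' @export
detection_params <- function(rollball_radius_px = 4L,
                             median_size_px = 3L,
                             puncta_threshold_fraction = 0.45,
                             puncta_dilation_px = 2L,
                             dendrite_dilation_px = 2L) {
  stopifnot(
    rollball_radius_px >= 1,
    median_size_px >= 3, median_size_px %% 2 == 1,
    puncta_threshold_fraction > 0, puncta_threshold_fraction < 1,
    puncta_dilation_px >= 1,
    dendrite_dilation_px >= 0
  )
  structure(
    list(
      rollball_radius_px = as.integer(rollball_radius_px),
      median_size_px = as.integer(median_size_px),
      puncta_threshold_fraction = puncta_threshold_fraction,
      puncta_dilation_px = as.integer(puncta_dilation_px),
      dendrite_dilation_px = as.integer(dendrite_dilation_px)
    ),
    class = "detection_params"
  )
}

#' Rolling-ball background subtraction
#'
#' Estimates the slowly varying background as the grayscale morphological
#' opening of the image with a disc of the given radius and subtracts it,
#' clamping at zero. Structures narrower than the protected zone
#' (diameter `2 * radius_px + 1` px; 9 px = 450 nm at the default radius 4
#' and 50 nm/px) do not fit the ball and are preserved, while flat or
#' slowly ramping illumination is removed.
#'
#' @param image numeric matrix.
#' @param radius_px ball radius in pixels (>= 1).
#' @return Non-negative numeric matrix of the same shape.
#' @export
subtract_background <- function(image, radius_px = 4L) {
  assert_image(image)
  stopifnot(radius_px >= 1)
  off <- disc_offsets(radius_px)
  # grayscale opening: erosion (local min) then dilation (local max) over
  # the disc; the opened surface is the background the ball can reach
  bg <- .gray_morph_cpp(.gray_morph_cpp(image, off, TRUE), off, FALSE)
  pmax(image - bg, 0)
}

#' Median filter for point-noise removal
#'
#' Replaces each pixel by the median of its `size_px` x `size_px`
#' neighbourhood (edge pixels replicated at the border), removing
#' single-pixel impulse noise while preserving puncta several pixels wide.
#'
#' @param image numeric matrix.
#' @param size_px odd window size >= 3.
#' @return Numeric matrix of the same shape.
#' @export
median_filter <- function(image, size_px = 3L) {
  assert_image(image)
  if (size_px < 3 || size_px %% 2 == 0) {
    stop("size_px must be odd and >= 3", call. = FALSE)
  }
  .median_filter_cpp(image, as.integer(size_px))
}

#' Intensity threshold at a quantile of the pixel distribution
#'
#' Returns the intensity value at the given fraction of the sorted pixel
#' intensity distribution: with `n` pixels the value at (0-based) rank
#' `floor(fraction * n)`. The default fraction 0.45 sits below the mean
#' intensity commonly used as a detection threshold, admitting genuine
#' low-intensity puncta; the downstream noise correction absorbs the extra
#' background maxima this lets through.
#'
#' @param image numeric matrix.
#' @param fraction quantile in (0, 1).
#' @return Scalar intensity threshold.
#' @export
fraction_threshold <- function(image, fraction = 0.45) {
  assert_image(image)
  stopifnot(fraction > 0, fraction < 1)
  v <- sort(as.vector(image))
  v[floor(fraction * length(v)) + 1L]
}

#' Locate intensity maxima above a threshold
#'
#' Finds pixels that are greater than or equal to all of their 8 neighbours,
#' strictly greater than at least one of them, and strictly above the
#' threshold. A flat plateau of qualifying pixels (adjacent qualifying
#' pixels necessarily share one value) contributes a single representative:
#' its lowest row-major `(row - 1) * ncol + col` index. Maxima at the image
#' border are kept; out-of-image neighbours are ignored.
#'
#' @param image numeric matrix.
#' @param threshold intensity cut-off; only maxima with value strictly
#'   above it are reported.
#' @return Integer matrix with columns `row`, `col` (possibly 0 rows),
#'   ordered by row-major position.
#' @export
detect_maxima <- function(image, threshold) {
  assert_image(image)
  nr <- nrow(image)
  nc <- ncol(image)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- image
  ge_all <- matrix(TRUE, nr, nc)
  gt_any <- matrix(FALSE, nr, nc)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      nb <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc, drop = FALSE]
      ge_all <- ge_all & (image >= nb)
      gt_any <- gt_any | (image > nb)
    }
  }
  cand <- ge_all & gt_any & (image > threshold)
  if (!any(cand)) {
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  }
  # adjacent candidates always share their value, so 8-connected components
  # of the candidate mask are exactly the plateaus
  lab <- .cc_label(cand)
  idx <- which(cand)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  rowmajor <- (rows - 1L) * nc + cols
  comp <- lab[idx]
  rep_idx <- tapply(seq_along(idx), comp, function(i) i[which.min(rowmajor[i])])
  rep_idx <- unlist(rep_idx, use.names = FALSE)
  out <- cbind(row = rows[rep_idx], col = cols[rep_idx])
  out[order((out[, 1] - 1L) * nc + out[, 2]), , drop = FALSE]
}

#' A set of punctum centroids with a common radius
#'
#' @param centroids integer matrix with columns `(row, col)`; may have zero
#'   rows. All centroids must lie inside `image_shape`.
#' @param radius_px disc radius used when rendering the puncta as a binary
#'   mask; the default 2 yields 5-px-wide (250 nm at 50 nm/px) puncta.
#' @param image_shape `c(height, width)` of the source image.
#' @return An object of class `puncta_set`.
#' @export
puncta_set <- function(centroids, radius_px = 2L, image_shape) {
  if (is.null(centroids)) {
    centroids <- matrix(integer(0), 0, 2)
  }
  centroids <- matrix(as.integer(centroids), ncol = 2,
                      dimnames = list(NULL, c("row", "col")))
  stopifnot(length(image_shape) == 2, all(image_shape >= 1), radius_px >= 0)
  if (nrow(centroids) > 0 &&
      (any(centroids[, 1] < 1) || any(centroids[, 1] > image_shape[1]) ||
       any(centroids[, 2] < 1) || any(centroids[, 2] > image_shape[2]))) {
    stop("centroids outside image bounds", call. = FALSE)
  }
  structure(
    list(centroids = centroids, radius_px = as.integer(radius_px),
         image_shape = as.integer(image_shape)),
    class = "puncta_set"
  )
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set> %d puncta, radius %d px, image %dx%d\n",
              nrow(x$centroids), x$radius_px,
              x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

#' Render a puncta set as a binary mask
#'
#' Stamps a rasterized circular disc of diameter `2 * radius_px + 1` pixels
#' (21 pixels at radius 2, the 5-px-wide 250 nm punctum) at
#' every centroid; discs are clipped at the image border and overlapping
#' discs merge into one connected object.
#'
#' @param puncta a [puncta_set()].
#' @return Logical matrix of shape `image_shape`.
#' @export
build_puncta_mask <- function(puncta) {
  stopifnot(inherits(puncta, "puncta_set"))
  stamp_discs(puncta$centroids, puncta$radius_px, puncta$image_shape)
}

#' Segment dendrites by mean-intensity thresholding
#'
#' Marks pixels strictly brighter than the image mean and dilates the
#' resulting mask by `dilation_px` (disc structuring element), so that
#' puncta lying on or immediately next to a dendrite fall inside the mask.
#' A constant image yields an empty mask with a warning.
#'
#' @param image numeric matrix (dendrite channel).
#' @param dilation_px dilation radius in pixels (0 disables dilation).
#' @return Logical matrix.
#' @export
segment_dendrites <- function(image, dilation_px = 2L) {
  assert_image(image)
  mask <- image > mean(image)
  if (!any(mask)) {
    warning("no pixel exceeds the mean intensity; empty dendrite mask")
    return(mask)
  }
  if (dilation_px >= 1) {
    brush <- EBImage::makeBrush(2L * as.integer(dilation_px) + 1L, "disc")
    mask <- EBImage::dilate(mask * 1, brush) > 0.5
  }
  mask
}

#' Detect puncta in one channel
#'
#' Runs the fixed segmentation chain on a raw puncta channel: rolling-ball
#' background subtraction, median filtering, quantile thresholding, and
#' local-maxima detection; the maxima become a [puncta_set()] whose discs
#' have radius `puncta_dilation_px`.
#'
#' @param image numeric matrix (projected puncta channel).
#' @param params a [detection_params()] object.
#' @return A [puncta_set()].
#' @export
detect_puncta <- function(image, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  x <- subtract_background(image, params$rollball_radius_px)
  x <- median_filter(x, params$median_size_px)
  thr <- fraction_threshold(x, params$puncta_threshold_fraction)
  maxima <- detect_maxima(x, thr)
  puncta_set(maxima, radius_px = params$puncta_dilation_px,
             image_shape = dim(image))
}
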