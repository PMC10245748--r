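#' Triple binary AND of puncta and dendrite masks
#'
#' A putative synapse is a presynaptic punctum overlapping a postsynaptic
#' punctum on a dendrite, so the colocalization mask is the pixel-wise
#' conjunction of the three binary masks.
#'
#' @param pre,post,dendrite logical matrices of identical shape.
#' @return Logical matrix.
#' @export
triple_and <- function(pre, post, dendrite) {
  assert_mask(pre); assert_mask(post); assert_mask(dendrite)
  if (!same_shape(pre, post, dendrite)) {
    stop("masks differ in shape", call. = FALSE)
  }
  pre & post & dendrite
}

#' Count colocalized detections
#'
#' Counts 8-connected components of a colocalization mask; discs that touch,
#' even diagonally, merge into a single detection.
#'
#' @param coloc_mask logical matrix.
#' @return Integer component count.
#' @export
count_colocalizations <- function(coloc_mask) {
  assert_mask(coloc_mask)
  max(.cc_label(coloc_mask))
}

#' Randomize punctum locations
#'
#' Draws a new position for every punctum, i.i.d. uniform over the whole
#' image, keeping the punctum count and radius. This destroys any spatial
#' correlation between channels and is the elementary move of the
#' randomization noise estimator (complete spatial randomness null; puncta
#' may overlap each other and may land off-dendrite by design).
#'
#' @param puncta a [puncta_set()].
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @return A [puncta_set()] with the same number of puncta.
#' @export
randomize_puncta <- function(puncta, seed = NULL) {
  stopifnot(inherits(puncta, "puncta_set"))
  n <- nrow(puncta$centroids)
  with_seed(seed, {
    puncta_set(
      cbind(sample.int(puncta$image_shape[1], n, replace = TRUE),
            sample.int(puncta$image_shape[2], n, replace = TRUE)),
      radius_px = puncta$radius_px,
      image_shape = puncta$image_shape
    )
  })
}

#' Randomize the objects of a binary mask
#'
#' Translates every 8-connected object of the mask to an independent
#' uniform position (the object's bounding box stays inside the image, so
#' shapes are preserved exactly). Placements
#' that would make an object touch an already placed one are rejected and
#' redrawn, so the randomized mask also keeps the input's object count and
#' total area — mirroring the source mask, whose objects are disjoint by
#' construction. This is the mask-level randomization move of the noise
#' estimator: operating on the observed objects (which may be clusters of
#' fused puncta) rather than on idealized punctum centroids keeps the
#' null's object-size and crowding statistics identical to the data's.
#'
#' @param mask logical matrix.
#' @param seed optional integer seed.
#' @param max_tries rejection-sampling cap per object; if exceeded (only
#'   plausible for masks near full coverage) an overlapping position is
#'   accepted.
#' @return Logical matrix with the same objects at random positions.
#' @export
randomize_mask_objects <- function(mask, seed = NULL, max_tries = 200L) {
  assert_mask(mask)
  lab <- .cc_label(mask)
  n <- max(lab)
  if (n == 0L) {
    return(mask)
  }
  with_seed(seed, .randomize_objects_cpp(lab, n, as.integer(max_tries)))
}

#' Noise estimate by mask-object randomization
#'
#' Estimates the random-chance colocalization count by repeatedly
#' randomizing the objects of both puncta masks ([randomize_mask_objects()])
#' and counting the detections of the triple AND with the dendrite mask;
#' the estimate is the mean over `n_reps` randomizations. This is the
#' noise estimator used by the quantification pipeline.
#'
#' @param pre,post logical puncta masks.
#' @param dendrite logical dendrite mask.
#' @param n_reps number of randomizations averaged (>= 1).
#' @param seed optional integer seed.
#' @return Numeric scalar (mean count) with attributes `se` and `counts`.
#' @export
noise_by_mask_randomization <- function(pre, post, dendrite, n_reps = 10L,
                                        seed = NULL) {
  assert_mask(pre); assert_mask(post); assert_mask(dendrite)
  stopifnot(n_reps >= 1)
  counts <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      count_colocalizations(triple_and(randomize_mask_objects(pre),
                                       randomize_mask_objects(post),
                                       dendrite))
    }, numeric(1))
  })
  est <- mean(counts)
  attr(est, "se") <- if (n_reps > 1) sd(counts) / sqrt(n_reps) else NA_real_
  attr(est, "counts") <- counts
  est
}

#' Noise estimate by puncta-location randomization
#'
#' Estimates the number of random-chance colocalizations expected on the
#' dendrites: both puncta sets are independently re-scattered uniformly over
#' the image, re-rendered as discs, AND-ed with the dendrite mask, and the
#' resulting detections counted; the estimate is the mean over `n_reps`
#' repetitions.
#'
#' @param pre,post [puncta_set()] objects (typically the detected puncta).
#' @param dendrite logical dendrite mask.
#' @param n_reps number of randomizations averaged (>= 1).
#' @param seed optional integer seed making the estimate reproducible.
#' @return Numeric scalar (mean count) with attributes `se` (standard error
#'   of the mean) and `counts` (per-replicate counts).
#' @export
noise_by_randomization <- function(pre, post, dendrite, n_reps = 10L,
                                   seed = NULL) {
  stopifnot(inherits(pre, "puncta_set"), inherits(post, "puncta_set"),
            n_reps >= 1)
  assert_mask(dendrite)
  counts <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      m <- triple_and(build_puncta_mask(randomize_puncta(pre)),
                      build_puncta_mask(randomize_puncta(post)),
                      dendrite)
      count_colocalizations(m)
    }, numeric(1))
  })
  est <- mean(counts)
  attr(est, "se") <- if (n_reps > 1) sd(counts) / sqrt(n_reps) else NA_real_
  attr(est, "counts") <- counts
  est
}

#' Spatial cross-correlation profile of the colocalization count
#'
#' Translates the postsynaptic mask relative to the presynaptic mask by
#' increasing row displacements (toroidal wrap, so the punctum count is
#' conserved at every shift) and counts colocalizations at each shift.
#' At shift 0 the count equals the original total; once the displacement
#' exceeds the reach of a true pre/post pair the count settles at the
#' random-chance level, so the profile's asymptote — the mean count over
#' shifts `>= min_asymptote_shift` — is a second, independent noise
#' estimate.
#'
#' @param pre,post,dendrite logical masks of identical shape.
#' @param max_shift_px largest displacement (default 50).
#' @param step_px displacement step (default 1).
#' @param min_asymptote_shift shifts at or beyond this displacement enter
#'   the asymptote (default 10 px, twice the punctum diameter, beyond which
#'   genuine pairs under the 250 nm rule cannot still overlap).
#' @return List of class `crosscorr_profile` with `shifts_px`, `counts`,
#'   `asymptote` and `asymptote_se`.
#' @export
crosscorr_profile <- function(pre, post, dendrite, max_shift_px = 50L,
                              step_px = 1L, min_asymptote_shift = 10L) {
  assert_mask(pre); assert_mask(post); assert_mask(dendrite)
  if (!same_shape(pre, post, dendrite)) {
    stop("masks differ in shape", call. = FALSE)
  }
  if (max_shift_px < min_asymptote_shift) {
    stop("max_shift_px must be >= min_asymptote_shift", call. = FALSE)
  }
  if (max_shift_px >= nrow(pre)) {
    stop("shift exceeds image size", call. = FALSE)
  }
  shifts <- seq(0L, as.integer(max_shift_px), by = as.integer(step_px))
  nr <- nrow(post)
  counts <- vapply(shifts, function(d) {
    shifted <- if (d == 0L) post else post[c((nr - d + 1L):nr, 1L:(nr - d)), ,
                                           drop = FALSE]
    count_colocalizations(triple_and(pre, shifted, dendrite))
  }, numeric(1))
  tailc <- counts[shifts >= min_asymptote_shift]
  structure(
    list(shifts_px = shifts, counts = counts,
         asymptote = mean(tailc),
         asymptote_se = if (length(tailc) > 1) {
           sd(tailc) / sqrt(length(tailc))
         } else {
           NA_real_
         }),
    class = "crosscorr_profile"
  )
}

#' @export
print.crosscorr_profile <- function(x, ...) {
  cat(sprintf(
    "<crosscorr_profile> shifts 0..%d px, count(0)=%d, asymptote=%.2f\n",
    max(x$shifts_px), x$counts[1], x$asymptote))
  invisible(x)
}

#' Noise-corrected synaptic density
#'
#' Subtracts the random-chance noise estimate from the total colocalization
#' count and normalizes by dendritic area. The corrected count is reported
#' even when negative (flagged, never silently clamped) so that averages
#' over images remain unbiased; a zero-area dendrite mask flags the image
#' as unusable.
#'
#' @param total total colocalization count (integer).
#' @param noise noise estimate (scalar).
#' @param dendrite logical dendrite mask whose true-pixel count defines the
#'   dendritic area.
#' @param pixel_size_nm physical pixel size (> 0).
#' @param noise_method,replicates,seed provenance fields echoed into the
#'   result.
#' @return List of class `coloc_result` with fields `total_count`,
#'   `noise_estimate`, `corrected_count`, `dendritic_area_um2`,
#'   `density_per_100um2`, `noise_method`, `replicates`, `seed`, `flags`.
#' @export
corrected_density <- function(total, noise, dendrite, pixel_size_nm = 50,
                              noise_method = c("randomization",
                                               "crosscorrelation"),
                              replicates = NA_integer_, seed = NA_integer_) {
  assert_mask(dendrite)
  stopifnot(pixel_size_nm > 0)
  noise_method <- match.arg(noise_method)
  area_um2 <- sum(dendrite) * (pixel_size_nm / 1000)^2
  corrected <- total - as.numeric(noise)
  flags <- character(0)
  if (corrected < 0) flags <- c(flags, "negative_corrected_count")
  density <- if (area_um2 > 0) {
    corrected / area_um2 * 100
  } else {
    flags <- c(flags, "zero_dendritic_area")
    NA_real_
  }
  structure(
    list(total_count = as.integer(total),
         noise_estimate = as.numeric(noise),
         corrected_count = corrected,
         dendritic_area_um2 = area_um2,
         density_per_100um2 = density,
         noise_method = noise_method,
         replicates = as.integer(replicates),
         seed = seed,
         flags = flags),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<coloc_result> total=%d noise=%.2f corrected=%.2f\n",
    "  dendritic area %.1f um^2, density %.2f per 100 um^2 (%s)%s\n"),
    x$total_count, x$noise_estimate, x$corrected_count,
    x$dendritic_area_um2, x$density_per_100um2, x$noise_method,
    if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]")
    else ""))
  invisible(x)
}

#' End-to-end synapse quantification of one image set
#'
#' Runs the full three-step procedure on a (projected) image set: puncta
#' and dendrite segmentation, triple-AND colocalization counting, and
#' random-chance noise correction by the requested method(s).
#'
#' @param iset an [image_set()]; z-stacks are max-projected first.
#' @param params a [detection_params()].
#' @param noise_method `"randomization"`, `"crosscorr"`, or `"both"`.
#' @param n_reps randomization replicates (see [noise_by_randomization()]).
#' @param seed optional integer seed for the randomization estimator.
#' @param max_shift_px largest displacement for [crosscorr_profile()].
#' @return A `coloc_result` (primary method first when both are computed;
#'   the cross-correlation result is attached as attribute `crosscorr`,
#'   and the detected objects as attributes `pre_puncta`, `post_puncta`,
#'   `dendrite_mask`).
#' @export
quantify_synapses <- function(iset, params = detection_params(),
                              noise_method = c("randomization", "crosscorr",
                                               "both"),
                              n_reps = 10L, seed = NULL, max_shift_px = 50L) {
  stopifnot(inherits(iset, "image_set"))
  noise_method <- match.arg(noise_method)
  iset <- project_image_set(iset)
  pre_p <- detect_puncta(iset$pre, params)
  post_p <- detect_puncta(iset$post, params)
  dend <- segment_dendrites(iset$dendrite, params$dendrite_dilation_px)
  pre_m <- build_puncta_mask(pre_p)
  post_m <- build_puncta_mask(post_p)
  total <- count_colocalizations(triple_and(pre_m, post_m, dend))

  xc <- NULL
  if (noise_method %in% c("crosscorr", "both")) {
    xc <- crosscorr_profile(pre_m, post_m, dend, max_shift_px = max_shift_px)
  }
  if (noise_method %in% c("randomization", "both")) {
    noise <- noise_by_mask_randomization(pre_m, post_m, dend,
                                         n_reps = n_reps, seed = seed)
    res <- corrected_density(total, noise, dend, iset$pixel_size_nm,
                             noise_method = "randomization",
                             replicates = n_reps,
                             seed = if (is.null(seed)) NA_integer_ else seed)
    attr(res, "noise_se") <- attr(noise, "se")
  } else {
    res <- corrected_density(total, xc$asymptote, dend, iset$pixel_size_nm,
                             noise_method = "crosscorrelation",
                             replicates = length(xc$shifts_px))
    attr(res, "noise_se") <- xc$asymptote_se
  }
  res$source_id <- iset$source_id
  attr(res, "crosscorr") <- xc
  attr(res, "pre_puncta") <- pre_p
  attr(res, "post_puncta") <- post_p
  attr(res, "dendrite_mask") <- dend
  res
}
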