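#' Rasterize line segments at a fixed width
#'
#' Renders each segment as the set of pixels within `(width_px - 1) / 2` of
#' the segment (discs stamped along a half-pixel-spaced walk), clipped at
#' the image border. A width-5 horizontal segment spanning a row therefore
#' covers exactly 5 rows over its column range.
#'
#' @param segments numeric matrix with columns `r0, c0, r1, c1` (one
#'   segment per row, endpoint pixel coordinates).
#' @param width_px odd line width (default 5, i.e. 250 nm at 50 nm/px).
#' @param shape `c(height, width)` of the mask.
#' @return Logical matrix.
#' @export
render_segments <- function(segments, width_px = 5L, shape) {
  stopifnot(width_px >= 1, width_px %% 2 == 1)
  segments <- matrix(segments, ncol = 4)
  radius <- (as.integer(width_px) - 1L) %/% 2L
  mask <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(nrow(segments))) {
    p0 <- segments[i, 1:2]
    p1 <- segments[i, 3:4]
    len <- sqrt(sum((p1 - p0)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(len * 2) + 1L))
    pts <- unique(cbind(round(p0[1] + t * (p1[1] - p0[1])),
                        round(p0[2] + t * (p1[2] - p0[2]))))
    keep <- pts[, 1] >= 1 - radius & pts[, 1] <= shape[1] + radius &
      pts[, 2] >= 1 - radius & pts[, 2] <= shape[2] + radius
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts)) mask <- mask | stamp_discs(pts, radius, shape)
  }
  mask
}

#' Generate a synthetic dendrite mask
#'
#' Draws `n_segments` gently curving neurite paths, each entering from a
#' random border point and propagating with small angular diffusion until
#' it leaves the field, rendered as `width_px`-wide lines. The slight
#' curvature mimics real dendrites and avoids the degenerate geometry of
#' perfectly straight lines (a straight line translated along its own
#' direction overlaps itself, which would bias shift-based null
#' estimates). With the defaults (48 paths, width 5, 1024 x 1024) the mask
#' covers roughly 15-20% of the image. Deterministic for a given seed.
#'
#' @param n_segments number of dendrite paths (>= 1).
#' @param width_px odd line width in pixels.
#' @param shape `c(height, width)`.
#' @param curvature_sd standard deviation of the per-step heading change
#'   (radians); 0 gives straight lines.
#' @param seed optional integer seed.
#' @return Logical matrix.
#' @export
generate_dendrites <- function(n_segments = 48L, width_px = 5L,
                               shape = c(1024L, 1024L), curvature_sd = 0.06,
                               seed = NULL) {
  stopifnot(n_segments >= 1, width_px >= 1, width_px %% 2 == 1)
  radius <- (as.integer(width_px) - 1L) %/% 2L
  step <- 2
  max_steps <- ceiling(2 * sum(shape) / step)
  with_seed(seed, {
    mask <- matrix(FALSE, shape[1], shape[2])
    for (k in seq_len(n_segments)) {
      side <- sample.int(4, 1)
      pos <- switch(side,
        c(1, runif(1, 1, shape[2])),
        c(shape[1], runif(1, 1, shape[2])),
        c(runif(1, 1, shape[1]), 1),
        c(runif(1, 1, shape[1]), shape[2]))
      # initial heading pointing into the image, +/- 60 degrees
      inward <- switch(side, pi / 2, -pi / 2, 0, pi)
      theta <- inward + runif(1, -pi / 3, pi / 3)
      pts <- matrix(NA_real_, max_steps, 2)
      for (s in seq_len(max_steps)) {
        pts[s, ] <- pos
        theta <- theta + rnorm(1, 0, curvature_sd)
        # heading convention: row grows with sin, col with cos
        pos <- pos + step * c(sin(theta), cos(theta))
        if (pos[1] < 1 || pos[1] > shape[1] ||
            pos[2] < 1 || pos[2] > shape[2]) break
      }
      pts <- round(pts[!is.na(pts[, 1]), , drop = FALSE])
      mask <- mask | stamp_discs(unique(pts), radius, shape)
    }
    mask
  })
}

#' Place ground-truth synapse pairs on a dendrite mask
#'
#' Draws `n_true` presynaptic centroids i.i.d. uniform over the dendrite
#' pixels and pairs each with a postsynaptic centroid at a random offset
#' with `min_sep_px - 0.5 < distance <= max_sep_px + 0.5` (uniform over the
#' qualifying integer offsets), so every pair satisfies the 250 nm
#' centroid-separation rule (< 5 px at 50 nm/px for the default
#' `max_sep_px = 4`). The default `min_sep_px = 4` concentrates separations
#' just below the colocalization limit, reflecting the apposed-terminal
#' geometry of real synapses (two ~200 nm terminals across a ~50 nm cleft
#' put the centroids near 250 nm apart); set `min_sep_px = 0` for offsets
#' uniform over the whole disc. Postsynaptic centroids falling outside the
#' image are re-drawn (up to 1000 attempts per pair).
#'
#' @param dendrite logical dendrite mask (non-empty).
#' @param n_true number of true pairs.
#' @param max_sep_px maximum centroid separation in pixels.
#' @param min_sep_px minimum centroid separation in pixels.
#' @param seed optional integer seed.
#' @return List with integer matrices `pre` and `post` (`n_true` rows each,
#'   columns `row`, `col`).
#' @export
place_true_synapses <- function(dendrite, n_true, max_sep_px = 4L,
                                min_sep_px = 4L, seed = NULL) {
  assert_mask(dendrite)
  stopifnot(min_sep_px <= max_sep_px)
  if (n_true == 0L) {
    empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
    return(list(pre = empty, post = empty))
  }
  idx <- which(dendrite)
  if (length(idx) == 0L) stop("dendrite mask is empty", call. = FALSE)
  nr <- nrow(dendrite)
  off <- disc_offsets(max_sep_px)
  if (min_sep_px > 0) {
    d2 <- off[, 1]^2 + off[, 2]^2
    off <- off[d2 > (min_sep_px - 0.5)^2, , drop = FALSE]
  }
  with_seed(seed, {
    pick <- idx[sample.int(length(idx), n_true, replace = TRUE)]
    pre <- cbind(row = (pick - 1L) %% nr + 1L,
                 col = (pick - 1L) %/% nr + 1L)
    post <- pre
    for (i in seq_len(n_true)) {
      for (try in 1:1000) {
        o <- off[sample.int(nrow(off), 1L), ]
        cand <- pre[i, ] + o
        if (cand[1] >= 1 && cand[1] <= nr &&
            cand[2] >= 1 && cand[2] <= ncol(dendrite)) {
          post[i, ] <- cand
          break
        }
        if (try == 1000) {
          stop("could not place postsynaptic centroid inside the image",
               call. = FALSE)
        }
      }
    }
    list(pre = pre, post = post)
  })
}

# Dilate a logical mask by a disc of the given radius (0 = no-op).
dilate_mask <- function(mask, radius_px) {
  if (radius_px < 1) {
    return(mask)
  }
  EBImage::dilate(mask * 1,
                  EBImage::makeBrush(2L * as.integer(radius_px) + 1L,
                                     "disc")) > 0.5
}

# Per-pair probability that a uniformly placed presynaptic punctum and a
# uniformly placed postsynaptic punctum coincide (share >= 1 disc pixel) on
# the given (already dilated) dendrite mask. Estimated by Monte-Carlo:
# positions uniform over the image, centroid offsets uniform over the
# geometric coincidence set; uses the caller's RNG stream.
pair_coincidence_prob <- function(dil, radius_px, n_samples) {
  shape <- dim(dil)
  disc <- disc_offsets(radius_px)
  key <- function(m) paste(m[, 1], m[, 2])
  span <- 2L * radius_px + 1L
  coin <- list()
  for (dr in -span:span) {
    for (dc in -span:span) {
      shared <- disc[key(disc) %in% key(sweep(disc, 2, c(-dr, -dc))), ,
                     drop = FALSE]
      if (nrow(shared)) {
        coin[[length(coin) + 1L]] <- list(off = c(dr, dc), shared = shared)
      }
    }
  }
  pos <- cbind(sample.int(shape[1], n_samples, TRUE),
               sample.int(shape[2], n_samples, TRUE))
  pick <- sample.int(length(coin), n_samples, TRUE)
  hit <- logical(n_samples)
  for (j in seq_along(coin)) {
    sel <- which(pick == j)
    if (!length(sel)) next
    sh <- coin[[j]]$shared
    h <- logical(length(sel))
    for (q in seq_len(nrow(sh))) {
      rr <- pos[sel, 1] + sh[q, 1]
      cc <- pos[sel, 2] + sh[q, 2]
      ok <- rr >= 1 & rr <= shape[1] & cc >= 1 & cc <= shape[2]
      h[ok] <- h[ok] | dil[cbind(rr[ok], cc[ok])]
    }
    hit[sel] <- h
  }
  mean(hit) * length(coin) / prod(shape)
}

#' Calibrate noise-puncta counts to a target SNR
#'
#' The simulation SNR is the number of true synapse pairs divided by the
#' expected number of random-chance colocalizations on the dendrites. A
#' chance colocalization is a coincidence event: an (unrelated) presynaptic
#' and postsynaptic punctum whose discs share at least one dendrite pixel.
#' Counting events rather than merged mask components keeps the SNR
#' definition independent of how coincidences happen to fuse in the
#' rendered masks.
#'
#' With puncta scattered i.i.d. uniformly, the expected event count is
#' `n_pre * n_post * p`, where `p` is the per-pair coincidence
#' probability. `p` is estimated by Monte-Carlo: random punctum positions
#' and random centroid offsets drawn over the geometric coincidence set,
#' scoring whether the shared disc pixels hit the (dilated) dendrite mask.
#' Both channels carry `n_true` true puncta plus the noise puncta, and any
#' non-partnered pair can coincide by chance, so the calibration solves
#' `(n_true + n_noise)^2 * p = n_true / target_snr` for `n_noise`.
#'
#' @param dendrite logical dendrite mask (pre-dilation; the detector's
#'   dilation is applied internally).
#' @param n_true number of true pairs the scene will carry.
#' @param target_snr target signal-to-noise ratio (> 0; `Inf` means no
#'   noise).
#' @param radius_px punctum disc radius.
#' @param dendrite_dilation_px dilation applied to the dendrite mask before
#'   scoring coincidences, matching the detection pipeline.
#' @param n_reps Monte-Carlo batches of 200 sampled placements each used to
#'   estimate the coincidence probability (default 100, i.e. 20000
#'   placements).
#' @param seed optional integer seed.
#' @param max_noise largest admissible per-channel noise count before the
#'   target is declared unattainable.
#' @return Integer vector `c(n_pre_noise, n_post_noise)` with attributes
#'   `expected_chance` (calibrated expected event count) and
#'   `target_chance`.
#' @export
snr_calibrate <- function(dendrite, n_true, target_snr, radius_px = 2L,
                          dendrite_dilation_px = 2L, n_reps = 100L,
                          seed = NULL, max_noise = 2e5) {
  assert_mask(dendrite)
  stopifnot(target_snr > 0, n_reps >= 1)
  if (!is.finite(target_snr)) {
    out <- c(n_pre_noise = 0L, n_post_noise = 0L)
    attr(out, "expected_chance") <- 0
    attr(out, "target_chance") <- 0
    return(out)
  }
  target <- n_true / target_snr
  with_seed(seed, {
    p_pair <- pair_coincidence_prob(dilate_mask(dendrite,
                                                dendrite_dilation_px),
                                    radius_px, 200L * n_reps)
    if (p_pair <= 0) stop("target SNR unattainable on this dendrite mask",
                          call. = FALSE)
    n_tot <- sqrt(target / p_pair)
    n_noise <- as.integer(round(n_tot - n_true))
    if (n_noise < 0) {
      stop("target SNR unattainable: chance coincidences among the true ",
           "puncta alone already exceed the target", call. = FALSE)
    }
    if (n_noise > max_noise) {
      stop("target SNR unattainable: required noise exceeds image capacity",
           call. = FALSE)
    }
    out <- c(n_pre_noise = n_noise, n_post_noise = n_noise)
    attr(out, "expected_chance") <- (n_true + n_noise)^2 * p_pair
    attr(out, "target_chance") <- target
    out
  })
}

#' Simulate one ground-truth scene
#'
#' Builds a complete synthetic field: a dendrite mask, `n_true` colocalized
#' pre/post pairs on the dendrites (the signal), and SNR-calibrated counts
#' of spatially random noise puncta in each channel. All ground truth
#' (pair positions, noise positions, calibrated expectation) is recorded,
#' so detections can be scored against a gold standard.
#'
#' @inheritParams snr_calibrate
#' @inheritParams place_true_synapses
#' @param n_true number of true synapse pairs (default 800).
#' @param shape image shape.
#' @param n_segments,width_px dendrite layout (see [generate_dendrites()]).
#' @param calib_reps Monte-Carlo replicates for [snr_calibrate()].
#' @param n_noise optional explicit per-channel noise-puncta count; when
#'   given, SNR calibration is skipped (used e.g. for noise-only null
#'   scenes with `n_true = 0`) and the expected chance count is still
#'   computed for the requested noise level.
#' @param seed optional integer seed controlling the whole scene.
#' @return Object of class `synthetic_scene`.
#' @export
simulate_scene <- function(n_true = 800L, target_snr = Inf,
                           shape = c(1024L, 1024L), n_segments = 48L,
                           width_px = 5L, max_sep_px = 4L, radius_px = 2L,
                           dendrite_dilation_px = 2L, calib_reps = 100L,
                           n_noise = NULL, seed = NULL) {
  with_seed(seed, {
    dend <- generate_dendrites(n_segments, width_px, shape)
    pairs <- place_true_synapses(dend, n_true, max_sep_px)
    nn <- if (is.null(n_noise)) {
      snr_calibrate(dend, n_true, target_snr, radius_px,
                    dendrite_dilation_px, n_reps = calib_reps)
    } else {
      p_pair <- pair_coincidence_prob(dilate_mask(dend, dendrite_dilation_px),
                                      radius_px, 200L * calib_reps)
      structure(c(n_pre_noise = as.integer(n_noise),
                  n_post_noise = as.integer(n_noise)),
                expected_chance = (n_true + n_noise)^2 * p_pair,
                target_chance = NA_real_)
    }
    pre_noise <- puncta_set(
      cbind(sample.int(shape[1], nn[1], TRUE),
            sample.int(shape[2], nn[1], TRUE)),
      radius_px = radius_px, image_shape = shape)
    post_noise <- puncta_set(
      cbind(sample.int(shape[1], nn[2], TRUE),
            sample.int(shape[2], nn[2], TRUE)),
      radius_px = radius_px, image_shape = shape)
    expected <- attr(nn, "expected_chance")
    structure(
      list(dendrite_mask = dend,
           true_pairs = pairs,
           pre_noise = pre_noise,
           post_noise = post_noise,
           n_true = as.integer(n_true),
           target_snr = target_snr,
           expected_chance = expected,
           realized_snr = if (expected > 0) n_true / expected else Inf,
           radius_px = as.integer(radius_px),
           shape = as.integer(shape),
           seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
      class = "synthetic_scene"
    )
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_scene> %dx%d px, %d true pairs, noise %d+%d puncta,\n",
    "  target SNR %.3g (realized %.3g), dendrite coverage %.1f%%\n"),
    x$shape[1], x$shape[2], x$n_true,
    nrow(x$pre_noise$centroids), nrow(x$post_noise$centroids),
    x$target_snr, x$realized_snr,
    100 * mean(x$dendrite_mask)))
  invisible(x)
}

#' Render a synthetic scene as an image set
#'
#' In `"binary"` mode (the validation regime) the three channels are the
#' 0/1 masks themselves: puncta discs for pre and post (true plus noise),
#' and the dendrite lines. `"grayscale"` mode emulates a deconvolved
#' fluorescence image, which makes intensity-threshold sweeps meaningful:
#' puncta are rendered with log-normally distributed peak amplitudes and a
#' Gaussian point-spread blur, on top of a flat baseline plus a spatially
#' smooth noise floor (Gaussian noise with a deconvolution-like correlation
#' length); a field of dim sub-resolution clutter specks emulating
#' nonspecific staining can be added. Grayscale rendering exists so that
#' intensity-threshold sweeps are meaningful end-to-end; it is an
#' extension of the binary validation regime, not part of it.
#'
#' @param scene a [simulate_scene()] result.
#' @param mode `"binary"` or `"grayscale"`.
#' @param seed optional integer seed (grayscale mode only).
#' @param amp_meanlog,amp_sdlog log-normal parameters of punctum peak
#'   amplitude (intensity counts above the floor).
#' @param baseline flat background offset.
#' @param floor_sd standard deviation of the smooth noise floor.
#' @param floor_sigma correlation length (Gaussian blur sigma, px) of the
#'   noise floor.
#' @param psf_sigma Gaussian blur applied to the painted objects (px).
#' @param n_clutter number of clutter specks per puncta channel (default 0).
#' @param clutter_mean mean (exponential) amplitude of clutter specks.
#' @param dendrite_amp intensity of dendrite lines in the dendrite channel.
#' @return An [image_set()] (pixel size 50 nm/px, `source_id` `"synthetic"`).
#' @export
render_scene <- function(scene, mode = c("binary", "grayscale"),
                         seed = NULL, amp_meanlog = log(22), amp_sdlog = 0.75,
                         baseline = 20, floor_sd = 3, floor_sigma = 3,
                         psf_sigma = 1, n_clutter = 0L, clutter_mean = 4,
                         dendrite_amp = 40) {
  stopifnot(inherits(scene, "synthetic_scene"))
  mode <- match.arg(mode)
  shape <- scene$shape
  pre_c <- rbind(scene$true_pairs$pre, scene$pre_noise$centroids)
  post_c <- rbind(scene$true_pairs$post, scene$post_noise$centroids)
  if (mode == "binary") {
    return(image_set(
      pre = stamp_discs(pre_c, scene$radius_px, shape) * 1.0,
      post = stamp_discs(post_c, scene$radius_px, shape) * 1.0,
      dendrite = scene$dendrite_mask * 1.0,
      pixel_size_nm = 50, source_id = "synthetic"
    ))
  }
  paint <- function(centroids, amps, radius) {
    img <- matrix(0, shape[1], shape[2])
    if (nrow(centroids) == 0L) return(img)
    off <- disc_offsets(radius)
    rows <- rep(centroids[, 1], each = nrow(off)) + off[, 1]
    cols <- rep(centroids[, 2], each = nrow(off)) + off[, 2]
    vals <- rep(amps, each = nrow(off))
    keep <- rows >= 1 & rows <= shape[1] & cols >= 1 & cols <= shape[2]
    # accumulate into column-major linear indices: overlapping objects add
    lin <- (cols[keep] - 1L) * shape[1] + rows[keep]
    acc <- tapply(vals[keep], lin, sum)
    img[as.integer(names(acc))] <- acc
    img
  }
  channel <- function(centroids) {
    puncta <- paint(centroids,
                    stats::rlnorm(nrow(centroids), amp_meanlog, amp_sdlog),
                    scene$radius_px)
    if (n_clutter > 0) {
      puncta <- puncta + paint(cbind(sample.int(shape[1], n_clutter, TRUE),
                                     sample.int(shape[2], n_clutter, TRUE)),
                               stats::rexp(n_clutter, 1 / clutter_mean), 1L)
    }
    EBImage::gblur(puncta, sigma = psf_sigma)
  }
  smooth_floor <- function() {
    z <- EBImage::gblur(matrix(rnorm(prod(shape)), shape[1], shape[2]),
                        sigma = floor_sigma)
    baseline + z / sd(z) * floor_sd
  }
  with_seed(seed, {
    image_set(
      pre = pmax(channel(pre_c) + smooth_floor(), 0),
      post = pmax(channel(post_c) + smooth_floor(), 0),
      dendrite = pmax(EBImage::gblur(scene$dendrite_mask * dendrite_amp,
                                     sigma = 1) + smooth_floor(), 0),
      pixel_size_nm = 50, source_id = "synthetic"
    )
  })
}

#' Quantify a synthetic scene at the mask level
#'
#' Runs steps 2-3 of the algorithm (triple-AND counting plus noise
#' correction) directly on a scene's binary masks. The scene's channels
#' are already segmented objects, so the intensity-domain step 1
#' (background subtraction, filtering, thresholding, maxima) has nothing
#' to do and is bypassed; the dendrite mask is dilated exactly as the
#' detection pipeline would.
#'
#' @param scene a [simulate_scene()] result.
#' @param dendrite_dilation_px dendrite dilation radius (default 2).
#' @param noise_method `"randomization"`, `"crosscorr"`, or `"both"`.
#' @param n_reps randomization replicates.
#' @param seed optional integer seed.
#' @param max_shift_px largest displacement for [crosscorr_profile()].
#' @return A `coloc_result` (see [quantify_synapses()] for the attached
#'   attributes; here `pre_mask`/`post_mask` replace the puncta sets).
#' @export
quantify_scene <- function(scene, dendrite_dilation_px = 2L,
                           noise_method = c("randomization", "crosscorr",
                                            "both"),
                           n_reps = 10L, seed = NULL, max_shift_px = 50L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  noise_method <- match.arg(noise_method)
  shape <- scene$shape
  pre_m <- stamp_discs(rbind(scene$true_pairs$pre, scene$pre_noise$centroids),
                       scene$radius_px, shape)
  post_m <- stamp_discs(rbind(scene$true_pairs$post,
                              scene$post_noise$centroids),
                        scene$radius_px, shape)
  dend <- if (dendrite_dilation_px >= 1) {
    EBImage::dilate(scene$dendrite_mask * 1,
                    EBImage::makeBrush(2L * dendrite_dilation_px + 1L,
                                       "disc")) > 0.5
  } else {
    scene$dendrite_mask
  }
  total <- count_colocalizations(triple_and(pre_m, post_m, dend))
  xc <- NULL
  if (noise_method %in% c("crosscorr", "both")) {
    xc <- crosscorr_profile(pre_m, post_m, dend, max_shift_px = max_shift_px)
  }
  if (noise_method %in% c("randomization", "both")) {
    noise <- noise_by_mask_randomization(pre_m, post_m, dend,
                                         n_reps = n_reps, seed = seed)
    res <- corrected_density(total, noise, dend, 50,
                             noise_method = "randomization",
                             replicates = n_reps,
                             seed = if (is.null(seed)) NA_integer_ else seed)
    attr(res, "noise_se") <- attr(noise, "se")
  } else {
    res <- corrected_density(total, xc$asymptote, dend, 50,
                             noise_method = "crosscorrelation",
                             replicates = length(xc$shifts_px))
    attr(res, "noise_se") <- xc$asymptote_se
  }
  res$source_id <- "synthetic"
  attr(res, "crosscorr") <- xc
  attr(res, "pre_mask") <- pre_m
  attr(res, "post_mask") <- post_m
  attr(res, "dendrite_mask") <- dend
  res
}

#' Sensitivity of the detector across an SNR grid
#'
#' The validation harness: for every SNR in `snr_grid`, simulates
#' `n_scenes_per_snr` independent scenes with `n_true` true pairs, runs the
#' full detection and randomization noise-correction pipeline on the
#' rendered images, and averages per-scene results. Sensitivity is the
#' noise-corrected count divided by `n_true`; the uncorrected error is the
#' relative excess of the raw total over `n_true`.
#'
#' @param n_true true pairs per scene (default 800).
#' @param snr_grid SNR values to probe.
#' @param n_scenes_per_snr scenes averaged per SNR value (>= 1).
#' @param seed integer seed for the whole harness.
#' @param mode rendering mode passed to [render_scene()].
#' @param params detection parameters.
#' @param n_reps_noise randomization replicates per scene.
#' @param calib_reps Monte-Carlo replicates for SNR calibration.
#' @param shape,n_segments scene geometry.
#' @return Data frame with one row per SNR (columns `snr`, `realized_snr`,
#'   `total_detected`, `noise_estimate`, `corrected`, `sensitivity`,
#'   `uncorrected_error_pct`, `n_scenes`); per-scene rows in attribute
#'   `per_scene`.
#' @export
run_validation <- function(n_true = 800L, snr_grid = c(1.5, 2, 3, 4, 6),
                           n_scenes_per_snr = 5L, seed = 1L,
                           mode = c("binary", "grayscale"),
                           params = detection_params(), n_reps_noise = 10L,
                           calib_reps = 100L, shape = c(1024L, 1024L),
                           n_segments = 48L) {
  mode <- match.arg(mode)
  stopifnot(n_scenes_per_snr >= 1)
  grid <- expand.grid(scene = seq_len(n_scenes_per_snr), snr = snr_grid)
  seeds <- with_seed(seed, matrix(sample.int(2^30, 3 * nrow(grid)), ncol = 3))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    scene <- simulate_scene(n_true = n_true, target_snr = grid$snr[i],
                            shape = shape, n_segments = n_segments,
                            calib_reps = calib_reps, seed = seeds[i, 1])
    res <- if (mode == "binary") {
      # binary scenes are already segmented masks; apply steps 2-3 directly
      quantify_scene(scene, params$dendrite_dilation_px,
                     noise_method = "randomization",
                     n_reps = n_reps_noise, seed = seeds[i, 3])
    } else {
      iset <- render_scene(scene, mode = mode, seed = seeds[i, 2])
      quantify_synapses(iset, params, noise_method = "randomization",
                        n_reps = n_reps_noise, seed = seeds[i, 3])
    }
    data.frame(
      snr = grid$snr[i],
      realized_snr = scene$realized_snr,
      total_detected = res$total_count,
      noise_estimate = res$noise_estimate,
      corrected = res$corrected_count,
      sensitivity = res$corrected_count / n_true,
      uncorrected_error_pct = (res$total_count - n_true) / n_true * 100
    )
  })
  per_scene <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_scene, per_scene$snr), function(d) {
    out <- as.data.frame(lapply(d, mean))
    out$n_scenes <- nrow(d)
    out
  }))
  agg <- agg[order(agg$snr), ]
  rownames(agg) <- NULL
  attr(agg, "per_scene") <- per_scene
  agg
}

#' Write a scene to disk as TIFF masks plus a ground-truth sidecar
#'
#' Stores the three binary channels as single-page grayscale TIFFs and the
#' ground truth (pair centroids, noise centroids, calibration, seed) as a
#' JSON sidecar, so scenes can be re-analysed by external tools.
#'
#' @param scene a [simulate_scene()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("write_scene requires the 'jsonlite' package", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iset <- render_scene(scene, mode = "binary")
  paths <- file.path(dir, c("pre.tif", "post.tif", "dendrite.tif",
                            "ground_truth.json"))
  tiff::writeTIFF(iset$pre, paths[1], bits.per.sample = 8L)
  tiff::writeTIFF(iset$post, paths[2], bits.per.sample = 8L)
  tiff::writeTIFF(iset$dendrite, paths[3], bits.per.sample = 8L)
  gt <- list(
    n_true = scene$n_true,
    true_pre = scene$true_pairs$pre,
    true_post = scene$true_pairs$post,
    pre_noise = scene$pre_noise$centroids,
    post_noise = scene$post_noise$centroids,
    target_snr = scene$target_snr,
    realized_snr = scene$realized_snr,
    expected_chance = scene$expected_chance,
    radius_px = scene$radius_px,
    shape = scene$shape,
    seed = scene$seed
  )
  jsonlite::write_json(gt, paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
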