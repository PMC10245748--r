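# Internal geometry helpers shared by puncta and synthetic-scene code.

# Offsets (drow, dcol) of the rasterized disc of the given radius: pixels
# whose centers lie inside the circle of diameter 2r+1 (d <= r + 1/2).
# radius 2 -> 21 offsets, a 5-px-wide (250 nm at 50 nm/px) circular punctum.
# This rasterization guarantees that two puncta whose centroids satisfy the
# 250 nm rule (centre distance < 2r+1 px) always share at least one pixel.
disc_offsets <- function(radius_px) {
  r <- as.integer(radius_px)
  g <- expand.grid(drow = -r:r, dcol = -r:r)
  g <- g[g$drow^2 + g$dcol^2 <= (r + 0.5)^2, , drop = FALSE]
  as.matrix(g)
}

# Stamp discs of a fixed radius at the given (row, col) centroids into a
# logical mask, clipping at image borders. Overlapping discs simply merge.
stamp_discs <- function(centroids, radius_px, shape) {
  mask <- matrix(FALSE, shape[1], shape[2])
  if (is.null(centroids) || nrow(centroids) == 0L) {
    return(mask)
  }
  off <- disc_offsets(radius_px)
  rows <- rep(centroids[, 1], each = nrow(off)) + off[, 1]
  cols <- rep(centroids[, 2], each = nrow(off)) + off[, 2]
  keep <- rows >= 1L & rows <= shape[1] & cols >= 1L & cols <= shape[2]
  mask[cbind(rows[keep], cols[keep])] <- TRUE
  mask
}

assert_mask <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.logical(x)) {
    stop(sprintf("'%s' must be a logical matrix", name), call. = FALSE)
  }
  invisible(x)
}

assert_image <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x) || length(x) == 0L) {
    stop(sprintf("'%s' must be a non-empty numeric matrix", name), call. = FALSE)
  }
  invisible(x)
}

same_shape <- function(...) {
  dims <- lapply(list(...), dim)
  all(vapply(dims, identical, logical(1), dims[[1]]))
}

# Seed handling: functions that take a `seed` argument set it locally and
# restore the caller's RNG state on exit, so package calls never perturb
# the session RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
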