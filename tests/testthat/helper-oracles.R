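# Brute-force oracles, independent of the package's implementation paths.

# per-pixel max over a list of matrices, elementwise loop
oracle_max_project <- function(planes) {
  out <- planes[[1]]
  for (r in seq_len(nrow(out))) {
    for (c in seq_len(ncol(out))) {
      v <- vapply(planes, function(p) p[r, c], numeric(1))
      out[r, c] <- max(v)
    }
  }
  out
}

# square-window median with edge replication, sorted-neighborhood loop
oracle_median <- function(img, size) {
  h <- size %/% 2
  out <- img
  nr <- nrow(img)
  nc <- ncol(img)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      win <- numeric(0)
      for (dr in -h:h) {
        for (dc in -h:h) {
          rr <- min(max(r + dr, 1), nr)
          cc <- min(max(c + dc, 1), nc)
          win <- c(win, img[rr, cc])
        }
      }
      out[r, c] <- sort(win)[(size * size) %/% 2 + 1]
    }
  }
  out
}

# elementwise logical conjunction loop
oracle_triple_and <- function(a, b, d) {
  out <- matrix(FALSE, nrow(a), ncol(a))
  for (r in seq_len(nrow(a))) {
    for (c in seq_len(ncol(a))) {
      out[r, c] <- a[r, c] && b[r, c] && d[r, c]
    }
  }
  out
}

# 8-connected component count by iterative flood fill
oracle_count_components <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  nr <- nrow(mask)
  nc <- ncol(mask)
  count <- 0L
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (!mask[r0, c0] || seen[r0, c0]) next
      count <- count + 1L
      stack <- list(c(r0, c0))
      seen[r0, c0] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (dr in -1:1) {
          for (dc in -1:1) {
            rr <- p[1] + dr
            cc <- p[2] + dc
            if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
                mask[rr, cc] && !seen[rr, cc]) {
              seen[rr, cc] <- TRUE
              stack[[length(stack) + 1L]] <- c(rr, cc)
            }
          }
        }
      }
    }
  }
  count
}

# exhaustive 8-neighborhood local-maxima check (plateau-free images)
oracle_maxima <- function(img, threshold) {
  nr <- nrow(img)
  nc <- ncol(img)
  res <- NULL
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (img[r, c] <= threshold) next
      ge_all <- TRUE
      gt_any <- FALSE
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          rr <- r + dr
          cc <- c + dc
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
          if (img[r, c] < img[rr, cc]) ge_all <- FALSE
          if (img[r, c] > img[rr, cc]) gt_any <- TRUE
        }
      }
      if (ge_all && gt_any) res <- rbind(res, c(r, c))
    }
  }
  res
}

# stamp rasterized discs (centers within r + 0.5) -- test-side twin of the
# punctum rendering convention
oracle_stamp <- function(centroids, radius, shape) {
  mask <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(nrow(centroids))) {
    for (dr in -radius:radius) {
      for (dc in -radius:radius) {
        if (dr^2 + dc^2 > (radius + 0.5)^2) next
        rr <- centroids[i, 1] + dr
        cc <- centroids[i, 2] + dc
        if (rr >= 1 && rr <= shape[1] && cc >= 1 && cc <= shape[2]) {
          mask[rr, cc] <- TRUE
        }
      }
    }
  }
  mask
}

# write a matrix of 12-bit-scale integers to a 16-bit grayscale TIFF whose
# as.is values round-trip exactly
write_test_tiff <- function(img, path) {
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  path
}
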