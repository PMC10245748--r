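#' Batch synapse quantification over a manifest
#'
#' Processes a set of imaging fields described by a manifest data frame:
#' each entry is loaded, max-projected, screened for image quality (both
#' puncta channels must reach the SNR floor), quantified with
#' [quantify_synapses()], and emitted as one result row. Entries that fail
#' to load or fail the screen are skipped with a recorded reason; a failure
#' never aborts the batch. Per-entry seeds are derived deterministically
#' from the batch seed, so a rerun with the same manifest and seed
#' reproduces the table exactly.
#'
#' @param manifest data frame with columns `source_id`, `pre`, `post`,
#'   `dendrite` (file paths), optionally `nuclei` and grouping columns such
#'   as `group` (e.g. DIV label) and `synapse_type`; `source_id` must be
#'   unique.
#' @param params a [detection_params()].
#' @param noise_method,n_reps,max_shift_px passed to [quantify_synapses()].
#' @param pixel_size_nm physical pixel size of the inputs.
#' @param min_snr quality-screen floor (default 0.5).
#' @param seed integer batch seed.
#' @return Data frame with one row per analysed image (grouping columns
#'   echoed, then `total_count`, `noise_estimate`, `corrected_count`,
#'   `dendritic_area_um2`, `density_per_100um2`, `snr_pre`, `snr_post`,
#'   `seed`); skipped entries in attribute `dropped` (source_id, reason).
#' @export
run_batch <- function(manifest, params = detection_params(),
                      noise_method = "randomization", n_reps = 10L,
                      max_shift_px = 50L, pixel_size_nm = 50,
                      min_snr = 0.5, seed = 1L) {
  stopifnot(is.data.frame(manifest))
  need <- c("source_id", "pre", "post", "dendrite")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(manifest$source_id)) {
    stop("source_id values must be unique", call. = FALSE)
  }
  extra_cols <- setdiff(names(manifest), c(need, "nuclei"))
  rows <- list()
  dropped <- list()
  for (i in seq_len(nrow(manifest))) {
    entry <- manifest[i, ]
    entry_seed <- (seed + i) %% .Machine$integer.max
    res <- tryCatch({
      paths <- c(pre = entry$pre, post = entry$post, dendrite = entry$dendrite)
      if ("nuclei" %in% names(entry) && !is.na(entry$nuclei)) {
        paths <- c(paths, nuclei = entry$nuclei)
      }
      iset <- load_image_set(paths, pixel_size_nm = pixel_size_nm,
                             source_id = entry$source_id)
      iset <- project_image_set(iset)
      q_pre <- screen_quality(iset$pre, min_snr)
      q_post <- screen_quality(iset$post, min_snr)
      if (!q_pre$passed || !q_post$passed) {
        list(drop = paste0("quality screen: pre ", q_pre$reason,
                           "; post ", q_post$reason))
      } else {
        r <- quantify_synapses(iset, params, noise_method = noise_method,
                               n_reps = n_reps, seed = entry_seed,
                               max_shift_px = max_shift_px)
        row <- data.frame(
          source_id = entry$source_id,
          total_count = r$total_count,
          noise_estimate = r$noise_estimate,
          corrected_count = r$corrected_count,
          dendritic_area_um2 = r$dendritic_area_um2,
          density_per_100um2 = r$density_per_100um2,
          snr_pre = q_pre$snr_estimate,
          snr_post = q_post$snr_estimate,
          seed = entry_seed
        )
        for (cc in extra_cols) row[[cc]] <- entry[[cc]]
        list(row = row)
      }
    }, error = function(e) list(drop = conditionMessage(e)))
    if (!is.null(res$row)) {
      rows[[length(rows) + 1L]] <- res$row
    } else {
      dropped[[length(dropped) + 1L]] <- data.frame(
        source_id = entry$source_id, reason = res$drop)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  attr(out, "dropped") <- if (length(dropped)) {
    do.call(rbind, dropped)
  } else {
    data.frame(source_id = character(0), reason = character(0))
  }
  attr(out, "params") <- params
  out
}

#' Pairwise group comparisons of synaptic density
#'
#' Compares synaptic densities between labelled groups (e.g. developmental
#' stages 5 vs 8, 8 vs 14 and 14 vs 20 DIV) with the nonparametric Wilcoxon
#' rank-sum test, Bonferroni-corrected across the requested pairs; group
#' densities are summarized as mean +/- SEM.
#'
#' @param results data frame (e.g. from [run_batch()]).
#' @param group_col name of the grouping column.
#' @param pairs list of length-2 character vectors of group labels.
#' @param value_col name of the value column (default
#'   `"density_per_100um2"`).
#' @param alpha significance level on the adjusted p-value.
#' @return Data frame with one row per pair: `group_a`, `group_b`,
#'   `mean_a`, `sem_a`, `mean_b`, `sem_b`, `n_a`, `n_b`, `statistic`,
#'   `p_raw`, `p_adjusted`, `significant`.
#' @export
compare_groups <- function(results, group_col, pairs,
                           value_col = "density_per_100um2", alpha = 0.05) {
  stopifnot(is.data.frame(results), group_col %in% names(results),
            value_col %in% names(results), length(pairs) >= 1)
  groups <- split(results[[value_col]], results[[group_col]])
  sem <- function(v) sd(v) / sqrt(length(v))
  rows <- lapply(pairs, function(p) {
    stopifnot(length(p) == 2)
    if (!all(p %in% names(groups))) {
      stop("unknown group label in pair: ", paste(p, collapse = " vs "),
           call. = FALSE)
    }
    a <- groups[[p[1]]]
    b <- groups[[p[2]]]
    if (length(a) < 2 || length(b) < 2) {
      stop("each group needs at least 2 observations", call. = FALSE)
    }
    wt <- suppressWarnings(wilcox.test(a, b))
    data.frame(group_a = p[1], group_b = p[2],
               mean_a = mean(a), sem_a = sem(a),
               mean_b = mean(b), sem_b = sem(b),
               n_a = length(a), n_b = length(b),
               statistic = unname(wt$statistic), p_raw = wt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_raw, method = "bonferroni")
  out$significant <- out$p_adjusted < alpha
  out
}
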