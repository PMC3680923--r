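#' Compute log2 ratios against a normal-tissue reference
#'
#' Converts per-probe intensities to copy-number log-ratios. The reference at
#' each probe is the mean intensity over the designated normal samples, so a
#' probe value is `log2(intensity / mean(normal intensities))`; normal
#' samples themselves are retained in the output (their profiles fluctuate
#' around zero).
#'
#' @param intensity Wide data frame: columns `chrom`, `pos`, plus one numeric
#'   column per sample. All intensities must be strictly positive.
#' @param normal_samples Character vector of column names to use as the
#'   normal reference (at least one).
#' @param sample_info Optional data frame with columns `sample`, `patient`,
#'   `lesion` to annotate the output; unknown samples get `NA` metadata.
#' @return Long tibble with columns `sample`, `patient`, `lesion`, `chrom`,
#'   `pos`, `logratio`.
#' @export
compute_log_ratios <- function(intensity, normal_samples, sample_info = NULL) {
  stopifnot(all(c("chrom", "pos") %in% names(intensity)))
  samples <- setdiff(names(intensity), c("chrom", "pos"))
  if (length(normal_samples) == 0 || !all(normal_samples %in% samples)) {
    stop("normal_samples must name at least one intensity column", call. = FALSE)
  }
  mat <- as.matrix(intensity[, samples, drop = FALSE])
  if (any(!is.finite(mat)) || any(mat <= 0)) {
    stop("intensities must be finite and strictly positive", call. = FALSE)
  }
  ref <- rowMeans(mat[, normal_samples, drop = FALSE])
  lr <- log2(mat / ref)
  out <- tibble::tibble(
    sample = rep(samples, each = nrow(mat)),
    chrom = rep(norm_chrom(intensity$chrom), times = length(samples)),
    pos = rep(intensity$pos, times = length(samples)),
    logratio = as.vector(lr)
  )
  if (!is.null(sample_info)) {
    out <- dplyr::left_join(out, sample_info[, c("sample", "patient", "lesion")],
                            by = "sample")
  } else {
    out$patient <- NA_character_
    out$lesion <- NA_character_
  }
  out[, c("sample", "patient", "lesion", "chrom", "pos", "logratio")]
}

#' Drop probes inside germline-CNV regions
#'
#' Removes every marker whose position lies inside any region of the CNV
#' region set (1-based inclusive; see [read_region_bed()]) from the profile
#' table, reporting the number of distinct markers removed.
#'
#' @param profiles Profile tibble (long; columns `chrom`, `pos` at minimum).
#' @param regions Region tibble. An empty region set is the identity.
#' @param quiet Suppress the removed-marker message.
#' @return The filtered profile tibble; the count of removed markers is
#'   attached as attribute `n_removed`.
#' @export
exclude_cnv_probes <- function(profiles, regions, quiet = FALSE) {
  mk <- unique(profiles[, c("chrom", "pos")])
  inside <- region_overlaps(regions, mk$chrom, mk$pos)
  bad <- mk[inside, , drop = FALSE]
  out <- dplyr::anti_join(profiles, bad, by = c("chrom", "pos"))
  if (!quiet) {
    message(nrow(bad), " marker(s) inside germline-CNV regions removed")
  }
  attr(out, "n_removed") <- nrow(bad)
  out
}

#' Reduce resolution by averaging blocks of adjacent markers
#'
#' Collapses runs of `block_size` adjacent markers into one marker at their
#' mean position with their mean log-ratio, lowering noise by roughly
#' `sqrt(block_size)`. Blocks are anchored at the start of each chromosome
#' arm and never span an arm boundary (so no block straddles a centromere).
#' A trailing partial block of at least `block_size * min_frac` markers
#' becomes its own marker; a shorter one is merged into the preceding block.
#' Missing values are skipped inside a block; a block is missing only if all
#' of its inputs are.
#'
#' @param profiles Profile tibble; arm columns are added via [assign_arms()]
#'   if absent.
#' @param layout Arm layout (used only if arm assignment is missing).
#' @param block_size Markers per block (default 100).
#' @param min_frac Minimum trailing-block fraction kept as its own marker
#'   (default 0.5).
#' @return Reduced profile tibble with refreshed `marker` indices.
#' @export
block_average <- function(profiles, layout = default_layout(),
                          block_size = 100, min_frac = 0.5) {
  stopifnot(block_size >= 1, min_frac > 0, min_frac <= 1)
  if (!"arm_index" %in% names(profiles)) {
    profiles <- as_profiles(profiles, layout, max_missing = 1)
  }
  mk <- unique(profiles[, c("chrom", "pos", "arm", "arm_id", "arm_index")])
  mk <- mk[order(mk$arm_index, mk$pos), , drop = FALSE]
  blk <- unlist(lapply(split(seq_len(nrow(mk)), mk$arm_index), function(idx) {
    arm_block_ids(length(idx), block_size, min_frac)
  }), use.names = FALSE)
  mk$block <- paste(mk$arm_index, blk, sep = ".")
  joined <- dplyr::inner_join(profiles, mk[, c("chrom", "pos", "block")],
                              by = c("chrom", "pos"))
  meta_cols <- intersect(c("patient", "lesion"), names(joined))
  out <- dplyr::summarise(
    dplyr::group_by(joined, dplyr::across(dplyr::all_of(c("sample", meta_cols, "block")))),
    chrom = .data$chrom[1],
    pos = round(mean(.data$pos)),
    logratio = if (all(is.na(.data$logratio))) NA_real_ else
      mean(.data$logratio, na.rm = TRUE),
    .groups = "drop"
  )
  out$block <- NULL
  as_profiles(out, layout, max_missing = 1)
}

# Block id per marker for one arm of n markers: full blocks of size B, the
# trailing remainder kept separate iff >= B * min_frac (and there is a
# preceding block to merge into otherwise).
arm_block_ids <- function(n, block_size, min_frac) {
  if (n == 0) return(integer(0))
  k <- n %/% block_size
  r <- n %% block_size
  ids <- pmin(ceiling(seq_len(n) / block_size), max(k, 1L))
  if (r > 0 && (r >= block_size * min_frac || k == 0)) {
    ids[(k * block_size + seq_len(r))] <- k + 1L
  }
  ids
}

#' Median-center a profile table
#'
#' Subtracts each sample's genome-wide median log-ratio so that the
#' copy-neutral baseline sits at zero, the reference level assumed by arm
#' calling. Idempotent.
#'
#' @param profiles Profile tibble.
#' @return The centered profile tibble (per-sample median of `logratio` = 0).
#' @export
median_center <- function(profiles) {
  med <- tapply(profiles$logratio, profiles$sample, stats::median, na.rm = TRUE)
  if (any(is.na(med))) {
    stop("sample(s) with all log-ratios missing: ",
         paste(names(med)[is.na(med)], collapse = ", "), call. = FALSE)
  }
  profiles$logratio <- as.vector(profiles$logratio - med[profiles$sample])
  profiles
}
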