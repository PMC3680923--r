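#' Read a marker-level profile table
#'
#' Reads a tab-delimited table of marker log2 copy-number ratios with header
#' columns `sample`, `patient`, `lesion`, `chrom`, `pos`, `logratio` (one row
#' per sample x marker). All samples must share one marker set; markers that
#' fall outside the arm layout are dropped with a warning reporting the count.
#'
#' @param path Path to the tab-delimited file.
#' @param layout Chromosome-arm layout tibble ([default_layout()] by default).
#' @param max_missing Reject a sample whose fraction of missing log-ratios
#'   exceeds this (default 0.2).
#' @return A profile tibble: `sample`, `patient`, `lesion`, `chrom`, `pos`,
#'   `logratio`, plus arm assignment columns `arm`, `arm_id`, `arm_index` and
#'   the global `marker` index. Ordered by sample, then genome order.
#' @export
read_profile_table <- function(path, layout = default_layout(), max_missing = 0.2) {
  tbl <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(), patient = readr::col_character(),
    lesion = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_double(), logratio = readr::col_double()
  ), na = c("", "NA"), progress = FALSE, lazy = FALSE))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    # problems() reports file line numbers (header included)
    stop("malformed profile table at line ", probs$row[1], " of ", path,
         ": expected ", probs$expected[1], call. = FALSE)
  }
  need <- c("sample", "patient", "lesion", "chrom", "pos", "logratio")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols)) {
    stop("profile table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(is.na(tbl$sample) | is.na(tbl$chrom) | is.na(tbl$pos))
  if (length(bad)) {
    stop("malformed profile table at line ", bad[1] + 1L, " of ", path,
         ": missing sample/chrom/pos", call. = FALSE)
  }
  as_profiles(tbl, layout = layout, max_missing = max_missing)
}

#' Validate and arm-annotate an in-memory profile table
#'
#' The data-frame-first equivalent of [read_profile_table()]: checks that all
#' samples share one marker set and that no sample exceeds the missingness
#' cap, assigns markers to arms, and orders rows by sample then genome order.
#'
#' @inheritParams read_profile_table
#' @param profiles Data frame with columns `sample`, `patient`, `lesion`,
#'   `chrom`, `pos`, `logratio`.
#' @return A profile tibble (see [read_profile_table()]).
#' @export
as_profiles <- function(profiles, layout = default_layout(), max_missing = 0.2) {
  profiles <- tibble::as_tibble(profiles)
  # re-derive any stale arm annotation
  profiles <- profiles[, setdiff(names(profiles),
                                 c("arm", "arm_id", "arm_index", "marker"))]
  profiles$chrom <- norm_chrom(profiles$chrom)
  key <- paste(profiles$chrom, profiles$pos)
  sets <- split(key, profiles$sample)
  ref <- sort(sets[[1]])
  same <- vapply(sets, function(k) identical(sort(k), ref), logical(1))
  if (!all(same)) {
    stop("inconsistent marker sets across samples: ",
         paste(names(sets)[!same], collapse = ", "), call. = FALSE)
  }
  markers <- assign_arms(unique(profiles[, c("chrom", "pos")]), layout)
  profiles <- dplyr::inner_join(
    profiles, markers[, c("chrom", "pos", "arm", "arm_id", "arm_index", "marker")],
    by = c("chrom", "pos")
  )
  profiles <- profiles[order(profiles$sample, profiles$marker), , drop = FALSE]
  miss <- tapply(is.na(profiles$logratio), profiles$sample, mean)
  if (any(miss > max_missing)) {
    stop("sample(s) exceed ", round(100 * max_missing),
         "% missing log-ratios: ",
         paste(names(miss)[miss > max_missing], collapse = ", "), call. = FALSE)
  }
  profiles
}

#' Write a marker-level profile table
#'
#' Inverse of [read_profile_table()]; only the six canonical columns are
#' written, so a write/read round trip reproduces values exactly.
#'
#' @param profiles Profile tibble.
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  cols <- c("sample", "patient", "lesion", "chrom", "pos", "logratio")
  readr::write_tsv(profiles[, cols], path, progress = FALSE)
  invisible(path)
}

#' Read germline-CNV regions from a BED file
#'
#' BED intervals (0-based, half-open; first three columns used) are converted
#' to the package's 1-based inclusive convention, so BED `chr1 100 200`
#' becomes `chr1:[101, 200]`.
#'
#' @param path Path to the BED file.
#' @param layout Optional layout; intervals on chromosomes absent from it are
#'   skipped with a warning.
#' @return A region tibble with columns `chrom`, `start`, `end` (1-based
#'   inclusive). Zero rows for an empty file.
#' @export
read_region_bed <- function(path, layout = NULL) {
  tbl <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "numeric", "numeric"),
                           col.names = c("chrom", "start", "end"),
                           comment.char = "#", fill = FALSE,
                           blank.lines.skip = TRUE)[, 1:3]
  tbl <- tibble::as_tibble(tbl)
  if (nrow(tbl) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  if (any(tbl$start >= tbl$end)) {
    stop("BED interval with start >= end at line ",
         which(tbl$start >= tbl$end)[1], call. = FALSE)
  }
  tbl$chrom <- norm_chrom(tbl$chrom)
  if (!is.null(layout)) {
    known <- tbl$chrom %in% layout$chrom
    if (any(!known)) {
      warning(sum(!known), " region(s) on chromosomes outside the layout were skipped",
              call. = FALSE)
      tbl <- tbl[known, , drop = FALSE]
    }
  }
  tibble::tibble(chrom = tbl$chrom, start = tbl$start + 1, end = tbl$end)
}

#' Write regions back to BED
#'
#' Converts the internal 1-based inclusive intervals to 0-based half-open
#' BED; the exact inverse of [read_region_bed()].
#'
#' @param regions Region tibble (`chrom`, `start`, `end`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(regions, path) {
  out <- data.frame(chrom = regions$chrom, start = regions$start - 1,
                    end = regions$end)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Any-overlap query of spans against a region set, both 1-based inclusive.
# Returns a logical per query span.
region_overlaps <- function(regions, chrom, start, end = start) {
  chrom <- norm_chrom(chrom)
  hit <- rep(FALSE, length(chrom))
  if (is.null(regions) || nrow(regions) == 0) return(hit)
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    reg <- regions[regions$chrom == ch, , drop = FALSE]
    if (nrow(reg) == 0) next
    ov <- IRanges::overlapsAny(
      IRanges::IRanges(start = start[sel], end = end[sel]),
      IRanges::IRanges(start = reg$start, end = reg$end)
    )
    hit[sel] <- ov
  }
  hit
}

#' Write segmentations in SEG format
#'
#' Writes one row per segment (including unchanged flanking segments) in the
#' IGV SEG dialect: `ID`, `chrom`, `loc.start`, `loc.end`, `num.mark`,
#' `seg.mean`. Segment rows tile each arm's markers exactly.
#'
#' @param segmentation A segmentation tibble from [segment_profiles()].
#' @param markers Marker tibble (the distinct marker rows of the profile
#'   tibble that was segmented); taken from the segmentation's attributes if
#'   omitted.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segmentation, path, markers = attr(segmentation, "markers")) {
  if (is.null(markers)) {
    stop("write_seg needs the marker table (markers = ...)", call. = FALSE)
  }
  rows <- seg_rows(segmentation, markers)
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

# Expands the nested per-arm segment tibbles into flat SEG rows.
seg_rows <- function(segmentation, markers) {
  markers <- markers[order(markers$marker), , drop = FALSE]
  arm_first <- tapply(markers$marker, markers$arm_index, min)
  per_row <- purrr::pmap(
    list(segmentation$sample, segmentation$chrom, segmentation$arm_index,
         segmentation$segments),
    function(sample, chrom, arm_index, segs) {
      offset <- arm_first[[as.character(arm_index)]] - 1L
      tibble::tibble(
        ID = sample, chrom = chrom,
        loc.start = markers$pos[segs$lo + offset],
        loc.end = markers$pos[segs$hi + offset],
        num.mark = segs$hi - segs$lo + 1L,
        seg.mean = round(segs$mean, 6)
      )
    }
  )
  dplyr::bind_rows(per_row)
}
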