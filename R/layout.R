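#' Default autosomal chromosome-arm layout
#'
#' Returns the packaged genome layout of 39 autosomal chromosome arms.
#' The five acrocentric short arms (13p, 14p, 15p, 21p, 22p) carry no
#' reliably assayable sequence on SNP platforms and are excluded, as is
#' conventional for arm-level copy-number analyses; sex chromosomes are
#' excluded because the analysis baseline (log-ratio zero = two copies)
#' does not hold for them across sexes. Coordinates are approximate
#' hg19-style arm boundaries; the pipeline treats positions as opaque but
#' internally consistent, so any layout on the same build as the marker
#' positions works.
#'
#' @param include_acrocentric_p Keep the acrocentric p arms (rarely wanted).
#' @return A tibble with columns `chrom` (character, "1".."22"), `arm`
#'   ("p"/"q"), `arm_id` (e.g. "16q"), `start`, `end` (1-based inclusive bp).
#' @export
#' @examples
#' default_layout()
default_layout <- function(include_acrocentric_p = FALSE) {
  len <- c(249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
           159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
           115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
           59128983, 63025520, 48129895, 51304566)
  cen <- c(125000000, 93300000, 91000000, 50400000, 48400000, 61000000,
           59900000, 45600000, 49000000, 40200000, 53700000, 35800000,
           17900000, 17600000, 19000000, 36600000, 24000000, 17200000,
           26500000, 27500000, 13200000, 14700000)
  chrom <- as.character(seq_len(22))
  layout <- tibble::tibble(
    chrom = rep(chrom, each = 2),
    arm   = rep(c("p", "q"), times = 22),
    start = as.numeric(rbind(1, cen + 1)),
    end   = as.numeric(rbind(cen, len))
  )
  if (!include_acrocentric_p) {
    drop <- layout$arm == "p" & layout$chrom %in% c("13", "14", "15", "21", "22")
    layout <- layout[!drop, ]
  }
  layout$arm_id <- paste0(layout$chrom, layout$arm)
  validate_layout(layout[, c("chrom", "arm", "arm_id", "start", "end")])
}

#' Read a chromosome-arm layout table
#'
#' @param path Tab-delimited file with header columns `chrom`, `arm`,
#'   `start`, `end` (1-based inclusive).
#' @return A validated layout tibble (see [default_layout()]).
#' @export
read_layout <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), arm = readr::col_character(),
    start = readr::col_double(), end = readr::col_double()
  ), progress = FALSE)
  tbl$chrom <- norm_chrom(tbl$chrom)
  tbl$arm_id <- paste0(tbl$chrom, tbl$arm)
  validate_layout(tbl[, c("chrom", "arm", "arm_id", "start", "end")])
}

# Checks the layout invariants: start < end, p before q, arms non-overlapping
# within chromosome, rows ordered by chromosome then position.
validate_layout <- function(layout) {
  stopifnot(all(c("chrom", "arm", "arm_id", "start", "end") %in% names(layout)))
  if (any(layout$start >= layout$end)) {
    stop("layout: every arm must have start < end", call. = FALSE)
  }
  if (!all(layout$arm %in% c("p", "q"))) {
    stop("layout: arm labels must be 'p' or 'q'", call. = FALSE)
  }
  if (anyDuplicated(layout$arm_id)) {
    stop("layout: duplicated arm_id", call. = FALSE)
  }
  layout <- layout[order(chrom_rank(layout$chrom), layout$start), , drop = FALSE]
  by_chr <- split(layout, layout$chrom)
  for (ch in by_chr) {
    if (nrow(ch) > 1) {
      if (any(ch$start[-1] <= ch$end[-nrow(ch)])) {
        stop("layout: overlapping arms on chromosome ", ch$chrom[1], call. = FALSE)
      }
      if (!identical(ch$arm, sort(ch$arm))) {
        stop("layout: p arm must precede q arm on chromosome ", ch$chrom[1], call. = FALSE)
      }
    }
  }
  layout$arm_index <- seq_len(nrow(layout))
  tibble::as_tibble(layout)
}

# "chr1"/"Chr1"/"1" -> "1"; keeps non-numeric labels (X, Y) as-is.
norm_chrom <- function(x) {
  sub("^[Cc][Hh][Rr]", "", as.character(x))
}

# Sort key: numeric chromosomes first in numeric order, then others
# alphabetically. Gives the total marker order used across the package.
chrom_rank <- function(chrom) {
  chrom <- norm_chrom(chrom)
  num <- suppressWarnings(as.numeric(chrom))
  rank <- ifelse(is.na(num), 1000 + match(chrom, sort(unique(chrom[is.na(num)]))), num)
  rank
}

#' Assign markers to chromosome arms
#'
#' Maps each (chrom, pos) marker onto the arm containing it and attaches a
#' global marker index in genome order (chromosome rank, then position).
#' Markers falling in no layout arm (centromeric or off-layout) are dropped
#' with a warning reporting the count.
#'
#' @param markers A data frame with columns `chrom` and `pos`.
#' @param layout A layout tibble from [default_layout()] or [read_layout()].
#' @param quiet Suppress the dropped-marker warning.
#' @return The input rows that fall inside an arm, ordered, with added
#'   columns `arm`, `arm_id`, `arm_index` and global `marker` index.
#' @export
assign_arms <- function(markers, layout = default_layout(), quiet = FALSE) {
  stopifnot(all(c("chrom", "pos") %in% names(markers)))
  markers <- tibble::as_tibble(markers)
  markers$chrom <- norm_chrom(markers$chrom)
  key_m <- markers$chrom
  hit <- rep(NA_integer_, nrow(markers))
  for (ch in unique(layout$chrom)) {
    sel <- which(key_m == ch)
    if (!length(sel)) next
    arms <- layout[layout$chrom == ch, ]
    ir_m <- IRanges::IRanges(start = markers$pos[sel], width = 1L)
    ir_a <- IRanges::IRanges(start = arms$start, end = arms$end)
    ov <- IRanges::findOverlaps(ir_m, ir_a, select = "first")
    hit[sel] <- ifelse(is.na(ov), NA_integer_, arms$arm_index[ov])
  }
  dropped <- sum(is.na(hit))
  if (dropped > 0 && !quiet) {
    warning(dropped, " marker(s) outside the arm layout were dropped",
            call. = FALSE)
  }
  out <- markers[!is.na(hit), , drop = FALSE]
  out$arm_index <- hit[!is.na(hit)]
  out <- out[order(out$arm_index, out$pos), , drop = FALSE]
  out$arm <- layout$arm[out$arm_index]
  out$arm_id <- layout$arm_id[out$arm_index]
  out$marker <- seq_len(nrow(out))
  attr(out, "n_dropped") <- dropped
  out
}
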