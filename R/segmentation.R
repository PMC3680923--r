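#' Segmentation configuration
#'
#' Tuning constants for the per-arm single-change segmentation.
#'
#' @param tau Change-significance threshold on the scan statistic `|T|` (and
#'   on the whole-arm z-statistic). The default 5.0 keeps the family-wise
#'   false-call rate across ~39 arms of a few hundred markers each well below
#'   1% under pure noise.
#' @param delta_min Minimum absolute calling-segment mean (log2 units) for a
#'   GAIN/LOSS call; smaller shifts are left NORMAL.
#' @param min_markers Minimum markers in a candidate change segment.
#' @param min_seg_bp Segments shorter than this (bp, first to last marker)
#'   that overlap a known germline CNV region are discarded (reset to
#'   NORMAL). Default 2.3 Mb.
#' @param regions Optional germline-CNV region tibble ([read_region_bed()]);
#'   `NULL` disables the CNV segment filter.
#' @param sigma Optional fixed noise SD; estimated per sample via
#'   [estimate_noise()] when `NULL`.
#' @return A list of class `seg_config`.
#' @export
seg_config <- function(tau = 5, delta_min = 0.10, min_markers = 3L,
                       min_seg_bp = 2.3e6, regions = NULL, sigma = NULL) {
  stopifnot(tau > 0, delta_min > 0, min_markers >= 1, min_seg_bp > 0)
  structure(list(tau = tau, delta_min = delta_min,
                 min_markers = as.integer(min_markers),
                 min_seg_bp = min_seg_bp, regions = regions, sigma = sigma),
            class = "seg_config")
}

#' Estimate the marker-level noise SD of each sample
#'
#' Robust noise scale from first differences of adjacent markers: within
#' each arm, `1.4826 * median(|diff|) / sqrt(2)` over non-missing values
#' (the MAD-consistent SD of a difference of two independent markers);
#' per-arm estimates are pooled by their median, so isolated true
#' copy-number jumps do not inflate the estimate.
#'
#' @param profiles Profile tibble (arm-annotated; see [as_profiles()]).
#' @return Tibble with columns `sample`, `sigma`.
#' @export
estimate_noise <- function(profiles) {
  if (!"arm_index" %in% names(profiles)) {
    profiles <- as_profiles(profiles, max_missing = 1)
  }
  profiles <- profiles[order(profiles$sample, profiles$marker), , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(profiles, .data$sample),
    sigma = noise_one(.data$logratio, .data$arm_index),
    .groups = "drop"
  )
  out
}

noise_one <- function(values, arm_index) {
  if (sum(!is.na(values)) < 10) {
    stop("estimate_noise needs at least 10 non-missing markers", call. = FALSE)
  }
  per_arm <- vapply(split(values, arm_index), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    1.4826 * stats::median(abs(diff(v))) / sqrt(2)
  }, numeric(1))
  stats::median(per_arm, na.rm = TRUE)
}

#' Scan one arm for its best single change
#'
#' Exhaustively maximizes `|T(i, j)|` over all contiguous candidate segments
#' `i..j` of at least `min_markers` markers, where
#' `T = (mean inside - mean outside) / (sigma * sqrt(1/n_in + 1/n_out))`,
#' and compares the best interior/edge segment against the whole-arm
#' z-statistic `mean / (sigma / sqrt(m))`. Missing values are skipped; the
#' returned indices refer to the full arm (1..length(values)). Ties go to
#' the smallest `i`, then the smallest `j`.
#'
#' @param values Numeric vector of one arm's log-ratios (may contain `NA`).
#' @param sigma Noise SD (floored at 1e-6).
#' @param config A [seg_config()].
#' @return List with elements `i`, `j` (candidate segment, arm index space),
#'   `t_stat` (its signed statistic; the whole-arm z when the candidate is
#'   the whole arm), `z_whole`, `n_bkpt` (0, 1 or 2 breakpoints implied) and
#'   `m_obs` (non-missing marker count). All-`NA` arms give `NULL`.
#' @export
segment_arm <- function(values, sigma, config = seg_config()) {
  obs <- which(!is.na(values))
  n_obs <- length(obs)
  if (n_obs == 0) return(NULL)
  sigma <- max(sigma, 1e-6)
  x <- values[obs]
  z_whole <- mean(x) / (sigma / sqrt(n_obs))
  cand <- .scan_one_change(x, config$min_markers)
  t_part <- if (is.na(cand[3])) NA_real_ else cand[3] / sigma
  # choose between best partial segment and the whole arm; lexicographic
  # (i, j) tie-break, with the whole arm sitting at (1, n_obs)
  use_whole <- is.na(t_part) || abs(z_whole) > abs(t_part) ||
    (abs(z_whole) == abs(t_part) && cand[1] > 1)
  if (use_whole) {
    io <- 1L; jo <- n_obs; t_stat <- z_whole
  } else {
    io <- as.integer(cand[1]); jo <- as.integer(cand[2]); t_stat <- t_part
  }
  n_bkpt <- (io > 1L) + (jo < n_obs)
  list(i = obs[io], j = obs[jo], i_obs = io, j_obs = jo,
       t_stat = t_stat, z_whole = z_whole, n_bkpt = as.integer(n_bkpt),
       m_obs = n_obs, obs = obs)
}

#' Classify one arm from its scan candidate
#'
#' Applies the calling rule: an arm is NORMAL when neither the candidate
#' statistic nor the whole-arm z reaches `tau`. Otherwise the calling
#' segment is the central segment when the candidate has two breakpoints,
#' the more outstanding (larger `|mean|`) of the two segments when it has
#' one, and the whole arm when it has none. The arm is called GAIN when the
#' calling-segment mean is at least `+delta_min`, LOSS when at most
#' `-delta_min`, and NORMAL otherwise (empty footprint, zero magnitude).
#'
#' @inheritParams segment_arm
#' @param candidate Result of [segment_arm()] on the same values.
#' @return One-row tibble: `i`, `j`, `n_bkpt`, `t_stat`, `z_whole`, `call`,
#'   `magnitude`, `fp_lo`, `fp_hi` (calling-segment bounds, arm index space,
#'   `NA` when NORMAL), `whole_arm`, and a nested `segments` tibble
#'   (`lo`, `hi`, `n`, `mean`) tiling the arm.
#' @export
classify_arm <- function(values, candidate, sigma, config = seg_config()) {
  m <- length(values)
  if (is.null(candidate)) {
    return(arm_record(m, values, call = "NORMAL"))
  }
  tau <- config$tau
  if (abs(candidate$t_stat) < tau && abs(candidate$z_whole) < tau) {
    return(arm_record(m, values, call = "NORMAL",
                      t_stat = candidate$t_stat, z_whole = candidate$z_whole))
  }
  obs <- candidate$obs
  io <- candidate$i_obs; jo <- candidate$j_obs; n_obs <- candidate$m_obs
  seg_mean <- function(a, b) mean(values[obs[a:b]])
  if (abs(candidate$t_stat) < tau) {
    # only the whole-arm z clears tau: zero-breakpoint calling segment
    fp <- c(1L, n_obs)
  } else if (candidate$n_bkpt == 2L) {
    fp <- c(io, jo)
  } else if (candidate$n_bkpt == 1L) {
    if (io == 1L) {
      other <- c(jo + 1L, n_obs)
    } else {
      other <- c(1L, io - 1L)
    }
    fp <- if (abs(seg_mean(io, jo)) >= abs(seg_mean(other[1], other[2]))) {
      c(io, jo)
    } else other
  } else {
    fp <- c(1L, n_obs)
  }
  mag <- seg_mean(fp[1], fp[2])
  call <- if (mag >= config$delta_min) "GAIN" else
    if (mag <= -config$delta_min) "LOSS" else "NORMAL"
  if (call == "NORMAL") {
    return(arm_record(m, values, call = "NORMAL",
                      t_stat = candidate$t_stat, z_whole = candidate$z_whole))
  }
  arm_record(m, values, call = call, magnitude = mag,
             fp_lo = obs[fp[1]], fp_hi = obs[fp[2]],
             i = candidate$i, j = candidate$j, n_bkpt = candidate$n_bkpt,
             t_stat = candidate$t_stat, z_whole = candidate$z_whole,
             whole_arm = fp[1] == 1L && fp[2] == n_obs)
}

# Builds the one-row arm tibble plus its tiling segments.
arm_record <- function(m, values, call, magnitude = 0, fp_lo = NA_integer_,
                       fp_hi = NA_integer_, i = NA_integer_, j = NA_integer_,
                       n_bkpt = 0L, t_stat = NA_real_, z_whole = NA_real_,
                       whole_arm = FALSE) {
  if (call == "NORMAL" || whole_arm) {
    cuts <- 1L
  } else {
    cuts <- sort(unique(c(1L, fp_lo, fp_hi + 1L)))
    cuts <- cuts[cuts <= m]
  }
  lo <- cuts
  hi <- c(cuts[-1] - 1L, m)
  if (m == 0) lo <- hi <- integer(0)
  seg_mean <- vapply(seq_along(lo), function(k) {
    v <- values[lo[k]:hi[k]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  segs <- tibble::new_tibble(
    list(lo = lo, hi = hi, n = hi - lo + 1L, mean = seg_mean),
    nrow = length(lo))
  tibble::new_tibble(list(
    i = as.integer(i), j = as.integer(j), n_bkpt = n_bkpt,
    t_stat = t_stat, z_whole = z_whole,
    call = call, magnitude = if (call == "NORMAL") 0 else magnitude,
    fp_lo = if (call == "NORMAL") NA_integer_ else as.integer(fp_lo),
    fp_hi = if (call == "NORMAL") NA_integer_ else as.integer(fp_hi),
    whole_arm = if (call == "NORMAL") FALSE else whole_arm,
    segments = list(segs)
  ), nrow = 1L)
}

#' Discard short calling segments overlapping germline CNV regions
#'
#' A called (non-NORMAL) arm whose calling-segment genomic span (first to
#' last footprint marker) is shorter than `config$min_seg_bp` *and* overlaps
#' any germline CNV region by at least 1 bp is reset to NORMAL: inherited
#' copy-number variation must not masquerade as a somatic event. Longer
#' segments, and short segments clear of CNV regions, are kept.
#'
#' @param segmentation Segmentation tibble ([segment_profiles()]).
#' @param regions Germline-CNV region tibble.
#' @param config A [seg_config()].
#' @param markers Marker tibble; defaults to the segmentation's attribute.
#' @return The segmentation with affected arms reset to NORMAL.
#' @export
filter_cnv_segment <- function(segmentation, regions, config = seg_config(),
                               markers = attr(segmentation, "markers")) {
  if (is.null(regions) || nrow(regions) == 0 || nrow(segmentation) == 0) {
    return(segmentation)
  }
  called <- which(segmentation$call != "NORMAL")
  if (!length(called)) return(segmentation)
  span <- segmentation$fp_end_bp[called] - segmentation$fp_start_bp[called]
  hit <- region_overlaps(regions, segmentation$chrom[called],
                         segmentation$fp_start_bp[called],
                         segmentation$fp_end_bp[called])
  reset <- called[span < config$min_seg_bp & hit]
  for (r in reset) {
    m <- segmentation$m[r]
    segs <- segmentation$segments[[r]]
    keep <- !is.na(segs$mean)
    arm_mean <- sum(segs$mean[keep] * segs$n[keep]) / sum(segs$n[keep])
    segmentation$call[r] <- "NORMAL"
    segmentation$magnitude[r] <- 0
    segmentation$n_bkpt[r] <- 0L
    segmentation$i[r] <- NA_integer_
    segmentation$j[r] <- NA_integer_
    segmentation$fp_lo[r] <- NA_integer_
    segmentation$fp_hi[r] <- NA_integer_
    segmentation$fp_start_marker[r] <- NA_integer_
    segmentation$fp_end_marker[r] <- NA_integer_
    segmentation$fp_start_bp[r] <- NA_real_
    segmentation$fp_end_bp[r] <- NA_real_
    segmentation$span_bp[r] <- NA_real_
    segmentation$whole_arm[r] <- FALSE
    segmentation$segments[[r]] <- tibble::tibble(
      lo = 1L, hi = m, n = m, mean = arm_mean)
  }
  segmentation
}

#' Segment every sample's profile arm by arm
#'
#' Runs the single-change-per-arm segmentation over all samples of a profile
#' table: estimates each sample's noise SD, scans every chromosome arm for
#' its best candidate change, classifies arms as GAIN / LOSS / NORMAL, and
#' (when `config$regions` is supplied) discards short calling segments that
#' overlap germline CNV regions. Arms are processed independently, so
#' results do not depend on processing order.
#'
#' @param profiles Profile tibble (preprocessed and median-centered).
#' @param layout Arm layout; used if the profile table lacks arm columns.
#' @param config A [seg_config()].
#' @return A tibble of class `cn_segmentation`, one row per sample x arm:
#'   sample metadata, arm identity, marker counts, the scan statistics, the
#'   `call` with `magnitude` and footprint columns (`fp_*`), `span_bp`,
#'   `whole_arm`, and the nested `segments` tiling. The marker table is
#'   attached as attribute `markers`.
#' @export
segment_profiles <- function(profiles, layout = default_layout(),
                             config = seg_config()) {
  if (!"arm_index" %in% names(profiles)) {
    profiles <- as_profiles(profiles, layout)
  }
  profiles <- profiles[order(profiles$sample, profiles$marker), , drop = FALSE]
  markers <- profiles[!duplicated(profiles$marker), ]
  markers <- markers[order(markers$marker),
                     c("chrom", "pos", "arm", "arm_id", "arm_index", "marker")]
  arm_tbl <- markers[!duplicated(markers$arm_index),
                     c("chrom", "arm", "arm_id", "arm_index")]
  arm_rows <- split(markers$marker, markers$arm_index)
  meta <- profiles[!duplicated(profiles$sample),
                   intersect(c("sample", "patient", "lesion"), names(profiles))]
  sigma_tbl <- if (is.null(config$sigma)) estimate_noise(profiles) else
    tibble::tibble(sample = meta$sample, sigma = config$sigma)
  vals_by_sample <- split(profiles$logratio, profiles$sample)
  out <- purrr::map(meta$sample, function(s) {
    v <- vals_by_sample[[s]]
    sigma <- sigma_tbl$sigma[match(s, sigma_tbl$sample)]
    per_arm <- purrr::map(seq_len(nrow(arm_tbl)), function(k) {
      idx <- arm_rows[[as.character(arm_tbl$arm_index[k])]]
      values <- v[idx]
      cand <- segment_arm(values, sigma, config)
      rec <- classify_arm(values, cand, sigma, config)
      rec$m <- length(values)
      rec$n_obs <- sum(!is.na(values))
      rec$first_marker <- idx[1]
      rec
    })
    res <- dplyr::bind_rows(per_arm)
    res <- dplyr::bind_cols(arm_tbl[, c("chrom", "arm", "arm_id", "arm_index")], res)
    res$sample <- s
    res$sigma <- sigma
    res
  })
  out <- dplyr::bind_rows(out)
  out <- dplyr::left_join(out, meta, by = "sample")
  out$fp_start_marker <- out$first_marker + out$fp_lo - 1L
  out$fp_end_marker <- out$first_marker + out$fp_hi - 1L
  out$fp_start_bp <- markers$pos[out$fp_start_marker]
  out$fp_end_bp <- markers$pos[out$fp_end_marker]
  out$span_bp <- out$fp_end_bp - out$fp_start_bp
  front <- intersect(c("sample", "patient", "lesion", "chrom", "arm", "arm_id",
                       "arm_index", "m", "n_obs", "sigma", "i", "j", "n_bkpt",
                       "t_stat", "z_whole", "call", "magnitude", "fp_lo",
                       "fp_hi", "fp_start_marker", "fp_end_marker",
                       "fp_start_bp", "fp_end_bp", "span_bp", "whole_arm",
                       "first_marker", "segments"), names(out))
  out <- out[, front]
  attr(out, "markers") <- markers
  class(out) <- c("cn_segmentation", class(out))
  out <- filter_cnv_segment(out, config$regions, config, markers)
  attr(out, "markers") <- markers
  class(out) <- unique(c("cn_segmentation", class(out)))
  out
}
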