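#' Build the empirical reference distribution from cross-patient pairs
#'
#' Computes the clonality logLR for (a sample of) all unordered pairs of
#' tumors from *different* patients. Such pairs are non-clonal by
#' construction, so their logLR values form the reference (null)
#' distribution against which real within-patient pairs are benchmarked.
#'
#' @param segmentation Cohort segmentation tibble with a `patient` column
#'   (at least 2 patients).
#' @param marginals Arm marginals ([estimate_marginals()]); estimated from
#'   `segmentation` when `NULL`.
#' @param config A [clonality_config()].
#' @param max_pairs Cap on the number of reference pairs; when the number of
#'   cross-patient pairs exceeds it, a simple random subsample is scored.
#' @param seed Optional seed for the subsample draw.
#' @return A tibble of class `cn_null` with columns `sample1`, `sample2`,
#'   `loglr`, one row per scored cross-patient pair.
#' @export
build_reference <- function(segmentation, marginals = NULL,
                            config = clonality_config(),
                            max_pairs = Inf, seed = NULL) {
  meta <- segmentation[!duplicated(segmentation$sample), c("sample", "patient")]
  if (length(unique(meta$patient)) < 2) {
    stop("build_reference needs tumors from at least 2 patients", call. = FALSE)
  }
  if (is.null(marginals)) marginals <- estimate_marginals(segmentation, config)
  pairs <- utils::combn(meta$sample, 2)
  pat <- meta$patient[match(pairs, meta$sample)]
  dim(pat) <- dim(pairs)
  cross <- pat[1, ] != pat[2, ]
  pairs <- pairs[, cross, drop = FALSE]
  if (ncol(pairs) > max_pairs) {
    if (!is.null(seed)) set.seed(seed)
    pairs <- pairs[, sample.int(ncol(pairs), max_pairs), drop = FALSE]
  }
  if (ncol(pairs) < 50) {
    warning("reference distribution built from only ", ncol(pairs),
            " cross-patient pairs; classifications may be unstable",
            call. = FALSE)
  }
  by_sample <- split(
    seq_len(nrow(segmentation)), segmentation$sample)
  res <- purrr::map(seq_len(ncol(pairs)), function(k) {
    s1 <- segmentation[by_sample[[pairs[1, k]]], ]
    s2 <- segmentation[by_sample[[pairs[2, k]]], ]
    pr <- pair_loglr(s1, s2, marginals, config)
    pr[, c("sample1", "sample2", "loglr")]
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("cn_null", class(out))
  out
}

#' Empirical p-value against the reference distribution
#'
#' Add-one rank estimator: `p = (1 + #(null >= obs)) / (1 + n null pairs)`,
#' so p is never exactly zero and the smallest attainable value is
#' `1 / (n + 1)`.
#'
#' @param obs Observed logLR value(s).
#' @param null A `cn_null` tibble (or a numeric vector of null logLRs).
#' @return p-value(s) in `(0, 1]`, same length as `obs`.
#' @export
p_value <- function(obs, null) {
  vals <- if (is.data.frame(null)) null$loglr else null
  if (length(vals) == 0) stop("empty reference distribution", call. = FALSE)
  vapply(obs, function(o) (1 + sum(vals >= o)) / (1 + length(vals)), numeric(1))
}

#' Three-way clonality classification
#'
#' A pair is `clonal` when its logLR lies outside (strictly above) the whole
#' reference distribution; `equivocal` when it is within the reference range
#' but more extreme than the `alpha` quantile (p < alpha); `independent`
#' otherwise.
#'
#' @inheritParams p_value
#' @param p p-value(s) from [p_value()] (recomputed if missing).
#' @param alpha Significance level (default 0.05).
#' @return Character vector: `"clonal"`, `"equivocal"` or `"independent"`.
#' @export
classify_pair <- function(obs, null, p = p_value(obs, null), alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  vals <- if (is.data.frame(null)) null$loglr else null
  ifelse(obs > max(vals), "clonal",
         ifelse(p < alpha, "equivocal", "independent"))
}

#' Cohort gain/loss frequencies per marker and per arm
#'
#' Summarizes a cohort segmentation into marker-level gain/loss proportions
#' (a marker carries its arm's call if it lies in the calling footprint,
#' else NORMAL) and per-arm whole-arm gain/loss percentages, optionally
#' stratified by a grouping column such as `lesion`.
#'
#' @param segmentation Cohort segmentation tibble.
#' @param group Optional name of a segmentation column to stratify by
#'   (e.g. `"lesion"`); `NULL` pools all samples.
#' @param markers Marker tibble; defaults to the segmentation's attribute.
#' @return List of class `cohort_frequencies` with elements `markers`
#'   (`group`, `marker`, `chrom`, `pos`, `gain`, `loss` proportions) and
#'   `arms` (`group`, `arm_id`, `n`, `gain_pct`, `loss_pct` whole-arm
#'   percentages).
#' @export
cohort_frequencies <- function(segmentation, group = NULL,
                               markers = attr(segmentation, "markers")) {
  if (is.null(markers)) stop("cohort_frequencies needs the marker table", call. = FALSE)
  markers <- markers[order(markers$marker), ]
  seg <- segmentation
  seg$group <- if (is.null(group)) "all" else as.character(seg[[group]])
  if (any(is.na(seg$group))) stop("grouping column has missing values", call. = FALSE)
  mk_res <- list()
  arm_res <- list()
  for (g in unique(seg$group)) {
    sub <- seg[seg$group == g, ]
    n <- length(unique(sub$sample))
    if (n == 0) stop("empty group: ", g, call. = FALSE)
    gain <- loss <- numeric(nrow(markers))
    called <- sub[sub$call != "NORMAL", ]
    for (k in seq_len(nrow(called))) {
      idx <- called$fp_start_marker[k]:called$fp_end_marker[k]
      if (called$call[k] == "GAIN") gain[idx] <- gain[idx] + 1
      else loss[idx] <- loss[idx] + 1
    }
    mk_res[[g]] <- tibble::tibble(
      group = g, marker = markers$marker, chrom = markers$chrom,
      pos = markers$pos, gain = gain / n, loss = loss / n
    )
    arm_res[[g]] <- dplyr::summarise(
      dplyr::group_by(sub, .data$arm_id, .data$arm_index),
      group = g, n = n,
      gain_pct = 100 * sum(.data$call == "GAIN" & .data$whole_arm) / n,
      loss_pct = 100 * sum(.data$call == "LOSS" & .data$whole_arm) / n,
      .groups = "drop"
    )
  }
  out <- list(markers = dplyr::bind_rows(mk_res),
              arms = dplyr::arrange(dplyr::bind_rows(arm_res),
                                    .data$group, .data$arm_index))
  class(out) <- "cohort_frequencies"
  out
}
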