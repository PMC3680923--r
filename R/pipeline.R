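#' Full clonality analysis of a cohort of tumor profiles
#'
#' One call from preprocessed (centered) marker profiles to classified
#' tumor pairs: segments every sample arm by arm, estimates cohort marginal
#' call frequencies, computes the logLR clonality statistic for every
#' within-patient tumor pair, builds the empirical reference distribution
#' from cross-patient pairs, and attaches p-values and the three-way
#' clonal / equivocal / independent classification.
#'
#' @param profiles Profile tibble with `sample`, `patient`, `lesion`,
#'   `chrom`, `pos`, `logratio` (see [read_profile_table()]).
#' @param layout Chromosome-arm layout.
#' @param seg_cfg A [seg_config()].
#' @param clon_cfg A [clonality_config()].
#' @param alpha Classification significance level.
#' @param center Median-center the profiles first (default `TRUE`).
#' @param null_max_pairs Cap on the number of reference pairs (see
#'   [build_reference()]).
#' @param seed Seed for the reference-pair subsample.
#' @return An object of class `clonality_result`: a list with `pairs`
#'   (per-pair tibble incl. `loglr`, `xi`, `p`, `classification`), `null`
#'   (`cn_null`), `marginals`, `segmentation`, `alpha`. Use [tidy()] /
#'   [glance()] / [ggplot2::autoplot()] on it.
#' @export
clonality_analysis <- function(profiles, layout = default_layout(),
                               seg_cfg = seg_config(),
                               clon_cfg = clonality_config(),
                               alpha = 0.05, center = TRUE,
                               null_max_pairs = Inf, seed = NULL) {
  if (!"arm_index" %in% names(profiles)) {
    profiles <- as_profiles(profiles, layout)
  }
  if (center) profiles <- median_center(profiles)
  segmentation <- segment_profiles(profiles, layout, seg_cfg)
  marginals <- estimate_marginals(segmentation, clon_cfg)
  meta <- segmentation[!duplicated(segmentation$sample), c("sample", "patient")]
  by_sample <- split(seq_len(nrow(segmentation)), segmentation$sample)
  pair_ids <- within_patient_pairs(meta)
  pairs <- purrr::map(seq_len(nrow(pair_ids)), function(k) {
    s1 <- segmentation[by_sample[[pair_ids$sample1[k]]], ]
    s2 <- segmentation[by_sample[[pair_ids$sample2[k]]], ]
    marg <- if (clon_cfg$leave_pair_out) {
      estimate_marginals(segmentation, clon_cfg,
                         exclude_samples = c(pair_ids$sample1[k], pair_ids$sample2[k]))
    } else marginals
    pair_loglr(s1, s2, marg, clon_cfg)
  })
  pairs <- dplyr::bind_rows(pairs)
  null <- build_reference(segmentation, marginals, clon_cfg,
                          max_pairs = null_max_pairs, seed = seed)
  if (nrow(pairs) > 0) {
    pairs$p <- p_value(pairs$loglr, null)
    pairs$classification <- classify_pair(pairs$loglr, null, pairs$p, alpha)
  }
  structure(list(pairs = pairs, null = null, marginals = marginals,
                 segmentation = segmentation, alpha = alpha,
                 seg_cfg = seg_cfg, clon_cfg = clon_cfg),
            class = "clonality_result")
}

# All unordered same-patient sample pairs (patients with >= 2 samples).
within_patient_pairs <- function(meta) {
  meta <- meta[!is.na(meta$patient), ]
  out <- list()
  for (p in unique(meta$patient)) {
    s <- meta$sample[meta$patient == p]
    if (length(s) < 2) next
    cmb <- utils::combn(s, 2)
    out[[p]] <- tibble::tibble(sample1 = cmb[1, ], sample2 = cmb[2, ])
  }
  if (!length(out)) {
    return(tibble::tibble(sample1 = character(), sample2 = character()))
  }
  dplyr::bind_rows(out)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-pair results of a clonality analysis
#'
#' @param x A `clonality_result`.
#' @param ... Unused.
#' @return Flat tibble of within-patient pair results (per-arm detail
#'   dropped): sample ids, patient ids, `loglr`, `xi`, `n_concordant`, `p`,
#'   `classification`.
#' @method tidy clonality_result
#' @export
tidy.clonality_result <- function(x, ...) {
  x$pairs[, setdiff(names(x$pairs), "arms")]
}

#' One-row summary of a clonality analysis
#'
#' @param x A `clonality_result`.
#' @param ... Unused.
#' @return One-row tibble: cohort sizes, reference-pair count, counts of
#'   each classification, `alpha`.
#' @method glance clonality_result
#' @export
glance.clonality_result <- function(x, ...) {
  tibble::tibble(
    n_samples = length(unique(x$segmentation$sample)),
    n_patients = length(unique(x$segmentation$patient)),
    n_pairs = nrow(x$pairs),
    n_null = nrow(x$null),
    n_clonal = sum(x$pairs$classification == "clonal"),
    n_equivocal = sum(x$pairs$classification == "equivocal"),
    n_independent = sum(x$pairs$classification == "independent"),
    alpha = x$alpha
  )
}

#' @export
print.clonality_result <- function(x, ...) {
  g <- glance(x)
  cat("Clonality analysis: ", g$n_samples, " samples / ", g$n_patients,
      " patients; ", g$n_pairs, " within-patient pairs, ",
      g$n_null, " reference pairs\n", sep = "")
  cat("  clonal: ", g$n_clonal, "  equivocal: ", g$n_equivocal,
      "  independent: ", g$n_independent, " (alpha = ", x$alpha, ")\n",
      sep = "")
  invisible(x)
}

#' Histogram of the clonality measure against its reference distribution
#'
#' Reference (cross-patient) logLR values as a filled histogram with the
#' observed within-patient pairs overlaid as colored marks, the standard
#' display for this analysis: clonal pairs sit to the right of the entire
#' reference histogram.
#'
#' @param object A `clonality_result`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot clonality_result
#' @export
autoplot.clonality_result <- function(object, bins = 40, ...) {
  null_df <- tibble::tibble(loglr = object$null$loglr)
  obs <- tidy(object)
  p <- ggplot2::ggplot(null_df, ggplot2::aes(x = .data$loglr)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey25", colour = "grey40") +
    ggplot2::labs(x = "log-likelihood ratio (logLR)", y = "reference pairs",
                  title = "Clonality measure vs cross-patient reference") +
    ggplot2::theme_minimal()
  if (nrow(obs) > 0) {
    p <- p + ggplot2::geom_rug(
      data = obs,
      ggplot2::aes(x = .data$loglr, colour = .data$classification),
      linewidth = 1, sides = "b", inherit.aes = FALSE
    ) +
      ggplot2::scale_colour_manual(values = c(
        clonal = "#c0392b", equivocal = "#e67e22", independent = "#2980b9"))
  }
  p
}

#' @rdname autoplot.clonality_result
#' @export
plot_loglr_histogram <- function(object, bins = 40, ...) {
  autoplot.clonality_result(object, bins = bins, ...)
}

#' Genome-wide gain/loss frequency plot
#'
#' Per-marker proportions of samples with a copy-number gain (plotted
#' upward) or loss (downward) along the genome, one panel per group.
#'
#' @param object A `cohort_frequencies` object ([cohort_frequencies()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cohort_frequencies
#' @export
autoplot.cohort_frequencies <- function(object, ...) {
  mk <- object$markers
  ggplot2::ggplot(mk, ggplot2::aes(x = .data$marker)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$gain), fill = "#2980b9", width = 1) +
    ggplot2::geom_col(ggplot2::aes(y = -.data$loss), fill = "#c0392b", width = 1) +
    ggplot2::facet_wrap(~group, ncol = 1) +
    ggplot2::labs(x = "marker (genome order)",
                  y = "proportion with gain (up) / loss (down)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cohort_frequencies
#' @export
plot_frequency_profile <- function(object, ...) {
  autoplot.cohort_frequencies(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
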