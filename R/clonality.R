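#' Clonality-test configuration
#'
#' @param grid_step Step of the grid over the shared-event fraction `xi`
#'   (profile-maximized on `{0, grid_step, ..., 1}`; ties take the smallest
#'   `xi`). Default 0.01.
#' @param pseudo Smoothing pseudo-count added to every call category when
#'   estimating per-arm marginal frequencies, keeping them strictly
#'   positive. Default 1.
#' @param leave_pair_out Re-estimate the marginals without the two samples
#'   under comparison for each pair (default `FALSE`: the full cohort,
#'   including the pair, is used).
#' @return A list of class `clonality_config`.
#' @export
clonality_config <- function(grid_step = 0.01, pseudo = 1,
                             leave_pair_out = FALSE) {
  stopifnot(grid_step > 0, grid_step <= 0.5, pseudo > 0)
  structure(list(grid_step = grid_step, pseudo = pseudo,
                 leave_pair_out = leave_pair_out),
            class = "clonality_config")
}

#' Estimate per-arm marginal call frequencies in a cohort
#'
#' Smoothed cohort frequencies of GAIN / LOSS / NORMAL per chromosome arm:
#' `pi_a(c) = (count of call c on arm a + pseudo) / (n samples + 3 * pseudo)`.
#' These marginals discount concordant events that are common in the cohort
#' (a shared 1q gain is weak evidence of clonality precisely because most
#' tumors carry one) relative to rare shared events.
#'
#' @param segmentation Segmentation tibble ([segment_profiles()]) for the
#'   whole cohort (at least 2 samples).
#' @param config A [clonality_config()] (only `pseudo` is used).
#' @param exclude_samples Optional sample ids to drop before counting (used
#'   by the leave-pair-out variant).
#' @return Tibble with columns `arm_id`, `arm_index`, `n`, `pi_gain`,
#'   `pi_loss`, `pi_normal` (each row sums to 1).
#' @export
estimate_marginals <- function(segmentation, config = clonality_config(),
                               exclude_samples = NULL) {
  seg <- segmentation[!segmentation$sample %in% exclude_samples, , drop = FALSE]
  n <- length(unique(seg$sample))
  if (n < 2) stop("estimate_marginals needs at least 2 samples", call. = FALSE)
  ps <- config$pseudo
  out <- dplyr::summarise(
    dplyr::group_by(seg, .data$arm_id, .data$arm_index),
    n = dplyr::n(),
    pi_gain = (sum(.data$call == "GAIN") + ps) / (dplyr::n() + 3 * ps),
    pi_loss = (sum(.data$call == "LOSS") + ps) / (dplyr::n() + 3 * ps),
    pi_normal = (sum(.data$call == "NORMAL") + ps) / (dplyr::n() + 3 * ps),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$arm_index)
}

#' Footprint overlap of two concordant arm calls
#'
#' Jaccard index of the two calling-segment footprints over marker indices:
#' `|A intersect B| / |A union B|`. Defined only for arms where both samples
#' carry the same non-NORMAL call; identical footprints give 1, disjoint
#' footprints 0.
#'
#' @param armseg1,armseg2 One-row slices of a segmentation tibble for the
#'   same arm in two samples.
#' @return The overlap `s` in `[0, 1]`.
#' @export
segment_overlap <- function(armseg1, armseg2) {
  if (armseg1$call[1] == "NORMAL" || armseg1$call[1] != armseg2$call[1]) {
    stop("segment_overlap requires the same non-NORMAL call on both arms",
         call. = FALSE)
  }
  jaccard_range(armseg1$fp_start_marker[1], armseg1$fp_end_marker[1],
                armseg2$fp_start_marker[1], armseg2$fp_end_marker[1])
}

jaccard_range <- function(lo1, hi1, lo2, hi2) {
  inter <- pmax(0, pmin(hi1, hi2) - pmax(lo1, lo2) + 1)
  union <- (hi1 - lo1 + 1) + (hi2 - lo2 + 1) - inter
  inter / union
}

#' Log-likelihood ratio of clonality for one tumor pair
#'
#' Contrasts a clonal model, in which each arm's change is shared
#' (originating in a common ancestor clone) with probability `xi`, against
#' independent occurrence. Per arm the shared-model probability mass is
#' `m_a = pi_a(c) * s_a` for a concordant GAIN/LOSS call `c` with footprint
#' overlap `s_a`, `m_a = pi_a(NORMAL)` for a concordant-NORMAL arm, and 0
#' for discordant arms; the independent-model mass is
#' `p_a = pi_a(c1) * pi_a(c2)`. The statistic is
#' `logLR = max over xi of sum_a log((xi * m_a + (1 - xi) * p_a) / p_a)`,
#' profile-maximized over the `xi` grid, hence always >= 0 (the grid
#' contains 0). Exactly symmetric in the two samples.
#'
#' @param seg1,seg2 Segmentation rows of the two samples (same arm set).
#' @param marginals Arm marginals ([estimate_marginals()]).
#' @param config A [clonality_config()].
#' @return One-row tibble: `sample1`, `sample2`, `patient1`, `patient2`,
#'   `loglr`, `xi`, `n_concordant` (non-NORMAL concordant arms), nested
#'   `arms` detail (`arm_id`, `call1`, `call2`, `s`, `m_a`, `p_a`,
#'   `contrib` at the fitted `xi`), and unset `p` / `classification`.
#' @export
pair_loglr <- function(seg1, seg2, marginals, config = clonality_config()) {
  seg1 <- dplyr::arrange(seg1, .data$arm_index)
  seg2 <- dplyr::arrange(seg2, .data$arm_index)
  if (!identical(seg1$arm_index, seg2$arm_index)) {
    stop("pair_loglr: the two samples have different arm sets", call. = FALSE)
  }
  marg <- marginals[match(seg1$arm_index, marginals$arm_index), ]
  if (anyNA(marg$arm_index)) {
    stop("pair_loglr: marginals missing for some arms", call. = FALSE)
  }
  pick <- function(call, m) {
    ifelse(call == "GAIN", m$pi_gain,
           ifelse(call == "LOSS", m$pi_loss, m$pi_normal))
  }
  c1 <- seg1$call
  c2 <- seg2$call
  p_a <- pick(c1, marg) * pick(c2, marg)
  conc <- c1 == c2 & c1 != "NORMAL"
  s <- rep(NA_real_, nrow(seg1))
  s[conc] <- jaccard_range(seg1$fp_start_marker[conc], seg1$fp_end_marker[conc],
                           seg2$fp_start_marker[conc], seg2$fp_end_marker[conc])
  m_a <- numeric(nrow(seg1))
  m_a[conc] <- pick(c1[conc], marg[conc, ]) * s[conc]
  both_norm <- c1 == "NORMAL" & c2 == "NORMAL"
  m_a[both_norm] <- marg$pi_normal[both_norm]
  r <- m_a / p_a
  xi_grid <- seq(0, 1, by = config$grid_step)
  if (xi_grid[length(xi_grid)] < 1) xi_grid <- c(xi_grid, 1)
  # loglr(xi) = sum_a log(1 + xi * (r_a - 1)); -Inf allowed when some r_a = 0
  ll <- vapply(xi_grid, function(xi) sum(log1p(xi * (r - 1))), numeric(1))
  best <- which.max(ll)  # first maximum = smallest xi on ties
  xi_hat <- xi_grid[best]
  contrib <- log1p(xi_hat * (r - 1))
  tibble::tibble(
    sample1 = seg1$sample[1], sample2 = seg2$sample[1],
    patient1 = if ("patient" %in% names(seg1)) seg1$patient[1] else NA_character_,
    patient2 = if ("patient" %in% names(seg2)) seg2$patient[1] else NA_character_,
    loglr = ll[best], xi = xi_hat, n_concordant = sum(conc),
    arms = list(tibble::tibble(
      arm_id = seg1$arm_id, call1 = c1, call2 = c2, s = s,
      m_a = m_a, p_a = p_a, contrib = contrib
    )),
    p = NA_real_, classification = NA_character_
  )
}
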