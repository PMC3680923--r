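#' Synthetic-cohort generator configuration
#'
#' Parameters of the paired copy-number profile simulator. Defaults emulate
#' the study conditions the pipeline is meant for: ~15,000 genome-wide
#' markers over 39 autosomal arms, an elevated 1q-gain rate of 0.73 and
#' 16q-loss rate of 0.53 (the hallmark events of low-grade breast lesions),
#' a 0.10 event rate split evenly between gain and loss elsewhere, a 50/50
#' mix of whole-arm and interior events, event shifts of +/-0.45 log2 units,
#' marker noise SD 0.25, and a shared-event fraction of 0.8 for clonal
#' pairs.
#'
#' @param layout Arm layout; markers are allocated to arms proportional to
#'   arm length (largest-remainder rounding, every arm >= 10 markers).
#' @param n_markers Total markers per genome (default 15000).
#' @param event_prob Tibble `arm_id`, `p_gain`, `p_loss`; `NULL` builds the
#'   default rates described above.
#' @param whole_arm_frac Probability that an event spans the whole arm
#'   (otherwise an interior segment).
#' @param interior_frac Range of the interior-segment length as a fraction
#'   of the arm (drawn uniformly).
#' @param delta Absolute event shift in log2 units (gain `+delta`, loss
#'   `-delta`).
#' @param phi Normal-cell contamination attenuation in (0, 1]: multiplies
#'   all event shifts (1 = pure tumor; lower values obscure signal).
#' @param sigma Additive per-marker noise SD.
#' @param xi Shared-event fraction for clonal pairs: each arm's event is
#'   ancestral (identical footprint in both tumors) with probability
#'   `xi * rate`, private with probability `(1 - xi) * rate`.
#' @return A list of class `sim_config`. The random generator is R's
#'   default Mersenne-Twister, recorded in the `rng` field so fixtures are
#'   reproducible across platforms.
#' @export
sim_config <- function(layout = default_layout(), n_markers = 15000,
                       event_prob = NULL, whole_arm_frac = 0.5,
                       interior_frac = c(0.1, 0.8), delta = 0.45,
                       phi = 1, sigma = 0.25, xi = 0.8) {
  stopifnot(delta > 0, sigma > 0, phi > 0, phi <= 1, xi >= 0, xi <= 1,
            whole_arm_frac >= 0, whole_arm_frac <= 1)
  if (is.null(event_prob)) {
    event_prob <- tibble::tibble(
      arm_id = layout$arm_id, p_gain = 0.05, p_loss = 0.05)
    event_prob$p_gain[event_prob$arm_id == "1q"] <- 0.73
    event_prob$p_loss[event_prob$arm_id == "1q"] <- 0
    event_prob$p_gain[event_prob$arm_id == "16q"] <- 0
    event_prob$p_loss[event_prob$arm_id == "16q"] <- 0.53
  }
  if (any(event_prob$p_gain < 0 | event_prob$p_loss < 0 |
          event_prob$p_gain + event_prob$p_loss > 1)) {
    stop("invalid per-arm event probabilities", call. = FALSE)
  }
  markers <- sim_markers(layout, n_markers)
  structure(list(layout = layout, n_markers = n_markers,
                 event_prob = event_prob, whole_arm_frac = whole_arm_frac,
                 interior_frac = interior_frac, delta = delta, phi = phi,
                 sigma = sigma, xi = xi, markers = markers,
                 rng = "Mersenne-Twister"),
            class = "sim_config")
}

# Evenly spaced marker map with per-arm counts proportional to arm length.
sim_markers <- function(layout, n_markers) {
  len <- layout$end - layout$start + 1
  raw <- n_markers * len / sum(len)
  n_a <- pmax(10L, floor(raw))
  rem <- n_markers - sum(n_a)
  if (rem > 0) {
    extra <- order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]
    n_a[extra] <- n_a[extra] + 1L
  }
  mk <- purrr::map(seq_len(nrow(layout)), function(k) {
    tibble::tibble(
      chrom = layout$chrom[k],
      pos = round(seq(layout$start[k], layout$end[k], length.out = n_a[k]))
    )
  })
  assign_arms(dplyr::bind_rows(mk), layout, quiet = TRUE)
}

# One sample's event draw on arms without an ancestral event.
draw_events <- function(config, rate_scale = 1, skip_arms = character()) {
  ep <- config$event_prob
  mk <- config$markers
  out <- list()
  if (rate_scale <= 0) return(dplyr::bind_rows(out))
  for (k in seq_len(nrow(ep))) {
    a <- ep$arm_id[k]
    if (a %in% skip_arms) next
    rate <- (ep$p_gain[k] + ep$p_loss[k]) * rate_scale
    if (stats::runif(1) >= rate) next
    call <- if (stats::runif(1) < ep$p_gain[k] / (ep$p_gain[k] + ep$p_loss[k]))
      "GAIN" else "LOSS"
    m <- sum(mk$arm_id == a)
    if (stats::runif(1) < config$whole_arm_frac) {
      fp <- c(1L, m)
    } else {
      frac <- stats::runif(1, config$interior_frac[1], config$interior_frac[2])
      w <- max(3L, round(frac * m))
      lo <- sample.int(m - w + 1L, 1)
      fp <- c(lo, lo + w - 1L)
    }
    out[[a]] <- tibble::tibble(arm_id = a, call = call,
                               fp_lo = fp[1], fp_hi = fp[2])
  }
  dplyr::bind_rows(out)
}

# Marker-level signal vector from an event table.
events_to_signal <- function(events, config) {
  mk <- config$markers
  sig <- numeric(nrow(mk))
  arm_first <- tapply(mk$marker, mk$arm_id, min)
  for (k in seq_len(NROW(events))) {
    off <- arm_first[[events$arm_id[k]]] - 1L
    idx <- (events$fp_lo[k]:events$fp_hi[k]) + off
    sig[idx] <- sig[idx] +
      config$phi * config$delta * if (events$call[k] == "GAIN") 1 else -1
  }
  sig
}

#' Simulate one tumor pair with known clonal structure
#'
#' For a clonal pair, ancestral events are drawn per arm with probability
#' `xi * rate` and copied with identical footprints into both tumors
#' (descendants of one transformed clone); each tumor then acquires private
#' events on the remaining arms with probability `(1 - xi) * rate`,
#' mimicking evolution after divergence. An independent pair is two fully
#' independent draws at the full per-arm rates. The signal is the sum of
#' event shifts (attenuated by `phi`) plus i.i.d. Gaussian marker noise.
#'
#' @param config A [sim_config()].
#' @param clonal Simulate a clonal (`TRUE`) or independent pair.
#' @param seed Optional RNG seed; a fixed seed gives bit-identical output.
#' @param sample_ids,patient_id,lesions Identifiers for the two profiles.
#' @return List with `profiles` (long profile tibble for both samples),
#'   `truth` (per-event tibble: `sample`, `arm_id`, `call`, `fp_lo`,
#'   `fp_hi`, `shared`) and `clonal`.
#' @export
simulate_pair <- function(config = sim_config(), clonal = TRUE, seed = NULL,
                          sample_ids = c("T1", "T2"), patient_id = "P1",
                          lesions = c("LCIS", "ILC")) {
  if (!is.null(seed)) set.seed(seed)
  if (clonal) {
    anc <- draw_events(config, rate_scale = config$xi)
    anc_arms <- if (NROW(anc)) anc$arm_id else character()
    ev <- purrr::map(1:2, function(i) {
      priv <- draw_events(config, rate_scale = 1 - config$xi,
                          skip_arms = anc_arms)
      dplyr::bind_rows(
        if (NROW(anc)) dplyr::mutate(anc, shared = TRUE),
        if (NROW(priv)) dplyr::mutate(priv, shared = FALSE)
      )
    })
  } else {
    ev <- purrr::map(1:2, function(i) {
      e <- draw_events(config)
      if (NROW(e)) dplyr::mutate(e, shared = FALSE) else e
    })
  }
  mk <- config$markers
  profiles <- purrr::map(1:2, function(i) {
    sig <- events_to_signal(ev[[i]], config) +
      stats::rnorm(nrow(mk), 0, config$sigma)
    tibble::tibble(sample = sample_ids[i], patient = patient_id,
                   lesion = lesions[i], chrom = mk$chrom, pos = mk$pos,
                   logratio = sig, arm = mk$arm, arm_id = mk$arm_id,
                   arm_index = mk$arm_index, marker = mk$marker)
  })
  truth <- dplyr::bind_rows(purrr::map(1:2, function(i) {
    e <- ev[[i]]
    if (!NROW(e)) return(tibble::tibble())
    dplyr::mutate(e, sample = sample_ids[i], .before = 1)
  }))
  list(profiles = dplyr::bind_rows(profiles), truth = truth, clonal = clonal)
}

#' Simulate a patient cohort of tumor pairs
#'
#' Each patient contributes one simulated tumor pair; the first
#' `round(fraction_clonal * n_patients)` patients are clonal, the rest
#' independent. The output is directly usable by [clonality_analysis()].
#'
#' @param config A [sim_config()].
#' @param n_patients Number of patients (>= 2).
#' @param fraction_clonal Fraction of patients whose pair is clonal.
#' @param seed Optional RNG seed.
#' @return List with `profiles` (all samples, patient-labeled), `truth`
#'   (per-sample events) and `pair_truth` (`patient`, `sample1`, `sample2`,
#'   `clonal`).
#' @export
simulate_cohort <- function(config = sim_config(), n_patients = 20,
                            fraction_clonal = 0.5, seed = NULL) {
  stopifnot(n_patients >= 2)
  if (!is.null(seed)) set.seed(seed)
  n_clonal <- round(fraction_clonal * n_patients)
  out <- purrr::map(seq_len(n_patients), function(i) {
    pid <- sprintf("P%03d", i)
    simulate_pair(config, clonal = i <= n_clonal, seed = NULL,
                  sample_ids = paste0(pid, c("_a", "_b")), patient_id = pid)
  })
  pids <- sprintf("P%03d", seq_len(n_patients))
  pair_truth <- tibble::tibble(
    patient = pids,
    sample1 = paste0(pids, "_a"),
    sample2 = paste0(pids, "_b"),
    clonal = seq_len(n_patients) <= n_clonal
  )
  list(profiles = dplyr::bind_rows(purrr::map(out, "profiles")),
       truth = dplyr::bind_rows(purrr::map(out, "truth")),
       pair_truth = pair_truth)
}

#' Score pipeline classifications against simulation truth
#'
#' Joins classified pairs to the generator's truth labels and reports
#' sensitivity (truly clonal pairs detected as clonal *or* equivocal),
#' the false-clonal rate and specificity on truly independent pairs, and
#' the full truth-by-classification confusion table.
#'
#' @param pairs Classified pair tibble (`sample1`, `sample2`,
#'   `classification`), e.g. `tidy()` of a [clonality_analysis()] result.
#' @param pair_truth Truth tibble from [simulate_cohort()].
#' @return List with `metrics` (one-row tibble: `sensitivity`,
#'   `false_clonal_rate`, `specificity`, `n_clonal_truth`,
#'   `n_independent_truth`) and `confusion` (counts tibble).
#' @export
evaluate_recovery <- function(pairs, pair_truth) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  pairs <- dplyr::mutate(pairs, .key = key(.data$sample1, .data$sample2))
  pair_truth <- dplyr::mutate(pair_truth, .key = key(.data$sample1, .data$sample2))
  joined <- dplyr::inner_join(
    pairs[, c(".key", "classification")],
    pair_truth[, c(".key", "clonal")], by = ".key")
  if (nrow(joined) != nrow(pair_truth) || nrow(joined) != nrow(pairs)) {
    stop("pair ids do not match between classifications and truth", call. = FALSE)
  }
  pos <- joined[joined$clonal, ]
  neg <- joined[!joined$clonal, ]
  metrics <- tibble::tibble(
    sensitivity = if (nrow(pos)) mean(pos$classification %in% c("clonal", "equivocal")) else NA_real_,
    false_clonal_rate = if (nrow(neg)) mean(neg$classification == "clonal") else NA_real_,
    specificity = if (nrow(neg)) 1 - mean(neg$classification == "clonal") else NA_real_,
    n_clonal_truth = nrow(pos),
    n_independent_truth = nrow(neg)
  )
  confusion <- dplyr::count(joined,
                            truth = ifelse(.data$clonal, "clonal", "independent"),
                            .data$classification)
  list(metrics = metrics, confusion = confusion)
}
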