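# Shared fixtures and independent oracles for the test suite.

# Two-chromosome toy layout with a centromeric gap on chr1 (901..1000).
tiny_layout <- function() {
  clonalcn:::validate_layout(tibble::tibble(
    chrom = c("1", "1", "2", "2"),
    arm = c("p", "q", "p", "q"),
    arm_id = c("1p", "1q", "2p", "2q"),
    start = c(1, 1001, 1, 1501),
    end = c(900, 2000, 1500, 3000)
  ))
}

# Profile tibble on tiny_layout: one marker every 10 bp inside each arm.
tiny_profiles <- function(values_by_sample, layout = tiny_layout(),
                          spacing = 10, patient = NULL) {
  pos <- unlist(lapply(seq_len(nrow(layout)), function(k) {
    seq(layout$start[k], layout$end[k], by = spacing)
  }))
  chrom <- rep(layout$chrom, times = vapply(seq_len(nrow(layout)), function(k) {
    length(seq(layout$start[k], layout$end[k], by = spacing))
  }, integer(1)))
  n <- length(pos)
  dplyr::bind_rows(lapply(names(values_by_sample), function(s) {
    v <- values_by_sample[[s]]
    stopifnot(length(v) == n)
    tibble::tibble(
      sample = s,
      patient = if (is.null(patient)) s else patient[[s]],
      lesion = "LCIS", chrom = chrom, pos = pos, logratio = v
    )
  }))
}

n_tiny_markers <- function(layout = tiny_layout(), spacing = 10) {
  sum(vapply(seq_len(nrow(layout)), function(k) {
    length(seq(layout$start[k], layout$end[k], by = spacing))
  }, integer(1)))
}

# Independent exhaustive single-change scan (plain R): enumerates every
# interval of >= min_markers markers plus the whole-arm z, mirroring the
# documented maximization and tie-break. Used as the oracle for the
# compiled scan.
oracle_scan <- function(x, sigma = 1, min_markers = 3) {
  n <- length(x)
  sigma <- max(sigma, 1e-6)
  best <- NULL
  consider <- function(i, j, t) {
    if (is.null(best) || abs(t) > abs(best$t) ||
        (abs(t) == abs(best$t) && (i < best$i || (i == best$i && j < best$j)))) {
      best <<- list(i = i, j = j, t = t)
    }
  }
  for (i in seq_len(n)) {
    for (j in seq(i + min_markers - 1, n)) {
      if (j > n) break
      # a suffix whose complementary prefix is itself a candidate is that
      # prefix's mirror image (equal |T|); the prefix wins the tie
      if (i > 1 && j == n && i - 1 >= min_markers) next
      if (i == 1 && j == n) {
        t <- mean(x) / (sigma / sqrt(n))
      } else {
        nin <- j - i + 1
        nout <- n - nin
        t <- (mean(x[i:j]) - mean(x[-(i:j)])) /
          (sigma * sqrt(1 / nin + 1 / nout))
      }
      consider(i, j, t)
    }
  }
  best
}

# Brute-force any-overlap of a point/span against a region table.
brute_overlap <- function(regions, chrom, start, end = start) {
  vapply(seq_along(chrom), function(k) {
    any(regions$chrom == chrom[k] & regions$start <= end[k] &
          regions$end >= start[k])
  }, logical(1))
}

# Hand-built one-row segmentation record for clonality tests.
fake_arm <- function(sample, arm_index, arm_id, call, fp = c(NA, NA),
                     patient = sample) {
  tibble::tibble(
    sample = sample, patient = patient, arm_id = arm_id,
    arm_index = arm_index, call = call,
    fp_start_marker = fp[1], fp_end_marker = fp[2]
  )
}

# Three one-arm chromosomes with planted gains for the CNV segment filter:
# 1q carries a ~0.96 Mb interior gain (markers 26..50 at 40 kb spacing),
# 2q a ~3.12 Mb interior gain (markers 11..50 at 80 kb spacing), 3q is
# quiet. Both footprints overlap a 1.5-1.7 Mb CNV region on their own
# chromosome.
cnv_filter_fixture <- function(seed = 1) {
  lay <- clonalcn:::validate_layout(tibble::tibble(
    chrom = c("1", "2", "3"), arm = "q", arm_id = c("1q", "2q", "3q"),
    start = 1, end = 10e6))
  set.seed(seed)
  v <- rnorm(300, 0, 0.05)
  v[26:50] <- v[26:50] + 0.8
  v[100 + (11:50)] <- v[100 + (11:50)] + 0.8
  pr <- tibble::tibble(
    sample = "A", patient = "P", lesion = "x",
    chrom = rep(c("1", "2", "3"), each = 100),
    pos = c(seq(40000, by = 40000, length.out = 100),
            seq(80000, by = 80000, length.out = 100),
            seq(40000, by = 40000, length.out = 100)),
    logratio = v)
  list(layout = lay, profiles = pr,
       regions_overlapping = tibble::tibble(chrom = c("1", "2"),
                                            start = 1.5e6, end = 1.7e6),
       regions_elsewhere = tibble::tibble(chrom = "3",
                                          start = 1.5e6, end = 1.7e6))
}

# Small-genome simulator settings used where full 15,000-marker resolution
# is not the point of the test.
small_sim <- function(n_markers = 3000, ...) {
  sim_config(n_markers = n_markers, ...)
}
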