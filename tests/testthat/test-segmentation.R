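test_that("noise estimation is calibrated and robust to true jumps", {
  set.seed(42)
  cfg <- sim_config()  # full 15,000-marker map, no signal added below
  mk <- cfg$markers
  pr <- tibble::tibble(sample = "A", patient = "P", lesion = "x",
                       chrom = mk$chrom, pos = mk$pos,
                       logratio = rnorm(nrow(mk), 0, 0.25),
                       arm = mk$arm, arm_id = mk$arm_id,
                       arm_index = mk$arm_index, marker = mk$marker)
  est <- estimate_noise(pr)
  expect_gt(est$sigma, 0.24)
  expect_lt(est$sigma, 0.26)

  # constant profile: zero noise
  pr0 <- pr; pr0$logratio <- 0.3
  expect_equal(estimate_noise(pr0)$sigma, 0)

  # one genuine step inside one arm leaves the pooled median untouched
  pr1 <- pr0
  one_arm <- which(pr1$arm_id == "5q")
  pr1$logratio[one_arm[seq(length(one_arm) %/% 2)]] <- 1.3
  expect_equal(estimate_noise(pr1)$sigma, 0)

  expect_error(clonalcn:::noise_one(c(1, 2, 3), c(1, 1, 1)), "at least 10")
})

test_that("segment_arm finds the planted segment and matches the exhaustive oracle", {
  x <- c(0, 0, 0, 0.8, 0.8, 0.8, 0.8, 0, 0, 0)
  cand <- segment_arm(x, sigma = 0.1)
  expect_equal(c(cand$i, cand$j), c(4, 7))
  orc <- oracle_scan(x, sigma = 0.1)
  expect_equal(cand$t_stat, orc$t)

  # all zeros: |T| = 0, first valid interval by the tie rule
  z <- segment_arm(rep(0, 10), sigma = 0.1)
  expect_equal(z$t_stat, 0)
  expect_equal(c(z$i, z$j), c(1, 3))

  # random arms vs exhaustive enumeration
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(7:80, 1)
    x <- rnorm(n, 0, 0.3)
    if (rep %% 3 == 0) {
      lo <- sample.int(n - 3, 1); hi <- min(n, lo + sample.int(10, 1))
      x[lo:hi] <- x[lo:hi] + 0.6
    }
    got <- segment_arm(x, sigma = 0.3)
    orc <- oracle_scan(x, sigma = 0.3)
    expect_equal(c(got$i, got$j, got$t_stat), c(orc$i, orc$j, orc$t))
  }
})

test_that("segment_arm skips missing values and floors sigma at zero noise", {
  x <- c(0, NA, 0, 0.9, NA, 0.9, 0.9, 0, NA, 0)
  cand <- segment_arm(x, sigma = 0.1)
  expect_equal(c(cand$i, cand$j), c(4, 7))  # indices on the full arm
  # sigma = 0 must not divide by zero
  cand0 <- segment_arm(c(0, 0, 0, 1, 1, 1, 0, 0), sigma = 0)
  expect_true(is.finite(cand0$t_stat))
  expect_equal(c(cand0$i, cand0$j), c(4, 6))
})

test_that("arm classification follows the central / outstanding segment rule", {
  cfg <- seg_config(sigma = 0.1)
  # two breakpoints: central segment calls the arm
  x <- c(rep(0, 10), rep(0.8, 8), rep(0, 10))
  rec <- classify_arm(x, segment_arm(x, 0.1, cfg), 0.1, cfg)
  expect_equal(rec$call, "GAIN")
  expect_equal(c(rec$fp_lo, rec$fp_hi), c(11, 18))
  expect_equal(rec$magnitude, 0.8)
  expect_equal(nrow(rec$segments[[1]]), 3)

  # magnitude gate: significant statistic but tiny shift stays NORMAL
  x2 <- c(rep(0, 200), rep(0.05, 200))
  cand2 <- segment_arm(x2, 0.01, cfg)
  expect_gt(abs(cand2$t_stat), cfg$tau)
  rec2 <- classify_arm(x2, cand2, 0.01, cfg)
  expect_equal(rec2$call, "NORMAL")
  expect_equal(rec2$magnitude, 0)
  expect_true(is.na(rec2$fp_lo))

  # one breakpoint: the more outstanding side carries the call
  x3 <- c(rep(-0.5, 12), rep(0.02, 20))
  rec3 <- classify_arm(x3, segment_arm(x3, 0.05, cfg), 0.05, cfg)
  expect_equal(rec3$call, "LOSS")
  expect_equal(c(rec3$fp_lo, rec3$fp_hi), c(1, 12))
  expect_equal(rec3$magnitude, -0.5)

  # whole-arm shift: zero breakpoints, footprint is the full arm
  x4 <- rep(0.4, 30) + rnorm(30, 0, 0.01)
  rec4 <- classify_arm(x4, segment_arm(x4, 0.05, cfg), 0.05, cfg)
  expect_equal(rec4$call, "GAIN")
  expect_true(rec4$whole_arm)
})

test_that("short CNV-overlapping calling segments are reset to NORMAL", {
  fx <- cnv_filter_fixture()
  # short + overlap: excluded (reset to NORMAL)
  seg_a <- segment_profiles(fx$profiles, fx$layout,
                            seg_config(sigma = 0.05,
                                       regions = fx$regions_overlapping))
  expect_equal(seg_a$call[seg_a$arm_id == "1q"], "NORMAL")
  expect_true(is.na(seg_a$fp_lo[seg_a$arm_id == "1q"]))
  # long + overlap: retained
  expect_equal(seg_a$call[seg_a$arm_id == "2q"], "GAIN")
  # short, no overlap: retained
  seg_b <- segment_profiles(fx$profiles, fx$layout,
                            seg_config(sigma = 0.05,
                                       regions = fx$regions_elsewhere))
  expect_equal(seg_b$call[seg_b$arm_id == "1q"], "GAIN")
  expect_lt(seg_b$span_bp[seg_b$arm_id == "1q"], 2.3e6)
})

test_that("profile segmentation is order-invariant and exact without noise", {
  lay <- tiny_layout()
  n <- n_tiny_markers(lay)
  # noiseless interior gains: breakpoints recovered exactly
  pr <- as_profiles(tiny_profiles(list(A = rnorm(n, 0, 1e-9))), lay)
  gain <- which(pr$arm_id == "1q")[31:70]
  loss <- which(pr$arm_id == "2p")[1:50]
  pr$logratio[gain] <- pr$logratio[gain] + 0.45
  pr$logratio[loss] <- pr$logratio[loss] - 0.45
  seg <- segment_profiles(pr, lay)
  expect_equal(seg$call[seg$arm_id == "1q"], "GAIN")
  expect_equal(seg$fp_start_marker[seg$arm_id == "1q"], min(pr$marker[gain]))
  expect_equal(seg$fp_end_marker[seg$arm_id == "1q"], max(pr$marker[gain]))
  expect_equal(seg$call[seg$arm_id == "2p"], "LOSS")
  expect_equal(seg$fp_start_marker[seg$arm_id == "2p"], min(pr$marker[loss]))
  expect_equal(seg$fp_end_marker[seg$arm_id == "2p"], max(pr$marker[loss]))
  expect_equal(seg$call[seg$arm_id %in% c("1p", "2q")], c("NORMAL", "NORMAL"))

  # shuffling input rows does not change the result
  pr_shuf <- pr[sample.int(nrow(pr)), ]
  seg_shuf <- segment_profiles(as_profiles(pr_shuf[, 1:6], lay), lay)
  expect_equal(seg_shuf$call, seg$call)
  expect_equal(seg_shuf$t_stat, seg$t_stat)

  # all-zero profile: every arm NORMAL
  pr0 <- tiny_profiles(list(A = rnorm(n, 0, 0.05)))
  seg0 <- segment_profiles(pr0, lay, seg_config(sigma = 0.05))
  expect_true(all(seg0$call == "NORMAL"))
})

test_that("raising tau never creates calls, and the scan is scale-equivariant", {
  set.seed(19)
  for (rep in 1:20) {
    x <- rnorm(60, 0, 0.3)
    if (rep %% 2 == 0) x[20:35] <- x[20:35] + runif(1, 0.1, 0.6)
    lo_cfg <- seg_config(tau = 3, sigma = 0.3)
    hi_cfg <- seg_config(tau = 8, sigma = 0.3)
    rec_lo <- classify_arm(x, segment_arm(x, 0.3, lo_cfg), 0.3, lo_cfg)
    rec_hi <- classify_arm(x, segment_arm(x, 0.3, hi_cfg), 0.3, hi_cfg)
    if (rec_lo$call == "NORMAL") expect_equal(rec_hi$call, "NORMAL")

    # scale equivariance: (values, sigma) -> (c*values, c*sigma)
    cand <- segment_arm(x, 0.3)
    cand_sc <- segment_arm(3.7 * x, 3.7 * 0.3)
    expect_equal(c(cand$i, cand$j), c(cand_sc$i, cand_sc$j))
    expect_equal(cand$t_stat, cand_sc$t_stat, tolerance = 1e-12)
  }
})

test_that("pure noise rarely produces calls at the default threshold", {
  set.seed(4)
  cfg <- sim_config(event_prob = tibble::tibble(
    arm_id = default_layout()$arm_id, p_gain = 0, p_loss = 0))
  sim <- simulate_cohort(cfg, n_patients = 3, fraction_clonal = 0, seed = 4)
  seg <- segment_profiles(median_center(sim$profiles))
  expect_lt(mean(seg$call != "NORMAL"), 0.01)
})
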