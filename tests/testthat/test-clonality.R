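test_that("marginal call frequencies use add-pseudo smoothing and sum to one", {
  seg <- dplyr::bind_rows(lapply(1:10, function(i) {
    fake_arm(paste0("S", i), 1, "1q",
             call = if (i <= 7) "GAIN" else "NORMAL", fp = c(1, 100))
  }))
  marg <- estimate_marginals(seg)
  expect_equal(marg$pi_gain, (7 + 1) / 13)
  expect_equal(marg$pi_normal, (3 + 1) / 13)
  expect_equal(marg$pi_gain + marg$pi_loss + marg$pi_normal, 1)

  # an all-quiet cohort: NORMAL maximal and equal across arms
  seg2 <- dplyr::bind_rows(lapply(1:4, function(i) dplyr::bind_rows(
    fake_arm(paste0("S", i), 1, "1p", "NORMAL"),
    fake_arm(paste0("S", i), 2, "1q", "NORMAL"))))
  marg2 <- estimate_marginals(seg2)
  expect_equal(marg2$pi_normal, rep((4 + 1) / 7, 2))
  expect_true(all(marg2$pi_normal > marg2$pi_gain))

  # random cohorts still normalize per arm
  set.seed(2)
  seg3 <- dplyr::bind_rows(lapply(1:12, function(i) dplyr::bind_rows(lapply(1:5, function(a)
    fake_arm(paste0("S", i), a, paste0(a, "q"),
             sample(c("GAIN", "LOSS", "NORMAL"), 1), fp = c(1, 10))))))
  marg3 <- estimate_marginals(seg3, clonality_config(pseudo = 0.5))
  expect_equal(marg3$pi_gain + marg3$pi_loss + marg3$pi_normal, rep(1, 5))

  expect_error(estimate_marginals(seg[seg$sample == "S1", ]), "at least 2")
})

test_that("footprint overlap is the Jaccard index of marker ranges", {
  a <- fake_arm("A", 1, "1q", "GAIN", fp = c(1, 10))
  b <- fake_arm("B", 1, "1q", "GAIN", fp = c(6, 15))
  expect_equal(segment_overlap(a, b), 5 / 15)
  expect_equal(segment_overlap(a, a), 1)
  expect_equal(segment_overlap(a, fake_arm("B", 1, "1q", "GAIN", c(11, 20))), 0)
  expect_error(segment_overlap(a, fake_arm("B", 1, "1q", "LOSS", c(1, 10))),
               "same non-NORMAL call")
  expect_error(segment_overlap(fake_arm("A", 1, "1q", "NORMAL"),
                               fake_arm("B", 1, "1q", "NORMAL")),
               "same non-NORMAL call")
})

# Marginals for a toy two-arm genome used by several blocks below.
toy_marginals <- function() tibble::tibble(
  arm_id = c("Aq", "Bq"), arm_index = 1:2, n = 10,
  pi_gain = c(0.2, 0.1), pi_loss = c(0.1, 0.1), pi_normal = c(0.7, 0.8))

test_that("the two-arm worked example evaluates exactly", {
  s1 <- dplyr::bind_rows(fake_arm("T1", 1, "Aq", "GAIN", c(1, 50)),
                         fake_arm("T1", 2, "Bq", "NORMAL"))
  s2 <- dplyr::bind_rows(fake_arm("T2", 1, "Aq", "GAIN", c(1, 50)),
                         fake_arm("T2", 2, "Bq", "NORMAL"))
  res <- pair_loglr(s1, s2, toy_marginals())
  # arm A: pi 0.2, s = 1 -> log(0.2/0.04); arm B: log(0.8/0.64); xi-hat = 1
  expect_equal(res$loglr, log(6.25), tolerance = 1e-9)
  expect_equal(res$xi, 1)
  expect_equal(res$arms[[1]]$contrib, c(log(5), log(1.25)), tolerance = 1e-9)
})

test_that("logLR is symmetric, non-negative, and zero for all-discordant pairs", {
  set.seed(31)
  calls <- c("GAIN", "LOSS", "NORMAL")
  for (rep in 1:25) {
    mk1 <- sample(calls, 2, replace = TRUE)
    mk2 <- sample(calls, 2, replace = TRUE)
    fp <- function() { lo <- sample.int(40, 1); c(lo, lo + sample.int(40, 1)) }
    s1 <- dplyr::bind_rows(fake_arm("T1", 1, "Aq", mk1[1], fp()),
                           fake_arm("T1", 2, "Bq", mk1[2], fp()))
    s2 <- dplyr::bind_rows(fake_arm("T2", 1, "Aq", mk2[1], fp()),
                           fake_arm("T2", 2, "Bq", mk2[2], fp()))
    r12 <- pair_loglr(s1, s2, toy_marginals())
    r21 <- pair_loglr(s2, s1, toy_marginals())
    expect_identical(r12$loglr, r21$loglr)
    expect_identical(r12$xi, r21$xi)
    expect_gte(r12$loglr, 0)
  }
  # fully discordant: xi-hat = 0 and logLR = 0
  s1 <- dplyr::bind_rows(fake_arm("T1", 1, "Aq", "GAIN", c(1, 10)),
                         fake_arm("T1", 2, "Bq", "LOSS", c(1, 10)))
  s2 <- dplyr::bind_rows(fake_arm("T2", 1, "Aq", "LOSS", c(1, 10)),
                         fake_arm("T2", 2, "Bq", "GAIN", c(1, 10)))
  r <- pair_loglr(s1, s2, toy_marginals())
  expect_equal(r$loglr, 0)
  expect_equal(r$xi, 0)
})

test_that("rare concordant events count for more than common ones", {
  # pi_normal matched across arms so only the event frequency differs
  marg <- tibble::tibble(arm_id = c("Aq", "Bq"), arm_index = 1:2, n = 100,
                         pi_gain = c(0.73, 0.10), pi_loss = c(0.05, 0.68),
                         pi_normal = c(0.22, 0.22))
  pair_on <- function(arm) {
    calls <- c("NORMAL", "NORMAL"); calls[arm] <- "GAIN"
    fps <- list(c(NA, NA), c(NA, NA)); fps[[arm]] <- c(1, 100)
    s1 <- dplyr::bind_rows(fake_arm("T1", 1, "Aq", calls[1], fps[[1]]),
                           fake_arm("T1", 2, "Bq", calls[2], fps[[2]]))
    s2 <- dplyr::bind_rows(fake_arm("T2", 1, "Aq", calls[1], fps[[1]]),
                           fake_arm("T2", 2, "Bq", calls[2], fps[[2]]))
    pair_loglr(s1, s2, marg)
  }
  common <- pair_on(1)  # shared gain on the pi = 0.73 arm
  rare <- pair_on(2)    # identical shared gain on the pi = 0.10 arm
  expect_gt(rare$loglr, common$loglr)
  # and the common arm's own contribution is the smaller one
  expect_gt(rare$arms[[1]]$contrib[2], common$arms[[1]]$contrib[1])
})

test_that("shrinking footprint overlap never increases logLR", {
  marg <- toy_marginals()
  loglr_s <- vapply(c(50, 30, 15, 5, 1, 0), function(ov) {
    s1 <- dplyr::bind_rows(fake_arm("T1", 1, "Aq", "GAIN", c(1, 50)),
                           fake_arm("T1", 2, "Bq", "NORMAL"))
    s2 <- dplyr::bind_rows(fake_arm("T2", 1, "Aq", "GAIN", c(51 - ov, 100 - ov)),
                           fake_arm("T2", 2, "Bq", "NORMAL"))
    pair_loglr(s1, s2, marg)$loglr
  }, numeric(1))
  expect_true(all(diff(loglr_s) <= 1e-12))
})

test_that("the coarse xi grid tracks a 10x finer grid", {
  set.seed(55)
  for (rep in 1:20) {
    n_arm <- 8
    calls1 <- sample(c("GAIN", "LOSS", "NORMAL"), n_arm, TRUE, prob = c(.3, .3, .4))
    calls2 <- calls1
    flip <- runif(n_arm) < 0.3
    calls2[flip] <- sample(c("GAIN", "LOSS", "NORMAL"), sum(flip), TRUE)
    marg <- tibble::tibble(arm_id = paste0("a", 1:n_arm), arm_index = 1:n_arm,
                           n = 50, pi_gain = runif(n_arm, .05, .4),
                           pi_loss = runif(n_arm, .05, .3))
    marg$pi_normal <- 1 - marg$pi_gain - marg$pi_loss
    mkseg <- function(id, calls) dplyr::bind_rows(lapply(1:n_arm, function(a) {
      lo <- sample.int(50, 1)
      fake_arm(id, a, paste0("a", a), calls[a], c(lo, lo + sample.int(50, 1)))
    }))
    s1 <- mkseg("T1", calls1); s2 <- mkseg("T2", calls2)
    coarse <- pair_loglr(s1, s2, marg, clonality_config(grid_step = 0.01))
    fine <- pair_loglr(s1, s2, marg, clonality_config(grid_step = 0.001))
    expect_lte(abs(coarse$xi - fine$xi), 0.01)
    expect_lte(fine$loglr - coarse$loglr, 1e-3)
  }
})

test_that("clonal pairs score higher than independent pairs on synthetic cohorts", {
  cfg <- small_sim(n_markers = 2000)
  sim <- simulate_cohort(cfg, n_patients = 200, fraction_clonal = 0.5, seed = 77)
  seg <- segment_profiles(median_center(sim$profiles))
  marg <- estimate_marginals(seg)
  by_sample <- split(seq_len(nrow(seg)), seg$sample)
  loglr <- vapply(seq_len(nrow(sim$pair_truth)), function(k) {
    pair_loglr(seg[by_sample[[sim$pair_truth$sample1[k]]], ],
               seg[by_sample[[sim$pair_truth$sample2[k]]], ], marg)$loglr
  }, numeric(1))
  tt <- stats::wilcox.test(loglr[sim$pair_truth$clonal],
                           loglr[!sim$pair_truth$clonal],
                           alternative = "greater")
  expect_lt(tt$p.value, 0.001)
  expect_gt(mean(loglr[sim$pair_truth$clonal]),
            mean(loglr[!sim$pair_truth$clonal]))
})

test_that("pair_loglr rejects mismatched arm sets", {
  s1 <- dplyr::bind_rows(fake_arm("T1", 1, "Aq", "NORMAL"),
                         fake_arm("T1", 2, "Bq", "NORMAL"))
  s2 <- fake_arm("T2", 1, "Aq", "NORMAL")
  expect_error(pair_loglr(s1, s2, toy_marginals()), "different arm sets")
})
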