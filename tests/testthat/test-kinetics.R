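test_that("repeated-measures ANOVA matches the definitional sum-of-squares decomposition", {
  m <- matrix(c(10, 12, 11,
                9,  13, 12,
                11, 15, 14), 3, 3, byrow = TRUE)
  got <- rm_anova_oneway(m)
  want <- rm_anova_ss_oracle(m)
  expect_equal(got$F, want$F, tolerance = 1e-10)
  expect_equal(got$df1, want$df1)
  expect_equal(got$df2, want$df2)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  set.seed(61)
  m2 <- matrix(rnorm(7 * 9, 8, 2), 7, 9) + outer(rnorm(7, 0, 2), rep(1, 9))
  got2 <- rm_anova_oneway(m2)
  want2 <- rm_anova_ss_oracle(m2)
  expect_equal(got2$F, want2$F, tolerance = 1e-10)
  expect_equal(got2$p, want2$p, tolerance = 1e-10)
})

test_that("RM-ANOVA degenerate and invariance behaviour", {
  flat <- matrix(5, 4, 3)
  got <- rm_anova_oneway(flat)
  expect_equal(got$F, 0); expect_equal(got$p, 1)
  set.seed(62)
  m <- matrix(rnorm(12), 4, 3)
  a <- rm_anova_oneway(m)
  # permuting subject rows leaves the statistic unchanged
  expect_equal(rm_anova_oneway(m[c(3, 1, 4, 2), ])$F, a$F, tolerance = 1e-12)
  # adding a per-subject constant leaves F unchanged (within-subject centring)
  expect_equal(rm_anova_oneway(m + c(10, -3, 5, 100))$F, a$F,
               tolerance = 1e-9)
  m_na <- m; m_na[2, 2] <- NA
  expect_error(rm_anova_oneway(m_na), "missing")
  expect_error(rm_anova_oneway(m[1, , drop = FALSE]), "at least 2")
})

test_that("first significant timepoint honours the 'and thereafter' rule", {
  tp <- c(2, 10, 15, 20, 25, 30, 35, 40, 45)
  flat <- matrix(7.7, 7, 9); colnames(flat) <- tp
  got <- first_significant_timepoint(flat, tp)
  expect_true(is.na(got$timepoint))
  # step decrease at 20 min with small noise: uncorrected and corrected
  # paired-t decisions agree, detection lands on 20
  set.seed(63)
  m <- simulate_nf_cohort(n_subjects = 7, timepoints_min = tp,
                          step_time_min = 20, step_drop_ml = 2.4,
                          noise_sd_ml = 0.2, seed = 631)
  got2 <- first_significant_timepoint(m, tp)
  expect_equal(got2$timepoint, 20)
  # direct paired-t confirmation at the detected timepoint
  d <- m[, 4] - m[, 1]
  t_direct <- mean(d) / (sd(d) / sqrt(7))
  expect_lt(2 * pt(abs(t_direct), 6, lower.tail = FALSE), 0.05)
  expect_error(first_significant_timepoint(m[1, , drop = FALSE], tp),
               "single subject")
  expect_error(first_significant_timepoint(m, tp, reference = 3),
               "reference")
})

test_that("t statistics match hand computation and degenerate contracts", {
  got <- independent_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(got$t, -1.224745, tolerance = 1e-6)
  expect_equal(got$df, 4)
  # definitional pooled-variance oracle
  sp2 <- (2 * var(c(1, 2, 3)) + 2 * var(c(2, 3, 4))) / 4
  expect_equal(got$t, (2 - 3) / sqrt(sp2 * (1 / 3 + 1 / 3)), tolerance = 1e-12)
  same <- independent_t(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  p <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(p$t, 0); expect_equal(p$p, 1)
  w <- independent_t(c(1, 2, 3), c(2, 4, 9), welch = TRUE)
  expect_lt(w$df, 4)  # Welch df shrink under unequal variances
})

test_that("KS normality accepts Gaussian samples in most seeded replicates", {
  set.seed(64)
  hits <- 0L
  for (i in 1:50) {
    x <- rnorm(300, 10, 2)
    if (ks_normality(x)$p > 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.9)
  d <- ks_normality(rnorm(100))
  expect_true(d$D >= 0 && d$D <= 1)
})

test_that("the NF time course reproduces phantom kinetics within tolerance", {
  tr <- small_truth()
  masks <- list()
  for (tp in tr$spec$timepoints_min) {
    ser <- render_lge_series(tr, tp)
    masks[[as.character(tp)]] <- segment_series(ser, tr$contours)
  }
  kin <- nf_timecourse(masks, tr$pixel_spacing_mm, tr$slice_thickness_mm)
  truth_nf <- unname(tr$volumes$nf_ml_by_time[as.character(kin$timepoint_min)])
  expect_true(all(abs(kin$nf_volume_ml / truth_nf - 1) < 0.05))
  # measured series non-increasing (within one voxel of slack)
  expect_true(all(diff(kin$nf_volume_ml) <= tr$voxel_ml + 1e-9))
  # total infarct volume stays constant within 5% across timepoints
  expect_true(all(abs(kin$mi_volume_ml / tr$volumes$mi_ml - 1) < 0.05))
  # a missing timepoint is recorded as NA with a warning
  masks2 <- masks; masks2["25"] <- list(NULL)
  expect_warning(kin2 <- nf_timecourse(masks2, tr$pixel_spacing_mm,
                                       tr$slice_thickness_mm), "missing")
  expect_true(is.na(kin2$nf_volume_ml[kin2$timepoint_min == 25]))
})
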