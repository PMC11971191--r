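test_that("ci_upper_cutoff matches the frozen t-table oracle", {
  # 99% two-sided upper CI limit, reference sets of size 3..12
  for (n in 3:12) {
    x <- seq_len(n) * 1.7          # arbitrary fixed reference values
    want <- mean(x) + T_TABLE_99[[as.character(n - 1)]] * sd(x) / sqrt(n)
    expect_equal(ci_upper_cutoff(x, 0.99), want, tolerance = 1e-4)
  }
  # worked example: [1,2,3] -> 2 + 9.924843/sqrt(3) * 1 = 7.7301; ceil -> 8
  expect_equal(ci_upper_cutoff(c(1, 2, 3)), 7.7301, tolerance = 1e-4)
  expect_equal(ci_upper_cutoff(c(1, 2, 3), rounding = "ceil"), 8)
})

test_that("ci_upper_cutoff degenerate and monotonicity properties", {
  # sigma = 0: cutoff equals the common value
  expect_equal(ci_upper_cutoff(rep(4.2, 5)), 4.2)
  # increases with confidence
  expect_lt(ci_upper_cutoff(c(1, 2, 3), 0.90), ci_upper_cutoff(c(1, 2, 3), 0.99))
  # increases with sigma at fixed mean and n
  expect_lt(ci_upper_cutoff(c(1.5, 2, 2.5)), ci_upper_cutoff(c(0, 2, 4)))
  # decreases with n at fixed mean and sample SD (both sets have sd = 1)
  expect_gt(ci_upper_cutoff(c(1, 2, 3)), ci_upper_cutoff(c(1, 2, 3, 1, 3)))
  expect_error(ci_upper_cutoff(c(5)), "at least 2")
})

test_that("group assignment implements the positivity grid", {
  thr <- group_thresholds(30, 1)
  expect_equal(assign_group(10, 0, thr), "DOUBLE_NEGATIVE")
  expect_equal(assign_group(50, 0, thr), "INTERMEDIATE")
  expect_equal(assign_group(50, 5, thr), "DOUBLE_POSITIVE")
  expect_warning(lab <- assign_group(10, 5, thr), "ATYPICAL")
  expect_equal(lab, "ATYPICAL")
  # strict inequality: exactly at the cut-off is negative
  expect_equal(assign_group(30, 1, thr), "DOUBLE_NEGATIVE")
})

test_that("cohort classification derives cut-offs from Braak 0 references", {
  samples <- data.frame(
    sample_id = sprintf("S%d", 1:8),
    braak_stage = c("0", "0", "0", "0", "I", "I", "IV", "IV"),
    pla_diffuse_mean = c(10, 12, 8, 11, 80, 95, 200, 260),
    at8_perikaryal_mean = c(0, 0.2, 0.1, 0, 0.3, 0.5, 20, 30)
  )
  cls <- classify_cohort(samples)
  ref <- samples[samples$braak_stage == "0", ]
  expect_equal(cls$thresholds$pla_cutoff,
               ci_upper_cutoff(ref$pla_diffuse_mean))
  expect_equal(cls$thresholds$at8_cutoff,
               ci_upper_cutoff(ref$at8_perikaryal_mean, rounding = "ceil"))
  expect_equal(cls$samples$label,
               c(rep("DOUBLE_NEGATIVE", 4), "INTERMEDIATE", "INTERMEDIATE",
                 "DOUBLE_POSITIVE", "DOUBLE_POSITIVE"))
  # all-zero reference values: cutoff 0, any positive count is positive
  z <- samples
  z$pla_diffuse_mean[1:4] <- 0
  z$at8_perikaryal_mean[1:4] <- 0
  clz <- classify_cohort(z)
  expect_equal(clz$thresholds$pla_cutoff, 0)
  expect_true(all(clz$samples$label[5:8] != "DOUBLE_NEGATIVE"))
  # explicit thresholds bypass derivation
  cle <- classify_cohort(samples, thresholds = group_thresholds(30, 1))
  expect_equal(cle$samples$label[5], "INTERMEDIATE")
  # no reference samples and no explicit thresholds: clean error
  nr <- samples[samples$braak_stage != "0", ]
  expect_error(classify_cohort(nr), "reference samples")
})

test_that("labels partition the cohort and respect PLA monotonicity", {
  plate <- simulate_plate(default_group_presets(), seed = 17)
  cls <- classify_cohort(plate$samples)
  expect_true(all(table(cls$samples$sample_id) == 1))
  expect_true(all(cls$samples$label %in%
                    c("DOUBLE_NEGATIVE", "INTERMEDIATE", "DOUBLE_POSITIVE",
                      "ATYPICAL")))
  # raising a PLA count can never send a PLA-positive label to DN
  thr <- cls$thresholds
  for (i in seq_len(nrow(cls$samples))) {
    s <- cls$samples[i, ]
    if (s$label %in% c("INTERMEDIATE", "DOUBLE_POSITIVE")) {
      bumped <- suppressWarnings(
        assign_group(s$pla_diffuse_mean * 2, s$at8_perikaryal_mean, thr)
      )
      expect_true(bumped != "DOUBLE_NEGATIVE")
    }
  }
})

test_that("well-separated synthetic cohorts recover their generating labels", {
  # explicit nominal cut-offs (30, 1): count distributions sit >= 3 SD away
  mis <- 0L; tot <- 0L
  for (s in 1:10) {
    plate <- simulate_plate(default_group_presets(), seed = s)
    cls <- classify_cohort(plate$samples,
                           thresholds = group_thresholds(30, 1))
    mis <- mis + sum(cls$samples$label != cls$samples$group)
    tot <- tot + nrow(cls$samples)
  }
  expect_gte(1 - mis / tot, 0.95)
})
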