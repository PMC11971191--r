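test_that("Dunnett p-values match the independent scipy oracle", {
  # fixtures frozen from scipy.stats.dunnett (two-sided)
  ctrl <- c(10.1, 9.8, 10.3, 10.0, 9.9, 10.2)
  g1 <- c(11.2, 10.9, 11.5, 11.1, 11.3)
  g2 <- c(10.2, 10.4, 9.9, 10.1, 10.3)
  r <- anova_oneway_dunnett(c(ctrl, g1, g2),
                            rep(c("ctrl", "g1", "g2"), c(6, 5, 5)), "ctrl")
  expect_equal(r$posthoc$t, c(9.468538662573994, 1.070356544464907),
               tolerance = 1e-8)
  expect_lt(r$posthoc$adjusted_p[1], 1e-5)        # oracle: 1.64e-07
  expect_lt(abs(r$posthoc$adjusted_p[2] - 0.482692120873223), 1e-3)

  c2 <- c(0.3, -0.5, 0.1, 0.7, -0.2, 0.4, 0.0)
  a <- c(1.1, 0.6, 1.4, 0.9)
  b <- c(0.2, -0.1, 0.5, 0.1, 0.0)
  c3 <- c(2.1, 1.8, 2.5)
  r2 <- anova_oneway_dunnett(
    c(c2, a, b, c3),
    rep(c("ctrl", "a", "b", "c"), c(7, 4, 5, 3)), "ctrl"
  )
  ph <- r2$posthoc[order(r2$posthoc$comparison), ]
  expect_equal(ph$t, c(4.1404343892527375, 0.12867300654835806,
                       8.572861228014704), tolerance = 1e-8)
  expect_lt(abs(ph$adjusted_p[1] - 0.0024457020016268594), 1e-3)
  expect_lt(abs(ph$adjusted_p[2] - 0.998663202320717), 2e-3)
  expect_lt(ph$adjusted_p[3], 1e-5)               # oracle: 3.49e-07
})

test_that("Dunnett handles the null case and inflates over raw p", {
  # two identical groups: omnibus p = 1, nothing significant
  r <- anova_oneway_dunnett(c(1, 2, 3, 1, 2, 3),
                            rep(c("ctrl", "t"), each = 3), "ctrl")
  expect_equal(r$omnibus_p, 1)
  expect_false(any(r$posthoc$significant))
  # with k = 1 comparison the adjusted p equals the raw two-sided t p
  expect_equal(r$posthoc$adjusted_p, r$posthoc$raw_p, tolerance = 1e-10)
  # with k = 2 comparisons adjustment can only inflate
  set.seed(31)
  v <- rnorm(18)
  g <- rep(c("ctrl", "a", "b"), each = 6)
  r2 <- anova_oneway_dunnett(v, g, "ctrl")
  expect_true(all(r2$posthoc$adjusted_p >= r2$posthoc$raw_p))
  expect_error(anova_oneway_dunnett(v, g, "absent"), "not present")
})

test_that("Dunnett flags a 5-SD shift against control", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    v <- c(rnorm(6, 0), rnorm(5, 5), rnorm(5, 0))
    g <- rep(c("ctrl", "shift", "same"), c(6, 5, 5))
    r <- anova_oneway_dunnett(v, g, "ctrl")
    hits <- hits + r$posthoc$significant[grepl("shift", r$posthoc$comparison)]
  }
  expect_gte(hits, 19)
})

test_that("Bonferroni pairwise comparisons multiply raw p by the family size", {
  set.seed(5)
  v <- rnorm(18)
  g <- rep(c("a", "b", "c"), each = 6)
  r <- anova_oneway_bonferroni(v, g)
  expect_equal(nrow(r$posthoc), 3)
  expect_equal(r$posthoc$adjusted_p, pmin(1, 3 * r$posthoc$raw_p))
  # identical groups: nothing significant
  r0 <- anova_oneway_bonferroni(rep(c(1, 2, 3), 6), g)
  expect_false(any(r0$posthoc$significant))
  expect_equal(r0$omnibus_p, 1)
})

test_that("two-way ANOVA with Dunnett compares conditions to control per group", {
  grp <- rep(rep(c("Int", "DP"), each = 9), 1)
  cond <- rep(rep(c("preBH", "postAT8", "postTau5"), each = 3), 2)
  base <- rep(c(1, 2, 3), 6)
  # all conditions identical to control: nothing significant
  r0 <- anova_twoway_dunnett(base, grp, cond, "preBH")
  expect_false(any(r0$posthoc$significant))
  expect_equal(nrow(r0$posthoc), 4)   # 2 groups x 2 comparisons
  # one condition strongly shifted in one group
  v <- base
  v[grp == "Int" & cond == "postAT8"] <- base[1:3] + 25
  r1 <- anova_twoway_dunnett(v, grp, cond, "preBH")
  ph <- r1$posthoc
  expect_true(ph$significant[ph$comparison == "Int: postAT8 - preBH"])
  expect_false(ph$significant[ph$comparison == "DP: postAT8 - preBH"])
  # degenerate designs error
  expect_error(anova_twoway_dunnett(base, grp, rep("preBH", 18), "preBH"),
               "2 conditions")
  expect_error(anova_twoway_dunnett(base[-(1:3)], grp[-(1:3)], cond[-(1:3)],
                                    "preBH"),
               "incomplete factorial")
})

test_that("group size and input validation", {
  expect_error(anova_oneway_bonferroni(1:4, c("a", "a", "a", "b")), "n >= 2")
  expect_error(anova_oneway_bonferroni(1:4, rep("a", 4)), "2 groups")
  expect_error(anova_oneway_dunnett(1:3, c("a", "a", "b"), "a"), "n >= 2")
})
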