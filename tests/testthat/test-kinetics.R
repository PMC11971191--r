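test_that("restrict_to_cutoff drops readings past the assay endpoint", {
  cv <- flat_curve(duration = 60)
  r <- restrict_to_cutoff(cv, assay_config(cutoff_h = 52))
  expect_lte(max(r$times_h), 52)
  expect_equal(max(r$times_h), 52)   # 52 is on the 15-min grid
  # all times within the cut-off: identity
  short <- flat_curve(duration = 40)
  expect_identical(restrict_to_cutoff(short)$times_h, short$times_h)
  # empty retained window is an error
  late <- tht_curve(c(0.25, 0.5), c(100, 100))
  expect_error(restrict_to_cutoff(late, assay_config(cutoff_h = 0.1)),
               "cut-off")
})

test_that("compute_fmax is the maximum over the retained window", {
  cv <- tht_curve(0:3, c(100, 105, 200, 180))
  expect_equal(compute_fmax(cv), 200)
  expect_equal(compute_fmax(flat_curve(f0 = 100)), 100)
  # peak after the cut-off is excluded; brute-force oracle on retained reads
  t <- seq(0, 60, by = 0.25)
  f <- 100 + t                       # rises forever; peak at 60 h
  f[t == 55] <- 1e4                  # spike beyond the cut-off
  cv2 <- tht_curve(t, f)
  expect_equal(compute_fmax(cv2), max(f[t <= 52]))
  expect_equal(compute_fmax(cv2), 152)
})

test_that("lag time uses baseline mean + n_sd baseline SDs, strict crossing", {
  # zero-SD baseline: threshold is the baseline mean, any rise triggers
  cv <- step_curve(t_jump = 5)
  lag <- compute_lag_time(cv)
  expect_equal(lag$lag_h, 5)
  expect_false(lag$censored)
  expect_equal(lag$threshold, 100)

  # hand-computed threshold: baseline [100,102,98,100], sample SD
  # sqrt(8/3) = 1.63299, theta = 108.1650
  t <- seq(0, 10, by = 0.25)
  f <- rep(100, length(t))
  f[2] <- 102; f[3] <- 98
  f[t == 6.25] <- 108.2
  f[t > 6.25] <- 130
  cv2 <- tht_curve(t, f)
  lag2 <- compute_lag_time(cv2, assay_config(baseline_n_reads = 4))
  expect_equal(lag2$threshold, 100 + 5 * sqrt(8 / 3), tolerance = 1e-12)
  expect_equal(lag2$lag_h, 6.25)

  # monotone flat negative control: censored at the 52-h endpoint
  lag3 <- compute_lag_time(flat_curve())
  expect_equal(lag3$lag_h, 52)
  expect_true(lag3$censored)

  # baseline window longer than the curve is an error
  expect_error(
    compute_lag_time(tht_curve(0:3, rep(1, 4)),
                     assay_config(baseline_n_reads = 10)),
    "baseline window"
  )
})

test_that("time to Fmax takes the first attainment and censors at the end", {
  cv <- tht_curve(0:4, c(0, 10, 30, 35, 35))
  tf <- compute_time_to_fmax(cv)
  expect_equal(tf$t_fmax_h, 3)
  expect_false(tf$censored)
  # two equal maxima: earliest wins
  cv2 <- tht_curve(c(0, 10, 15, 20, 25), c(0, 50, 10, 50, 10))
  expect_equal(compute_time_to_fmax(cv2)$t_fmax_h, 10)
  # strictly increasing to the cut-off: censored at 52
  t <- seq(0, 60, by = 0.25)
  cv3 <- tht_curve(t, 100 + t)
  tf3 <- compute_time_to_fmax(cv3)
  expect_equal(tf3$t_fmax_h, 52)
  expect_true(tf3$censored)
})

test_that("Vmax is the maximum sliding-window slope", {
  cv <- tht_curve(0:3, c(0, 10, 30, 35))
  expect_equal(compute_vmax(cv), 20)
  expect_equal(compute_vmax(flat_curve()), 0)
  # noise-free logistic at dense sampling: max slope = rate_k*amplitude/4
  p <- kinetics_params(f0 = 0, amplitude = 1000, rate_k = 0.8, t_half = 20,
                       noise_sd = 0, read_interval_h = 0.05, duration_h = 40)
  cv2 <- simulate_tht_curve(p, seed = 1)
  expect_equal(compute_vmax(cv2), 0.8 * 1000 / 4, tolerance = 0.02)
  # wider least-squares window agrees on a straight line
  cv3 <- tht_curve(0:9, 3 * (0:9))
  expect_equal(compute_vmax(cv3, assay_config(slope_window = 4)), 3)
  expect_error(compute_vmax(tht_curve(0:2, 1:3),
                            assay_config(slope_window = 5)),
               "retained readings")
})

test_that("per-sample summaries average replicates with censor substitution", {
  cfg <- assay_config()
  wells <- list(step_curve(10, well_id = "A1"),
                step_curve(12, well_id = "A2"),
                flat_curve(well_id = "A3"))
  s <- summarize_sample(wells, cfg)
  expect_equal(s$sample$lag_h, mean(c(10, 12, 52)))
  expect_equal(s$sample$n_censored, 1)
  expect_equal(nrow(s$wells), 3)
  # identical wells: mean equals the single-well value
  trip <- list(step_curve(8, well_id = "B1"), step_curve(8, well_id = "B2"),
               step_curve(8, well_id = "B3"))
  expect_equal(summarize_sample(trip, cfg)$sample$lag_h, 8)
  expect_error(summarize_sample(list(), cfg), "at least one")
  mixed <- list(step_curve(8, sample_id = "S1"),
                step_curve(8, sample_id = "S2"))
  expect_error(summarize_sample(mixed, cfg), "multiple sample_ids")
})

test_that("kinetic invariants: ordering, censoring bounds, threshold monotonicity", {
  cfg <- assay_config()
  set.seed(99)
  for (i in 1:20) {
    p <- kinetics_params(
      f0 = runif(1, 50, 200), amplitude = runif(1, 500, 2000),
      rate_k = runif(1, 0.3, 1.5), t_half = runif(1, 8, 45), noise_sd = 0
    )
    cv <- simulate_tht_curve(p, seed = i)
    lag <- compute_lag_time(cv, cfg)
    tf <- compute_time_to_fmax(cv, cfg)
    # monotone non-decreasing noise-free curve: lag precedes time-to-max
    expect_lte(lag$lag_h, tf$t_fmax_h)
    # no kinetic time parameter exceeds the cut-off
    expect_lte(lag$lag_h, cfg$cutoff_h)
    expect_lte(tf$t_fmax_h, cfg$cutoff_h)
    if (lag$censored) expect_identical(lag$lag_h, cfg$cutoff_h)
    # raising n_sd never shortens the lag
    lag_hi <- compute_lag_time(cv, assay_config(n_sd = 10))
    expect_gte(lag_hi$lag_h, lag$lag_h)
  }
})

test_that("lag recovery on noisy wells: median error within one read interval", {
  errs <- vapply(1:100, function(s) {
    p <- kinetics_params(f0 = 100, amplitude = 1500, rate_k = 0.8,
                         t_half = 16, noise_sd = 15)   # 1% of amplitude
    cv <- simulate_tht_curve(p, seed = s)
    lag <- compute_lag_time(cv)
    abs(lag$lag_h - logistic_crossing_time(lag$threshold, p))
  }, numeric(1))
  expect_lte(median(errs), 0.25)
})
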