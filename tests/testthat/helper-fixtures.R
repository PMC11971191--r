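# Shared fixtures: constructed curves and tiny images with known answers.

# Step curve: baseline `f0` (zero noise), jumps to `f0 + jump` at `t_jump`.
# With a zero-SD baseline the lag threshold equals f0, so the lag is the
# first read strictly above f0, i.e. t_jump (on-grid).
step_curve <- function(t_jump, f0 = 100, jump = 900, duration = 60,
                       by = 0.25, sample_id = "S1", well_id = "W01") {
  t <- seq(0, duration, by = by)
  tht_curve(t, f0 + jump * (t >= t_jump), well_id = well_id,
            sample_id = sample_id)
}

flat_curve <- function(f0 = 100, duration = 60, by = 0.25,
                       sample_id = "S1", well_id = "W01") {
  t <- seq(0, duration, by = by)
  tht_curve(t, rep(f0, length(t)), well_id = well_id, sample_id = sample_id)
}

# Image with explicit foreground pixel coordinates on a constant background.
image_from_pixels <- function(nrow, ncol, pixels, fg = 1000L, bg = 0L,
                              pixel_size_um = 1) {
  m <- matrix(bg, nrow, ncol)
  if (length(pixels)) m[pixels] <- fg
  image_grid(m, pixel_size_um)
}

# Two-sided t quantiles at the 99% level, df 2..11, frozen from an
# independent t-table oracle (scipy.stats.t.ppf(0.995, df)).
T_TABLE_99 <- c(
  `2` = 9.924843, `3` = 5.840909, `4` = 4.604095, `5` = 4.032143,
  `6` = 3.707428, `7` = 3.499483, `8` = 3.355387, `9` = 3.249836,
  `10` = 3.169273, `11` = 3.105807
)
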