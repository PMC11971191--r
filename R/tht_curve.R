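#' ThT fluorescence curve for a single well
#'
#' Container for one well's Thioflavin-T fluorescence time series in a seed
#' amplification assay, together with its plate metadata.
#'
#' @param times_h numeric vector of read times in hours, strictly increasing.
#' @param fluorescence_au numeric vector of fluorescence readings (arbitrary
#'   units), same length as `times_h`.
#' @param well_id well identifier (e.g. `"A01"`).
#' @param sample_id sample identifier.
#' @param dilution sample dilution as a fraction (default `1e-1`, the dilution
#'   at which group comparisons are run).
#' @param group optional group label carried through from the sample sheet.
#' @param is_control logical; `TRUE` for assay control wells.
#' @return an object of class `tht_curve`: a list with the fields above.
#' @examples
#' tht_curve(times_h = c(0, 0.25, 0.5), fluorescence_au = c(100, 101, 99),
#'           well_id = "A01", sample_id = "S1")
#' @export
tht_curve <- function(times_h, fluorescence_au, well_id = "W01",
                      sample_id = "sample", dilution = 1e-1,
                      group = NA_character_, is_control = FALSE) {
  times_h <- as.numeric(times_h)
  fluorescence_au <- as.numeric(fluorescence_au)
  if (length(times_h) != length(fluorescence_au)) {
    stop("`times_h` and `fluorescence_au` must have the same length")
  }
  if (length(times_h) < 1L) stop("curve must contain at least one reading")
  if (any(diff(times_h) <= 0)) stop("`times_h` must be strictly increasing")
  structure(
    list(
      well_id = as.character(well_id),
      sample_id = as.character(sample_id),
      dilution = as.numeric(dilution),
      group = as.character(group),
      is_control = isTRUE(is_control),
      times_h = times_h,
      fluorescence_au = fluorescence_au
    ),
    class = "tht_curve"
  )
}

#' @export
print.tht_curve <- function(x, ...) {
  cat(sprintf(
    "<tht_curve> well %s, sample %s (group %s), dilution %g\n  %d reads over %.2f h, fluorescence %.1f-%.1f a.u.\n",
    x$well_id, x$sample_id, x$group, x$dilution,
    length(x$times_h), max(x$times_h),
    min(x$fluorescence_au), max(x$fluorescence_au)
  ))
  invisible(x)
}

#' @export
length.tht_curve <- function(x) length(x$times_h)

#' @export
as.data.frame.tht_curve <- function(x, ...) {
  data.frame(
    well = x$well_id, sample_id = x$sample_id, group = x$group,
    dilution = x$dilution, time_h = x$times_h,
    fluorescence_au = x$fluorescence_au,
    stringsAsFactors = FALSE
  )
}

#' Parameters of the logistic aggregation-kinetics model
#'
#' The simulator models a seeded-aggregation ThT curve as a four-parameter
#' logistic, \eqn{F(t) = f_0 + A / (1 + e^{-k (t - t_{1/2})})}, plus bounded
#' additive noise: the simplest form reproducing the lag, growth and plateau
#' phases of real seed-amplification curves while admitting a closed-form
#' threshold-crossing time (the ground-truth lag).
#'
#' @param f0 baseline fluorescence (a.u.).
#' @param amplitude plateau rise above baseline (a.u.), `>= 0`.
#' @param rate_k logistic growth rate (1/h), `> 0`.
#' @param t_half time of half-maximal rise (h).
#' @param noise_sd total additive noise standard deviation (a.u.). Read
#'   noise is modelled as the instrument's shake-cycle flicker — a periodic
#'   component at a period commensurate with the read grid carrying 80% of
#'   the noise variance, with a random phase per well — plus a truncated
#'   (3 SD) Gaussian residual. The baseline window therefore sees the full
#'   flicker range, which keeps the baseline + 5 SD lag threshold stable on
#'   flat negative-control curves, as it is on the real instrument.
#' @param read_interval_h sampling interval (h); the instrument reads every
#'   15 minutes, so the default is `0.25`.
#' @param duration_h total recorded time (h), default `60`.
#' @return an object of class `kinetics_params` (a named list).
#' @export
kinetics_params <- function(f0 = 100, amplitude = 900, rate_k = 1,
                            t_half = 20, noise_sd = 0,
                            read_interval_h = 0.25, duration_h = 60) {
  assert_scalar_num(f0, "f0")
  assert_scalar_num(amplitude, "amplitude", lower = 0)
  assert_scalar_num(rate_k, "rate_k", lower = 0, strict_lower = TRUE)
  assert_scalar_num(t_half, "t_half")
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  assert_scalar_num(read_interval_h, "read_interval_h", lower = 0,
                    strict_lower = TRUE)
  assert_scalar_num(duration_h, "duration_h", lower = read_interval_h)
  structure(
    list(f0 = f0, amplitude = amplitude, rate_k = rate_k, t_half = t_half,
         noise_sd = noise_sd, read_interval_h = read_interval_h,
         duration_h = duration_h),
    class = "kinetics_params"
  )
}

#' Noise-free logistic fluorescence
#'
#' @param t time(s) in hours.
#' @param params a [kinetics_params()] object.
#' @return fluorescence in a.u. at each `t`.
#' @export
logistic_fluorescence <- function(t, params) {
  params$f0 + params$amplitude / (1 + exp(-params$rate_k * (t - params$t_half)))
}

#' Analytic threshold-crossing time of the logistic model
#'
#' Inverts the noise-free logistic to the time at which fluorescence reaches
#' a threshold \eqn{\theta}: \eqn{t_{1/2} - \log(A/(\theta - f_0) - 1)/k}.
#' This is the ground-truth lag recorded next to every simulated curve.
#'
#' @param threshold fluorescence threshold (a.u.).
#' @param params a [kinetics_params()] object.
#' @return crossing time in hours, or `NA_real_` ("never") when the threshold
#'   lies outside the open interval `(f0, f0 + amplitude)` so no crossing
#'   exists.
#' @examples
#' p <- kinetics_params(f0 = 100, amplitude = 900, rate_k = 1, t_half = 10)
#' logistic_crossing_time(200, p)  # 10 - log(9) = 7.803 h
#' @export
logistic_crossing_time <- function(threshold, params) {
  lo <- params$f0
  hi <- params$f0 + params$amplitude
  if (!(threshold > lo && threshold < hi)) return(NA_real_)
  params$t_half - log(params$amplitude / (threshold - lo) - 1) / params$rate_k
}

#' Simulate one ThT curve
#'
#' Samples the logistic model at `t = 0, read_interval_h, ..., duration_h`
#' and adds truncated-Gaussian read noise. The returned object carries its
#' generating parameters and the analytic lag for any later threshold query.
#'
#' @param params a [kinetics_params()] object.
#' @param seed integer seed; the curve is reproducible given (`params`,
#'   `seed`).
#' @inheritParams tht_curve
#' @return a [tht_curve()] with attribute `"ground_truth"`: a list with the
#'   generating `params` and a function `lag_for(threshold)` returning the
#'   analytic crossing time (or `NA` for "never").
#' @export
simulate_tht_curve <- function(params, seed = 1L, well_id = "W01",
                               sample_id = "sample", dilution = 1e-1,
                               group = NA_character_, is_control = FALSE) {
  stopifnot(inherits(params, "kinetics_params"))
  times <- seq(0, params$duration_h, by = params$read_interval_h)
  clean <- logistic_fluorescence(times, params)
  noisy <- with_seed(seed, clean + curve_noise(times, params$noise_sd))
  curve <- tht_curve(times, noisy, well_id = well_id, sample_id = sample_id,
                     dilution = dilution, group = group,
                     is_control = is_control)
  attr(curve, "ground_truth") <- list(
    params = params,
    lag_for = function(threshold) logistic_crossing_time(threshold, params)
  )
  curve
}
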