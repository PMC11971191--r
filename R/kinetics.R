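#' Assay analysis configuration
#'
#' Settings of the kinetic-parameter extraction: the 52-h assay cut-off (a
#' reproducible endpoint before the negative control's spontaneous
#' aggregation), the lag threshold of baseline mean + 5 SD, the number of
#' initial reads defining the baseline, and the slope-window width for the
#' maximum-slope estimate.
#'
#' @param cutoff_h assay cut-off in hours (default 52). Times that never
#'   occur within the cut-off are censored to exactly this value.
#' @param n_sd number of baseline standard deviations above the baseline
#'   mean defining the lag threshold (default 5).
#' @param baseline_n_reads initial reads used for the baseline mean and SD
#'   (default 10, i.e. the first 2.5 h at 15-min reads).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`;
#'   the original analysis does not state which was used.
#' @param slope_window number of consecutive intervals per slope fit,
#'   `>= 2` points; default 2 points = raw finite difference.
#' @param strict_crossing if `TRUE` (default) the lag requires fluorescence
#'   strictly above the threshold.
#' @return an object of class `assay_config`.
#' @export
assay_config <- function(cutoff_h = 52, n_sd = 5, baseline_n_reads = 10L,
                         sd_type = c("sample", "population"),
                         slope_window = 2L, strict_crossing = TRUE) {
  assert_scalar_num(cutoff_h, "cutoff_h", lower = 0, strict_lower = TRUE)
  assert_scalar_num(n_sd, "n_sd", lower = 0)
  stopifnot(baseline_n_reads >= 2, slope_window >= 2)
  structure(
    list(cutoff_h = cutoff_h, n_sd = n_sd,
         baseline_n_reads = as.integer(baseline_n_reads),
         sd_type = match.arg(sd_type),
         slope_window = as.integer(slope_window),
         strict_crossing = isTRUE(strict_crossing)),
    class = "assay_config"
  )
}

#' Restrict a curve to the assay cut-off
#'
#' Drops all readings after `cutoff_h`; every kinetic parameter is computed
#' on the retained window only.
#'
#' @param curve a [tht_curve()].
#' @param config an [assay_config()].
#' @return the restricted [tht_curve()].
#' @export
restrict_to_cutoff <- function(curve, config = assay_config()) {
  stopifnot(inherits(curve, "tht_curve"))
  keep <- curve$times_h <= config$cutoff_h
  if (!any(keep)) {
    stop(sprintf("no readings at or before the %g-h cut-off", config$cutoff_h))
  }
  curve$times_h <- curve$times_h[keep]
  curve$fluorescence_au <- curve$fluorescence_au[keep]
  curve
}

#' Maximum ThT fluorescence (F_max)
#'
#' @inheritParams restrict_to_cutoff
#' @return maximum fluorescence (a.u.) within the cut-off window.
#' @export
compute_fmax <- function(curve, config = assay_config()) {
  curve <- restrict_to_cutoff(curve, config)
  max(curve$fluorescence_au)
}

# Baseline threshold: mean of the first `baseline_n_reads` readings plus
# `n_sd` of their standard deviation.
lag_threshold <- function(curve, config) {
  n <- config$baseline_n_reads
  if (length(curve$times_h) < n) {
    stop(sprintf("baseline window (%d reads) longer than curve (%d reads)",
                 n, length(curve$times_h)))
  }
  base <- curve$fluorescence_au[seq_len(n)]
  s <- stats::sd(base)
  if (config$sd_type == "population") s <- s * sqrt((n - 1) / n)
  mean(base) + config$n_sd * s
}

#' Lag time with endpoint censoring
#'
#' The lag is the first read time at which fluorescence exceeds the
#' threshold `baseline mean + n_sd * baseline SD`. A well that never
#' crosses within the cut-off is censored: its lag is reported as exactly
#' `cutoff_h` with `censored = TRUE`, the endpoint-substitution convention
#' used throughout the assay. No sub-read interpolation is applied; 15 min
#' is the instrument's native resolution.
#'
#' @inheritParams restrict_to_cutoff
#' @return list with `lag_h`, `censored`, and the `threshold` used.
#' @export
compute_lag_time <- function(curve, config = assay_config()) {
  curve <- restrict_to_cutoff(curve, config)
  theta <- lag_threshold(curve, config)
  above <- if (config$strict_crossing) {
    curve$fluorescence_au > theta
  } else {
    curve$fluorescence_au >= theta
  }
  if (any(above)) {
    list(lag_h = curve$times_h[which(above)[1]], censored = FALSE,
         threshold = theta)
  } else {
    list(lag_h = config$cutoff_h, censored = TRUE, threshold = theta)
  }
}

#' Time to maximum fluorescence with endpoint censoring
#'
#' First read time at which the within-cut-off maximum is attained (ties go
#' to the earliest read). Censored to `cutoff_h` when the maximum falls on
#' the cut-off itself, as for a curve still rising at 52 h.
#'
#' @inheritParams restrict_to_cutoff
#' @return list with `t_fmax_h` and `censored`.
#' @export
compute_time_to_fmax <- function(curve, config = assay_config()) {
  curve <- restrict_to_cutoff(curve, config)
  t_at <- curve$times_h[which.max(curve$fluorescence_au)]
  last <- curve$times_h[length(curve$times_h)]
  # first attainment on the final retained read means the maximum was not
  # reached within the window: endpoint-substitute
  if (t_at == last && length(curve$times_h) > 1L) {
    list(t_fmax_h = config$cutoff_h, censored = TRUE)
  } else {
    list(t_fmax_h = t_at, censored = FALSE)
  }
}

#' Maximum slope (V_max)
#'
#' Maximum over sliding windows of `slope_window` consecutive readings of
#' the least-squares slope of fluorescence against time; with the default
#' window of 2 this is the maximum pairwise finite difference dF/dt.
#'
#' @inheritParams restrict_to_cutoff
#' @return maximum slope in a.u./h.
#' @export
compute_vmax <- function(curve, config = assay_config()) {
  curve <- restrict_to_cutoff(curve, config)
  w <- config$slope_window
  n <- length(curve$times_h)
  if (n < w) {
    stop(sprintf("need at least %d retained readings for slope window %d",
                 w, w))
  }
  t <- curve$times_h; f <- curve$fluorescence_au
  if (w == 2L) {
    return(max(diff(f) / diff(t)))
  }
  slopes <- vapply(seq_len(n - w + 1L), function(i) {
    tt <- t[i:(i + w - 1L)]; ff <- f[i:(i + w - 1L)]
    sum((tt - mean(tt)) * (ff - mean(ff))) / sum((tt - mean(tt))^2)
  }, numeric(1))
  max(slopes)
}

#' Kinetic summary of one well
#'
#' All four kinetic parameters plus censoring flags for a single well.
#'
#' @inheritParams restrict_to_cutoff
#' @return one-row data frame of class `kinetic_summary`: `well`,
#'   `sample_id`, `group`, `fmax`, `lag_h`, `lag_censored`, `t_fmax_h`,
#'   `t_fmax_censored`, `vmax`.
#' @export
summarize_well <- function(curve, config = assay_config()) {
  lag <- compute_lag_time(curve, config)
  tf <- compute_time_to_fmax(curve, config)
  out <- data.frame(
    well = curve$well_id, sample_id = curve$sample_id,
    group = curve$group,
    fmax = compute_fmax(curve, config),
    lag_h = lag$lag_h, lag_censored = lag$censored,
    t_fmax_h = tf$t_fmax_h, t_fmax_censored = tf$censored,
    vmax = compute_vmax(curve, config),
    stringsAsFactors = FALSE
  )
  class(out) <- c("kinetic_summary", class(out))
  out
}

#' Per-sample kinetic summary over replicate wells
#'
#' Averages each kinetic parameter over a sample's replicate wells.
#' Censored wells contribute the cut-off value itself (the endpoint
#' substitution), so a fully censored triplicate averages to exactly
#' `cutoff_h`.
#'
#' @param curves list of [tht_curve()] objects, all from the same sample.
#' @param config an [assay_config()].
#' @return list with `sample` (one-row data frame of replicate means plus
#'   `n_wells` and `n_censored`) and `wells` (per-well `kinetic_summary`
#'   table).
#' @export
summarize_sample <- function(curves, config = assay_config()) {
  if (length(curves) < 1) stop("at least one replicate well is required")
  ids <- unique(vapply(curves, function(cv) cv$sample_id, character(1)))
  if (length(ids) != 1) {
    stop("curves span multiple sample_ids: ", paste(ids, collapse = ", "))
  }
  wells <- do.call(rbind, lapply(curves, summarize_well, config = config))
  sample <- data.frame(
    sample_id = ids, group = wells$group[1],
    fmax = mean(wells$fmax), lag_h = mean(wells$lag_h),
    t_fmax_h = mean(wells$t_fmax_h), vmax = mean(wells$vmax),
    n_wells = nrow(wells), n_censored = sum(wells$lag_censored),
    stringsAsFactors = FALSE
  )
  list(sample = sample, wells = wells)
}

#' Kinetic summaries for every sample on a plate
#'
#' @param curves list of [tht_curve()] objects (e.g. from
#'   [read_plate_csv()] or a [simulate_plate()] result's `$curves`).
#' @param config an [assay_config()].
#' @return list with `samples` (one row per sample) and `wells` (one row
#'   per well).
#' @export
summarize_plate <- function(curves, config = assay_config()) {
  ids <- vapply(curves, function(cv) cv$sample_id, character(1))
  per <- lapply(split(curves, ids), summarize_sample, config = config)
  list(
    samples = do.call(rbind, c(lapply(per, `[[`, "sample"),
                               list(make.row.names = FALSE))),
    wells = do.call(rbind, c(lapply(per, `[[`, "wells"),
                             list(make.row.names = FALSE)))
  )
}
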