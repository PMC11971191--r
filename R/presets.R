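#' Group simulation preset
#'
#' Bundles, for one pathology group, the between-sample distributions of the
#' aggregation-kinetics parameters, the per-sample mean particle-count
#' distributions (diffuse tau-PLA and perikaryal AT8), and the FRET inclusion
#' fraction. Samples drawn from a preset share one parameter draw across
#' their replicate wells; wells then differ only by read noise, mirroring a
#' case run in triplicate.
#'
#' @param group one of `"DOUBLE_NEGATIVE"`, `"INTERMEDIATE"`,
#'   `"DOUBLE_POSITIVE"`, `"NEG_CONTROL"`, `"POS_CONTROL"`.
#' @param n_samples number of cases drawn from this preset, `>= 1`.
#' @param n_replicates wells per case (default 3, triplicate).
#' @param f0 baseline fluorescence (a.u.).
#' @param amplitude c(mean, between-sample sd) of the plateau rise, truncated
#'   at 0.
#' @param rate_k c(mean, sd) of the logistic growth rate (1/h), truncated
#'   just above 0.
#' @param t_half c(mean, sd) of the half-rise time (h), normal; ignored when
#'   `t_half_range` is given.
#' @param t_half_range optional c(min, max): draw `t_half` uniformly instead
#'   (used for the negative control, whose spontaneous aggregation falls
#'   beyond the assay cut-off).
#' @param noise_sd per-read noise SD (a.u.).
#' @param pla_count c(mean, sd) of per-sample mean diffuse tau-PLA particle
#'   counts, truncated at 0.
#' @param at8_count c(mean, sd) of per-sample mean perikaryal AT8 particle
#'   counts, truncated at 0.
#' @param inclusion_fraction c(mean, sd) of the fraction of FRET biosensor
#'   cells bearing inclusions after exposure to this group's homogenate,
#'   truncated to `[0, 1]`.
#' @param braak_stage Braak stage recorded on the sample sheet for cases of
#'   this group (reference cases for cut-off derivation are stage `"0"`).
#' @return an object of class `group_preset`.
#' @seealso [default_group_presets()] for the stated study design.
#' @export
group_preset <- function(group, n_samples, n_replicates = 3L,
                         f0 = 100, amplitude = c(900, 200),
                         rate_k = c(0.8, 0.1), t_half = c(20, 4),
                         t_half_range = NULL, noise_sd = 5,
                         pla_count = c(10, 5), at8_count = c(0, 0),
                         inclusion_fraction = c(0, 0),
                         braak_stage = "0") {
  groups <- c("DOUBLE_NEGATIVE", "INTERMEDIATE", "DOUBLE_POSITIVE",
              "NEG_CONTROL", "POS_CONTROL")
  group <- match.arg(group, groups)
  stopifnot(n_samples >= 1, n_replicates >= 1,
            length(amplitude) == 2, length(rate_k) == 2,
            length(t_half) == 2, length(pla_count) == 2,
            length(at8_count) == 2, length(inclusion_fraction) == 2)
  if (amplitude[1] < 0 || pla_count[1] < 0 || at8_count[1] < 0) {
    stop("count and amplitude distribution means must be non-negative")
  }
  structure(
    list(group = group, n_samples = as.integer(n_samples),
         n_replicates = as.integer(n_replicates), f0 = f0,
         amplitude = amplitude, rate_k = rate_k, t_half = t_half,
         t_half_range = t_half_range, noise_sd = noise_sd,
         pla_count = pla_count, at8_count = at8_count,
         inclusion_fraction = inclusion_fraction,
         braak_stage = as.character(braak_stage)),
    class = "group_preset"
  )
}

#' Default cohort presets
#'
#' The stated study design: 6 Double-Negative, 5 Intermediate and 5
#' Double-Positive cases run in triplicate, plus tau-KO negative and
#' aggregated-fragment positive controls. Kinetic means are chosen so the
#' three groups reproduce the qualitative assay pattern: Double-Negative
#' curves barely rise within the 52-h window; Intermediate seeds fastest
#' (shortest half-rise time); Double-Positive is close behind with an
#' overlapping maximum slope. The negative control's spontaneous aggregation
#' half-rise lies in (55, 70) h, beyond the cut-off. Count distributions put
#' Double-Negative well below the >30 tau-PLA / >1 AT8 positivity cut-offs
#' and the positive groups well above, separated by several SDs.
#'
#' @param n_dn,n_int,n_dp group sizes (defaults 6, 5, 5).
#' @param n_neg,n_pos number of control "samples" (default 1 each).
#' @param n_replicates wells per case (default 3).
#' @return named list of [group_preset()] objects.
#' @export
default_group_presets <- function(n_dn = 6L, n_int = 5L, n_dp = 5L,
                                  n_neg = 1L, n_pos = 1L,
                                  n_replicates = 3L) {
  list(
    DOUBLE_NEGATIVE = group_preset(
      "DOUBLE_NEGATIVE", n_samples = n_dn, n_replicates = n_replicates,
      amplitude = c(300, 100), rate_k = c(0.4, 0.05), t_half = c(62, 6),
      noise_sd = 5, pla_count = c(12, 6), at8_count = c(0.2, 0.3),
      inclusion_fraction = c(0.01, 0.01), braak_stage = "0"
    ),
    INTERMEDIATE = group_preset(
      "INTERMEDIATE", n_samples = n_int, n_replicates = n_replicates,
      amplitude = c(1600, 250), rate_k = c(0.8, 0.1), t_half = c(16, 3),
      noise_sd = 5, pla_count = c(120, 30), at8_count = c(0.3, 0.3),
      inclusion_fraction = c(0.15, 0.04), braak_stage = "I"
    ),
    DOUBLE_POSITIVE = group_preset(
      "DOUBLE_POSITIVE", n_samples = n_dp, n_replicates = n_replicates,
      amplitude = c(1500, 250), rate_k = c(0.7, 0.1), t_half = c(22, 4),
      noise_sd = 5, pla_count = c(250, 60), at8_count = c(25, 8),
      inclusion_fraction = c(0.30, 0.06), braak_stage = "IV"
    ),
    NEG_CONTROL = group_preset(
      "NEG_CONTROL", n_samples = n_neg, n_replicates = n_replicates,
      amplitude = c(1000, 200), rate_k = c(2, 0.2),
      t_half_range = c(55, 70), noise_sd = 5,
      pla_count = c(0, 0), at8_count = c(0, 0),
      inclusion_fraction = c(0, 0), braak_stage = "0"
    ),
    POS_CONTROL = group_preset(
      "POS_CONTROL", n_samples = n_pos, n_replicates = n_replicates,
      amplitude = c(2000, 300), rate_k = c(1.5, 0.2), t_half = c(6, 1),
      noise_sd = 5, pla_count = c(0, 0), at8_count = c(0, 0),
      inclusion_fraction = c(0.35, 0.06), braak_stage = "0"
    )
  )
}

# Draw one case's kinetic parameters from a preset (uses the current RNG
# stream; callers wrap in with_seed()).
draw_sample_params <- function(preset) {
  amplitude <- rnorm_lower(1, preset$amplitude[1], preset$amplitude[2], 0)
  rate_k <- rnorm_lower(1, preset$rate_k[1], preset$rate_k[2], 1e-3)
  t_half <- if (!is.null(preset$t_half_range)) {
    stats::runif(1, preset$t_half_range[1], preset$t_half_range[2])
  } else {
    stats::rnorm(1, preset$t_half[1], preset$t_half[2])
  }
  kinetics_params(f0 = preset$f0, amplitude = amplitude, rate_k = rate_k,
                  t_half = t_half, noise_sd = preset$noise_sd)
}
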