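#' Simulate a 96-well seed-amplification plate
#'
#' Draws cases from a list of group presets, gives each case
#' `n_replicates` wells sharing the case's kinetic parameter draw, and
#' samples every well on the 15-min grid with independent read noise. Also
#' draws the per-case particle-count means and FRET inclusion fraction used
#' by the downstream classification and cell-assay stages, so one seed fixes
#' the whole synthetic cohort.
#'
#' Cohort cases are drawn consistently with their group's defining
#' inequalities at the nominal positivity cut-offs (Double-Negative:
#' tau-PLA <= 30 and AT8 <= 1; Intermediate: PLA > 30, AT8 <= 1;
#' Double-Positive: PLA > 30, AT8 > 1), mirroring how cases were selected
#' into the groups in the first place; count draws violating the
#' definition are redrawn. Assay controls contribute wells but carry no
#' histology, so they do not appear on the sample sheet.
#'
#' @param presets list of [group_preset()] objects (see
#'   [default_group_presets()]).
#' @param seed single integer; all randomness flows from it.
#' @param nominal_cutoffs c(pla, at8) cut-offs defining the groups
#'   (default `c(30, 1)`).
#' @return an object of class `sim_plate`: a list with
#'   \describe{
#'     \item{curves}{list of [tht_curve()] objects, one per well;}
#'     \item{data}{long-format data frame (`well`, `sample_id`, `group`,
#'       `dilution`, `time_h`, `fluorescence_au`);}
#'     \item{samples}{per-case sample sheet, cohort cases only
#'       (`sample_id`, `group`, `braak_stage`, `pla_diffuse_mean`,
#'       `at8_perikaryal_mean`, `inclusion_fraction`);}
#'     \item{ground_truth}{per-well data frame of generating parameters
#'       (`f0`, `amplitude`, `rate_k`, `t_half`, `noise_sd`);}
#'     \item{seed}{the seed used.}
#'   }
#' @examples
#' plate <- simulate_plate(default_group_presets(), seed = 7)
#' nrow(plate$samples)  # 16 cases + 2 controls
#' @export
simulate_plate <- function(presets, seed = 1L,
                           nominal_cutoffs = c(pla = 30, at8 = 1)) {
  stopifnot(length(presets) >= 1)
  for (p in presets) stopifnot(inherits(p, "group_preset"))
  n_wells <- sum(vapply(presets, function(p) p$n_samples * p$n_replicates,
                        numeric(1)))
  if (n_wells > 96) {
    stop(sprintf("layout requires %d wells; a plate has 96", n_wells))
  }
  well_ids <- sprintf("%s%02d", rep(LETTERS[1:8], each = 12L), 1:12)

  with_seed(seed, {
    curves <- list()
    gt <- list()
    samp <- list()
    widx <- 0L
    for (p in presets) {
      is_ctrl <- p$group %in% c("NEG_CONTROL", "POS_CONTROL")
      for (i in seq_len(p$n_samples)) {
        sample_id <- sprintf("%s_%02d", abbreviate_group(p$group), i)
        params <- draw_sample_params(p)
        if (!is_ctrl) {
          cnt <- draw_counts_for_group(p, nominal_cutoffs)
          incl <- min(1, rnorm_lower(1, p$inclusion_fraction[1],
                                     p$inclusion_fraction[2], 0))
          samp[[length(samp) + 1L]] <- data.frame(
            sample_id = sample_id, group = p$group,
            braak_stage = p$braak_stage, pla_diffuse_mean = cnt[1],
            at8_perikaryal_mean = cnt[2], inclusion_fraction = incl,
            stringsAsFactors = FALSE
          )
        }
        for (r in seq_len(p$n_replicates)) {
          widx <- widx + 1L
          times <- seq(0, params$duration_h, by = params$read_interval_h)
          f <- logistic_fluorescence(times, params) +
            curve_noise(times, params$noise_sd)
          cur <- tht_curve(times, f, well_id = well_ids[widx],
                           sample_id = sample_id, group = p$group,
                           is_control = p$group %in% c("NEG_CONTROL",
                                                       "POS_CONTROL"))
          attr(cur, "ground_truth") <- list(params = params)
          curves[[length(curves) + 1L]] <- cur
          gt[[length(gt) + 1L]] <- data.frame(
            well = well_ids[widx], sample_id = sample_id, group = p$group,
            f0 = params$f0, amplitude = params$amplitude,
            rate_k = params$rate_k, t_half = params$t_half,
            noise_sd = params$noise_sd, stringsAsFactors = FALSE
          )
        }
      }
    }
    structure(
      list(
        curves = curves,
        data = do.call(rbind, lapply(curves, as.data.frame)),
        samples = if (length(samp)) do.call(rbind, samp) else NULL,
        ground_truth = do.call(rbind, gt),
        seed = as.integer(seed)
      ),
      class = "sim_plate"
    )
  })
}

# Rejection-draw (pla, at8) count means until they satisfy the group's
# defining inequalities at the nominal cut-offs; the groups are defined by
# case selection, so a Double-Negative case with 40 tau-PLA particles is a
# contradiction in terms.
draw_counts_for_group <- function(preset, cutoffs) {
  ok <- function(pla, at8) {
    switch(preset$group,
      DOUBLE_NEGATIVE = pla <= cutoffs[1] && at8 <= cutoffs[2],
      INTERMEDIATE = pla > cutoffs[1] && at8 <= cutoffs[2],
      DOUBLE_POSITIVE = pla > cutoffs[1] && at8 > cutoffs[2],
      TRUE
    )
  }
  for (att in 1:1000) {
    pla <- rnorm_lower(1, preset$pla_count[1], preset$pla_count[2], 0)
    at8 <- rnorm_lower(1, preset$at8_count[1], preset$at8_count[2], 0)
    if (ok(pla, at8)) return(c(pla, at8))
  }
  stop(sprintf(
    "count distributions of preset %s are inconsistent with its group definition",
    preset$group
  ))
}

abbreviate_group <- function(group) {
  switch(group,
    DOUBLE_NEGATIVE = "DN", INTERMEDIATE = "INT", DOUBLE_POSITIVE = "DP",
    NEG_CONTROL = "NC", POS_CONTROL = "PC", group
  )
}

#' @export
print.sim_plate <- function(x, ...) {
  cat(sprintf(
    "<sim_plate> %d wells, %d cases, seed %d\n  groups: %s\n",
    length(x$curves), nrow(x$samples), x$seed,
    paste(sprintf("%s=%d", names(table(x$samples$group)),
                  table(x$samples$group)), collapse = ", ")
  ))
  invisible(x)
}

#' Write / read a plate as long-format CSV
#'
#' Columns `well, sample_id, group, dilution, time_h, fluorescence_au`;
#' UTF-8, '.' decimal separator. Writing is deterministic: the same plate
#' object always produces byte-identical files.
#'
#' @param plate a `sim_plate` or a long-format data frame with the columns
#'   above.
#' @param path output file path.
#' @return `write_plate_csv()` returns `path` invisibly; `read_plate_csv()`
#'   returns a list of [tht_curve()] objects, one per well.
#' @export
write_plate_csv <- function(plate, path) {
  df <- if (inherits(plate, "sim_plate")) plate$data else plate
  need <- c("well", "sample_id", "group", "dilution", "time_h",
            "fluorescence_au")
  if (!all(need %in% names(df))) {
    stop("plate data must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  df$time_h <- formatC(df$time_h, format = "g", digits = 15)
  df$fluorescence_au <- formatC(df$fluorescence_au, format = "g", digits = 15)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "sample_id", "dilution", "time_h", "fluorescence_au")
  if (!all(need %in% names(df))) {
    stop("plate CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (!"group" %in% names(df)) df$group <- NA_character_
  lapply(split(df, df$well), function(d) {
    d <- d[order(d$time_h), ]
    tht_curve(d$time_h, d$fluorescence_au, well_id = d$well[1],
              sample_id = d$sample_id[1], dilution = d$dilution[1],
              group = d$group[1],
              is_control = d$group[1] %in% c("NEG_CONTROL", "POS_CONTROL"))
  })
}
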