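#' Pipeline configuration
#'
#' One document fixing every tunable of an end-to-end cohort run. All
#' defaults equal the assay's stated constants: 52-h cut-off, 5-SD lag
#' threshold, 1.5-3.5 / 12.5-100 um^2 size windows, 99% CI cut-offs,
#' alpha = 0.05.
#'
#' @param presets list of [group_preset()]s (default
#'   [default_group_presets()]).
#' @param assay an [assay_config()].
#' @param windows a [size_windows()].
#' @param thresholds `"derive"` (default: cut-offs from Braak 0 reference
#'   samples) or a [group_thresholds()].
#' @param confidence CI level for threshold derivation.
#' @param seed integer seed for the whole run.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(presets = default_group_presets(),
                            assay = assay_config(),
                            windows = size_windows(),
                            thresholds = "derive",
                            confidence = 0.99,
                            seed = 1L) {
  stopifnot(inherits(assay, "assay_config"), inherits(windows, "size_windows"))
  if (!identical(thresholds, "derive")) {
    stopifnot(inherits(thresholds, "group_thresholds"))
  }
  structure(
    list(presets = presets, assay = assay, windows = windows,
         thresholds = thresholds, confidence = confidence,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# Stable hash of a config for provenance headers: serialize to canonical
# JSON and md5 it.
config_hash <- function(config) {
  flat <- jsonlite::toJSON(
    list(
      presets = lapply(config$presets, unclass),
      assay = unclass(config$assay), windows = unclass(config$windows),
      thresholds = if (identical(config$thresholds, "derive")) "derive" else
        unclass(config$thresholds),
      confidence = config$confidence, seed = config$seed
    ),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(flat), tf)
  unname(tools::md5sum(tf))
}

#' Run the cohort pipeline
#'
#' Chains the full analysis on one synthetic cohort: simulate the plate and
#' sample sheet, classify samples into pathology groups from their particle
#' counts, extract per-well and per-sample kinetic parameters with
#' censoring, and compare the three pathology groups (Bonferroni pairwise,
#' on the assigned labels) for each kinetic parameter. Deterministic given
#' the config's seed; when `output_dir` is given, writes `plate.csv`,
#' `groups.tsv`, `kinetics_wells.tsv`, `kinetics_samples.tsv`, `stats.tsv`
#' and `provenance.json`, each TSV carrying the config hash and seed in a
#' leading comment line.
#'
#' @param config a [pipeline_config()].
#' @param output_dir optional directory for the report bundle.
#' @return list of class `cohort_run`: `plate` (the `sim_plate`),
#'   `classification` (a `cohort_classification`), `kinetics` (list with
#'   `samples` and `wells`), `stats` (named list of `group_comparison`
#'   objects, one per kinetic parameter), `config_hash`, `seed`.
#' @export
run_cohort <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)

  stage <- "simulate"
  result <- tryCatch({
    plate <- simulate_plate(config$presets, seed = config$seed)

    stage <- "classify"
    thr <- if (identical(config$thresholds, "derive")) NULL else
      config$thresholds
    cls <- classify_cohort(plate$samples, thresholds = thr,
                           confidence = config$confidence)
    atyp <- sum(cls$samples$label == "ATYPICAL")
    if (atyp > 0) {
      warning(sprintf("%d sample(s) classified ATYPICAL", atyp))
    }

    stage <- "kinetics"
    kin <- summarize_plate(plate$curves, config$assay)
    ncen <- sum(kin$wells$lag_censored)
    if (ncen > 0) {
      message(sprintf("kinetics: %d well(s) lag-censored at %g h", ncen,
                      config$assay$cutoff_h))
    }

    stage <- "stats"
    # analysis groups = assigned labels; controls are excluded from the
    # three-group comparison
    lab <- cls$samples$label[match(kin$samples$sample_id,
                                   cls$samples$sample_id)]
    keep <- lab %in% c("DOUBLE_NEGATIVE", "INTERMEDIATE", "DOUBLE_POSITIVE")
    stats_out <- NULL
    if (length(unique(lab[keep])) >= 2 &&
        all(table(lab[keep]) >= 2)) {
      stats_out <- lapply(
        c(fmax = "fmax", lag_h = "lag_h", t_fmax_h = "t_fmax_h",
          vmax = "vmax"),
        function(par) {
          anova_oneway_bonferroni(kin$samples[[par]][keep], lab[keep])
        }
      )
    }
    list(plate = plate, classification = cls, kinetics = kin,
         stats = stats_out)
  }, error = function(e) {
    stop(sprintf("cohort pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  run <- structure(
    c(result, list(config_hash = hash, seed = config$seed)),
    class = "cohort_run"
  )
  if (!is.null(output_dir)) write_cohort_bundle(run, config, output_dir)
  run
}

#' @export
print.cohort_run <- function(x, ...) {
  cat(sprintf("<cohort_run> seed %d, config %s\n", x$seed, x$config_hash))
  print(x$classification)
  cat(sprintf("  kinetics: %d wells, %d samples, %d lag-censored wells\n",
              nrow(x$kinetics$wells), nrow(x$kinetics$samples),
              sum(x$kinetics$wells$lag_censored)))
  invisible(x)
}

write_tsv_with_header <- function(df, path, hash, seed) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con, sep = "\n")
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, format = "g",
                                                 digits = 15))
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(df, sep = "\t")))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

write_cohort_bundle <- function(run, config, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- run$config_hash; seed <- run$seed
  write_plate_csv(run$plate, file.path(output_dir, "plate.csv"))
  write_tsv_with_header(run$classification$samples,
                        file.path(output_dir, "groups.tsv"), hash, seed)
  write_tsv_with_header(run$kinetics$wells,
                        file.path(output_dir, "kinetics_wells.tsv"),
                        hash, seed)
  write_tsv_with_header(run$kinetics$samples,
                        file.path(output_dir, "kinetics_samples.tsv"),
                        hash, seed)
  if (!is.null(run$stats)) {
    st <- do.call(rbind, lapply(names(run$stats), function(par) {
      ph <- run$stats[[par]]$posthoc
      cbind(parameter = par, omnibus_F = run$stats[[par]]$omnibus_F,
            omnibus_p = run$stats[[par]]$omnibus_p, ph)
    }))
    write_tsv_with_header(st, file.path(output_dir, "stats.tsv"), hash, seed)
  }
  thr <- run$classification$thresholds
  jsonlite::write_json(
    list(config_hash = hash, seed = seed,
         package_version = as.character(utils::packageVersion("seedquant")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         thresholds = unclass(thr),
         assay = unclass(config$assay)),
    file.path(output_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(output_dir)
}
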