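#' Upper confidence-interval cut-off from reference samples
#'
#' Positivity cut-offs are the upper limit of the two-sided confidence
#' interval `CI = xbar +/- t * sigma / sqrt(n)` computed on pathology-free
#' (Braak stage 0) reference samples, with `t` the two-sided Student
#' quantile at `n - 1` degrees of freedom and `sigma` the sample standard
#' deviation. The AT8 cut-off is additionally rounded up to the nearest
#' whole particle.
#'
#' @param reference_values numeric vector of reference-sample measurements,
#'   `length >= 2`.
#' @param confidence confidence level in (0, 1); default 0.99.
#' @param rounding `"none"` (default) or `"ceil"` (round the upper limit up
#'   to the nearest whole number).
#' @return the cut-off (a single number).
#' @examples
#' ci_upper_cutoff(c(1, 2, 3))            # 7.7301
#' ci_upper_cutoff(c(1, 2, 3), rounding = "ceil")  # 8
#' @export
ci_upper_cutoff <- function(reference_values, confidence = 0.99,
                            rounding = c("none", "ceil")) {
  rounding <- match.arg(rounding)
  x <- as.numeric(reference_values)
  n <- length(x)
  if (n < 2) stop("at least 2 reference values are required (t undefined)")
  if (any(!is.finite(x))) stop("reference values must be finite")
  assert_scalar_num(confidence, "confidence", lower = 0, upper = 1,
                    strict_lower = TRUE)
  if (confidence >= 1) stop("`confidence` must be < 1")
  tq <- stats::qt((1 + confidence) / 2, df = n - 1)
  upper <- mean(x) + tq * stats::sd(x) / sqrt(n)
  if (rounding == "ceil") upper <- ceiling(upper)
  upper
}

#' Positivity thresholds for group assignment
#'
#' @param pla_cutoff diffuse tau-PLA particle-count cut-off (a sample is
#'   PLA-positive when its mean count is strictly greater).
#' @param at8_cutoff perikaryal AT8 particle-count cut-off (strictly
#'   greater = positive).
#' @param confidence confidence level the cut-offs were derived at.
#' @param reference_n number of reference samples used (NA when supplied
#'   explicitly).
#' @return an object of class `group_thresholds`.
#' @export
group_thresholds <- function(pla_cutoff = 30, at8_cutoff = 1,
                             confidence = 0.99, reference_n = NA_integer_) {
  stopifnot(pla_cutoff >= 0, at8_cutoff >= 0)
  structure(
    list(pla_cutoff = pla_cutoff, at8_cutoff = at8_cutoff,
         confidence = confidence, reference_n = reference_n),
    class = "group_thresholds"
  )
}

#' @export
print.group_thresholds <- function(x, ...) {
  cat(sprintf(
    "<group_thresholds> PLA-positive > %g, AT8-positive > %g (%.0f%% CI%s)\n",
    x$pla_cutoff, x$at8_cutoff, 100 * x$confidence,
    if (is.na(x$reference_n)) ", supplied" else
      sprintf(", %d reference samples", x$reference_n)
  ))
  invisible(x)
}

#' Assign one sample to a pathology group
#'
#' Samples are PLA-positive when their mean diffuse tau-PLA count strictly
#' exceeds the PLA cut-off, and AT8-positive when their mean perikaryal AT8
#' count strictly exceeds the AT8 cut-off. (PLA-, AT8-) is Double-Negative,
#' (PLA+, AT8-) Intermediate, (PLA+, AT8+) Double-Positive. The
#' (PLA-, AT8+) cell is not part of the stratification scheme; it is
#' labelled `ATYPICAL` with a warning rather than silently binned.
#'
#' @param pla_diffuse_mean mean diffuse tau-PLA particle count, `>= 0`.
#' @param at8_perikaryal_mean mean perikaryal AT8 particle count, `>= 0`.
#' @param thresholds a [group_thresholds()].
#' @return one of `"DOUBLE_NEGATIVE"`, `"INTERMEDIATE"`,
#'   `"DOUBLE_POSITIVE"`, `"ATYPICAL"`.
#' @export
assign_group <- function(pla_diffuse_mean, at8_perikaryal_mean,
                         thresholds = group_thresholds()) {
  stopifnot(inherits(thresholds, "group_thresholds"),
            pla_diffuse_mean >= 0, at8_perikaryal_mean >= 0)
  pla_pos <- pla_diffuse_mean > thresholds$pla_cutoff
  at8_pos <- at8_perikaryal_mean > thresholds$at8_cutoff
  if (pla_pos && at8_pos) return("DOUBLE_POSITIVE")
  if (pla_pos) return("INTERMEDIATE")
  if (at8_pos) {
    warning("sample is AT8-positive but PLA-negative: labelled ATYPICAL")
    return("ATYPICAL")
  }
  "DOUBLE_NEGATIVE"
}

#' Classify a cohort of samples
#'
#' Derives the positivity cut-offs from the cohort's reference (Braak 0)
#' samples — PLA cut-off unrounded, AT8 cut-off rounded up to the nearest
#' whole number — and assigns every sample a group label. Explicit
#' thresholds bypass derivation.
#'
#' @param samples data frame with columns `sample_id`, `braak_stage`,
#'   `pla_diffuse_mean`, `at8_perikaryal_mean`.
#' @param thresholds optional [group_thresholds()]; when `NULL` (default)
#'   cut-offs are derived from the reference samples.
#' @param reference_stage Braak stage defining the reference set (default
#'   `"0"`).
#' @param confidence confidence level for derivation (default 0.99).
#' @return list of class `cohort_classification`: `samples` (input plus a
#'   `label` column) and `thresholds` (the [group_thresholds()] used).
#' @export
classify_cohort <- function(samples, thresholds = NULL,
                            reference_stage = "0", confidence = 0.99) {
  need <- c("sample_id", "braak_stage", "pla_diffuse_mean",
            "at8_perikaryal_mean")
  if (!all(need %in% names(samples))) {
    stop("`samples` must have columns: ", paste(need, collapse = ", "))
  }
  if (any(samples$pla_diffuse_mean < 0 | samples$at8_perikaryal_mean < 0)) {
    stop("particle-count means must be non-negative")
  }
  if (is.null(thresholds)) {
    ref <- samples[samples$braak_stage == reference_stage, ]
    if (nrow(ref) < 2) {
      stop(sprintf(
        paste0("need >= 2 reference samples at Braak stage %s to derive ",
               "cut-offs (found %d); supply `thresholds` explicitly"),
        reference_stage, nrow(ref)
      ))
    }
    thresholds <- group_thresholds(
      pla_cutoff = ci_upper_cutoff(ref$pla_diffuse_mean, confidence, "none"),
      at8_cutoff = ci_upper_cutoff(ref$at8_perikaryal_mean, confidence,
                                   "ceil"),
      confidence = confidence, reference_n = nrow(ref)
    )
  } else {
    stopifnot(inherits(thresholds, "group_thresholds"))
  }
  samples$label <- vapply(seq_len(nrow(samples)), function(i) {
    assign_group(samples$pla_diffuse_mean[i], samples$at8_perikaryal_mean[i],
                 thresholds)
  }, character(1))
  structure(list(samples = samples, thresholds = thresholds),
            class = "cohort_classification")
}

#' @export
print.cohort_classification <- function(x, ...) {
  print(x$thresholds)
  tab <- table(x$samples$label)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}
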