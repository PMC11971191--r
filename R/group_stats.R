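#' Two-sided Dunnett many-to-one probability
#'
#' Joint probability that all `k` many-to-one comparison statistics stay
#' within `[-q, q]` under the null, for the classical correlation structure
#' `corr(T_i, T_j) = sqrt(lambda_i * lambda_j)` with
#' `lambda_i = n_i / (n_i + n_0)` and a common error estimate on `df`
#' degrees of freedom. Evaluated through the multivariate-t integral
#' (mvtnorm); the quasi-Monte-Carlo evaluation is run under a fixed
#' internal seed so identical inputs give identical probabilities.
#'
#' @param q non-negative quantile.
#' @param df error degrees of freedom.
#' @param n_treat vector of treatment group sizes.
#' @param n_control control group size.
#' @param abseps absolute integration tolerance (default 1e-5).
#' @return `P(max_i |T_i| <= q)`.
#' @keywords internal
#' @export
pdunnett <- function(q, df, n_treat, n_control, abseps = 1e-5) {
  stopifnot(q >= 0, df >= 1, all(n_treat >= 1), n_control >= 1)
  k <- length(n_treat)
  if (k == 1L) {
    return(stats::pt(q, df) - stats::pt(-q, df))
  }
  lam <- n_treat / (n_treat + n_control)
  b <- sqrt(lam)
  corr <- outer(b, b)
  diag(corr) <- 1
  # pmvt's lattice rule consumes R's RNG stream: pin it for determinism
  with_seed(20260918L, {
    as.numeric(mvtnorm::pmvt(
      lower = rep(-q, k), upper = rep(q, k), df = as.integer(round(df)),
      corr = corr, algorithm = mvtnorm::GenzBretz(abseps = abseps,
                                                  maxpts = 100000L)
    ))
  })
}

new_group_comparison <- function(method, omnibus_F, omnibus_p, posthoc,
                                 alpha = 0.05, details = list()) {
  structure(
    list(method = method, omnibus_F = omnibus_F, omnibus_p = omnibus_p,
         posthoc = posthoc, alpha = alpha, details = details),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s\n  omnibus F = %.4g, p = %.4g\n",
              x$method, x$omnibus_F, x$omnibus_p))
  ph <- x$posthoc
  ph$adjusted_p <- signif(ph$adjusted_p, 4)
  ph$estimate <- signif(ph$estimate, 4)
  print(ph[, c("comparison", "estimate", "adjusted_p", "significant")],
        row.names = FALSE)
  invisible(x)
}

check_groups <- function(values, group) {
  if (length(values) != length(group)) {
    stop("`values` and `group` must have the same length")
  }
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]; group <- as.character(group)[keep]
  n <- table(group)
  if (length(n) < 2) stop("at least 2 groups are required")
  if (any(n < 2)) {
    stop("every group needs n >= 2 (violated by: ",
         paste(names(n)[n < 2], collapse = ", "), ")")
  }
  list(values = values, group = group)
}

oneway_fit <- function(values, group) {
  fit <- stats::aov(values ~ factor(group))
  an <- stats::anova(fit)
  list(
    F = an[1, "F value"], p = an[1, "Pr(>F)"],
    mse = an[2, "Mean Sq"], df = an[2, "Df"],
    means = tapply(values, group, mean),
    n = table(group)
  )
}

#' One-way ANOVA with Dunnett's many-to-one post-hoc test
#'
#' Equal-variance one-way ANOVA followed by two-sided Dunnett comparisons of
#' every treatment group against the designated control, with family-wise
#' adjusted p-values from the multivariate-t distribution.
#'
#' @param values numeric response vector.
#' @param group group label per value.
#' @param control_group name of the control group.
#' @param alpha significance level (default 0.05).
#' @return a `group_comparison` object; `$posthoc` has one row per
#'   treatment-vs-control comparison with `estimate` (treatment mean minus
#'   control mean), `t`, `raw_p`, `adjusted_p` and `significant`.
#' @export
anova_oneway_dunnett <- function(values, group, control_group,
                                 alpha = 0.05) {
  g <- check_groups(values, group)
  if (!control_group %in% g$group) {
    stop(sprintf("control group '%s' not present in `group`", control_group))
  }
  fit <- oneway_fit(g$values, g$group)
  treat <- setdiff(names(fit$means), control_group)
  n0 <- as.numeric(fit$n[control_group])
  nt <- as.numeric(fit$n[treat])
  est <- as.numeric(fit$means[treat] - fit$means[control_group])
  se <- sqrt(fit$mse * (1 / nt + 1 / n0))
  tstat <- est / se
  raw <- 2 * stats::pt(-abs(tstat), fit$df)
  adj <- vapply(abs(tstat), function(q) {
    1 - pdunnett(q, fit$df, nt, n0)
  }, numeric(1))
  adj <- pmin(pmax(adj, raw), 1)   # adjusted p can never undercut raw p
  posthoc <- data.frame(
    comparison = paste(treat, "-", control_group),
    estimate = est, t = tstat, raw_p = raw, adjusted_p = adj,
    significant = adj < alpha,
    stringsAsFactors = FALSE
  )
  new_group_comparison("one-way ANOVA + Dunnett vs control",
                       fit$F, fit$p, posthoc, alpha,
                       details = list(df = fit$df, mse = fit$mse,
                                      control = control_group))
}

#' One-way ANOVA with Bonferroni-adjusted pairwise comparisons
#'
#' Equal-variance one-way ANOVA; all pairwise two-sided t comparisons use
#' the pooled ANOVA error, with each p-value multiplied by the number of
#' comparisons (capped at 1).
#'
#' @inheritParams anova_oneway_dunnett
#' @return a `group_comparison` object with one posthoc row per pair.
#' @export
anova_oneway_bonferroni <- function(values, group, alpha = 0.05) {
  g <- check_groups(values, group)
  fit <- oneway_fit(g$values, g$group)
  gs <- names(fit$means)
  pairs <- utils::combn(gs, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    est <- as.numeric(fit$means[a] - fit$means[b])
    se <- sqrt(fit$mse * (1 / fit$n[[a]] + 1 / fit$n[[b]]))
    tstat <- est / se
    raw <- 2 * stats::pt(-abs(tstat), fit$df)
    data.frame(comparison = paste(a, "-", b), estimate = est, t = tstat,
               raw_p = raw, adjusted_p = min(1, m * raw),
               significant = min(1, m * raw) < alpha,
               stringsAsFactors = FALSE)
  })
  new_group_comparison("one-way ANOVA + Bonferroni pairwise",
                       fit$F, fit$p, do.call(rbind, rows), alpha,
                       details = list(df = fit$df, mse = fit$mse,
                                      n_comparisons = m))
}

#' Two-way ANOVA with Dunnett comparisons against a control condition
#'
#' Fits a two-factor ANOVA with interaction on a complete factorial layout
#' and, within each group, compares every condition to the control
#' condition using the pooled residual error and a Dunnett family-wise
#' adjustment over that group's comparisons (the design used when
#' comparing immunodepleted to untreated homogenates within each pathology
#' group).
#'
#' @param values numeric response vector.
#' @param group first factor (e.g. pathology group).
#' @param condition second factor (e.g. pre/post immunodepletion).
#' @param control_condition condition every other condition is compared to.
#' @param alpha significance level.
#' @return a `group_comparison`; the omnibus row reports the condition
#'   main effect, `$details$anova_table` carries the full two-way table.
#' @export
anova_twoway_dunnett <- function(values, group, condition,
                                 control_condition, alpha = 0.05) {
  stopifnot(length(values) == length(group),
            length(values) == length(condition))
  group <- as.character(group); condition <- as.character(condition)
  conds <- unique(condition)
  if (length(conds) < 2) {
    stop("at least 2 conditions are required (nothing to compare)")
  }
  if (!control_condition %in% conds) {
    stop(sprintf("control condition '%s' not present", control_condition))
  }
  cells <- table(group, condition)
  if (any(cells == 0)) {
    stop("incomplete factorial layout: every group x condition cell must ",
         "be observed")
  }
  if (any(cells < 2)) {
    stop("every group x condition cell needs n >= 2")
  }
  fit <- stats::aov(values ~ factor(group) * factor(condition))
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  dfres <- an["Residuals", "Df"]
  cond_row <- grep("condition", rownames(an), fixed = TRUE)[1]
  cmeans <- tapply(values, list(group, condition), mean)
  rows <- list()
  for (gname in rownames(cells)) {
    others <- setdiff(conds, control_condition)
    n0 <- cells[gname, control_condition]
    nt <- as.numeric(cells[gname, others])
    est <- as.numeric(cmeans[gname, others] -
                        cmeans[gname, control_condition])
    se <- sqrt(mse * (1 / nt + 1 / n0))
    tstat <- est / se
    raw <- 2 * stats::pt(-abs(tstat), dfres)
    adj <- vapply(abs(tstat), function(q) 1 - pdunnett(q, dfres, nt, n0),
                  numeric(1))
    adj <- pmin(pmax(adj, raw), 1)
    rows[[gname]] <- data.frame(
      comparison = sprintf("%s: %s - %s", gname, others, control_condition),
      estimate = est, t = tstat, raw_p = raw, adjusted_p = adj,
      significant = adj < alpha, stringsAsFactors = FALSE
    )
  }
  new_group_comparison(
    "two-way ANOVA + Dunnett vs control condition",
    an[cond_row, "F value"], an[cond_row, "Pr(>F)"],
    do.call(rbind, c(rows, list(make.row.names = FALSE))), alpha,
    details = list(anova_table = an, df = dfres, mse = mse,
                   control = control_condition)
  )
}
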