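# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores whatever
#' RNG state existed before the call, so seeded generators never disturb a
#' user's random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Gaussian draws truncated at +/- `trunc` standard deviations: bounded
# detector noise, so a 5-SD threshold rule cannot trip on a flat baseline.
rnorm_trunc <- function(n, mean = 0, sd = 1, trunc = 3) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, 0, 1)
  bad <- abs(x) > trunc
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, 1)
    bad <- abs(x) > trunc
  }
  mean + sd * x
}

# Normal draw truncated below at `lower` (rejection; used for strictly
# non-negative biological quantities such as amplitudes and counts).
rnorm_lower <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(pmax(rep(mean, n), lower))
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lower
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lower
  }
  x
}

# Plate-reader read noise: quasi-periodic shake-cycle flicker (80% of the
# variance, period commensurate with the 15-min read grid, random phase per
# well) plus a 3-SD-truncated Gaussian residual. The baseline window sees
# the flicker's full range, so a "baseline mean + 5 SD" threshold rule has
# a negligible false-trigger rate on flat curves. Uses the current RNG
# stream; callers wrap in with_seed().
curve_noise <- function(times, sd, flicker_fraction = 0.8,
                        flicker_period_h = 1.25) {
  n <- length(times)
  if (sd == 0) return(numeric(n))
  a <- sd * sqrt(2 * flicker_fraction)
  sg <- sd * sqrt(1 - flicker_fraction)
  phi <- stats::runif(1, 0, 2 * pi)
  a * sin(2 * pi * times / flicker_period_h + phi) + rnorm_trunc(n, 0, sg)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
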