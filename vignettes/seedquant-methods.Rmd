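---
title: "seedquant: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seedquant: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedquant)
```

## What the package measures

Tau pathology in Alzheimer-type disease progresses from small, soluble
multimers to the large perikaryal neurofibrillary tangles that define Braak
staging. seedquant implements the quantitative chain used to ask whether the
early multimers — visible as small proximity-ligation (tau-PLA) dots before
any tangle is detectable by AT8 immunohistochemistry — are already
seeding-competent:

1. **Particle quantification** (`segment_particles()`,
   `classify_particles()`): histology images are thresholded, connected
   components are extracted, and particles are classified by area into a
   *diffuse* window (1.5–3.5 µm², dot-like multimeric signal) and a
   *perikaryal* window (12.5–100 µm², tangle-sized lesions). Per-sample
   values are means over three representative fields. `gfap_burden()`
   computes the percentage of a region of interest occupied by
   GFAP-stained astrocyte signal, `100·stain/ROI`.
2. **Stratification** (`ci_upper_cutoff()`, `classify_cohort()`): positivity
   cut-offs are the upper limit of the two-sided 99% confidence interval
   `x̄ ± t·σ/√n` computed on pathology-free (Braak 0) reference samples,
   with `t` at `n−1` degrees of freedom; samples are Double-Negative
   (PLA−/AT8−), Intermediate (PLA+/AT8−) or Double-Positive (PLA+/AT8+),
   with strict `>` positivity.
3. **Seed-amplification kinetics** (`summarize_plate()`): each well's ThT
   fluorescence curve yields `F_max` (maximum fluorescence), the lag time
   (first read strictly above baseline mean + 5 baseline SD), the time to
   maximum fluorescence, and `V_max` (maximum slope). Times that never
   occur within the 52-h assay window are *censored to exactly 52 h* — the
   endpoint-substitution convention — and carried into group statistics at
   that value.
4. **Cell-based seeding** (`fret_field_percent()`): the percentage of
   biosensor cells bearing intracellular inclusions, from a two-channel
   field (cell channel, inclusion channel).
5. **Group statistics** (`anova_oneway_bonferroni()`,
   `anova_oneway_dunnett()`, `anova_twoway_dunnett()`): equal-variance
   ANOVA with either Bonferroni pairwise comparisons or Dunnett
   many-to-one comparisons against a control, at α = 0.05.

## The synthetic world

No raw data are deposited with the study this pipeline addresses, so the
package ships generators that emulate the *measurement structure* with
known ground truth. The generators are first-class, tested code; their
defaults are the stated study design (6/5/5 cases in triplicate, 15-min
reads, 52-h analysis window, controls on-plate).

### Aggregation curves

A well is modelled as a four-parameter logistic,
\[ F(t) = f_0 + \frac{A}{1 + e^{-k (t - t_{1/2})}} + \varepsilon_t , \]
the simplest shape with a lag, growth and plateau phase that admits a
closed-form threshold-crossing time,
\(t_{1/2} - \log(A/(\theta - f_0) - 1)/k\), which is recorded as the
ground-truth lag. Cases drawn from a group preset share one parameter draw
across their replicate wells (a case run in triplicate); wells differ only
by read noise.

**Read noise.** Noise is *not* iid Gaussian. An unbounded iid model makes
the "baseline mean + 5 SD" lag rule fire spuriously on flat curves
(≈0.05% per read — about one false lag per ten 52-h negative-control
wells), and even a 3σ-truncated iid model trips ≈2% of flat wells because
the 10-read baseline SD estimate is occasionally far too small. On the
real instrument the rule is stable, because baseline fluctuation is
dominated by the periodic shake/read cycle rather than white noise. The
generator therefore models read noise as a quasi-periodic flicker at a
period commensurate with the read grid (80% of the noise variance, random
phase per well) plus a 3σ-truncated Gaussian residual. The baseline window
then witnesses the flicker's full range, and the measured false-trigger
rate is ≈7×10⁻⁶ per flat well (Monte Carlo, 3×10⁵ wells).

**Group presets.** The study reports no numeric curve parameters, only the
qualitative pattern, so preset means are the package's own choices, fixed
once: Double-Negative wells barely rise within 52 h (half-rise ≈ 62 ± 6 h,
amplitude ≈ 300), Intermediate seeds fastest (half-rise ≈ 16 ± 3 h,
amplitude ≈ 1600, rate 0.8 h⁻¹), Double-Positive close behind
(22 ± 4 h, 1500, 0.7 h⁻¹) with an overlapping maximum slope; the negative
control's spontaneous aggregation half-rise is uniform in (55, 70) h with a
steep rate, so it never crosses threshold before 52 h; the positive
control rises within hours. Count distributions put Double-Negative well
below the >30 tau-PLA / >1 AT8 cut-offs and the positive groups several
SDs above.

**Selection consistency.** The pathology groups are *defined* by the
cut-offs, so a simulated Double-Negative case with 40 tau-PLA particles
would be a contradiction in terms. Count draws are rejection-sampled until
they satisfy their group's defining inequalities at the nominal cut-offs;
assay controls carry no histology and never appear on the sample sheet.

### Images

Histology fields place perikaryal ellipses (axis ratio 1–2) and diffuse
disks with areas drawn uniformly from their class windows, on a truncated-
Gaussian background. Objects are rasterized to an **exact pixel budget**:
candidate pixels are ranked by elliptical distance from the centre and
exactly `round(area/pixel_area)` are kept (clamped to the window), so the
pixelated area always lies within one pixel-area of the requested area and
never leaves its class window. A dilated occupancy mask enforces a minimum
Chebyshev separation (default 2 px), which guarantees distinct objects can
never merge under 8-connectivity. FRET fields place disk cells the same
way and paint ≥4-px puncta strictly inside exactly
`round(n_cells · fraction)` of them.

## Numerical choices and conventions

- **Baseline window**: the first 10 reads (2.5 h) define the lag
  threshold; the source analysis does not state its window, so it is
  configurable (`assay_config(baseline_n_reads=)`), as is sample-vs-
  population SD (sample, n−1, is the default for small read counts).
- **No interpolation**: the lag is reported at the read time, not a
  sub-interval crossing; 15 min is the instrument's native resolution.
- **Ties for time-to-maximum**: first attainment; a maximum first attained
  on the final retained read is treated as "not yet reached" and censored.
- **V_max estimator**: maximum pairwise finite difference by default
  (window of 2 reads); a least-squares slope over a wider window is
  configurable since no estimator is stated.
- **Dunnett probabilities** come from the multivariate-t integral
  (mvtnorm) with the classical correlation structure
  `√(λ_i λ_j)`, `λ_i = n_i/(n_i+n_0)`; the quasi-Monte-Carlo evaluation
  runs under a pinned internal seed (tolerance 10⁻⁵) so results are
  deterministic. Adjusted p-values are floored at the raw p. Validated
  against p-values frozen from an independent implementation.
- **Two-way design**: comparisons run within each group against the
  control condition, pooling the residual error of the full two-factor
  model; the Dunnett family is the set of comparisons within one group.
- **CI cut-offs**: two-sided t quantile at `(1+confidence)/2` (the "±"
  formula implies a two-sided interval whose upper limit is used); the
  PLA cut-off is not rounded, the AT8 cut-off is rounded up to a whole
  particle. The (PLA−, AT8+) cell is outside the scheme and labelled
  `ATYPICAL` with a warning.
- **Degenerate corners**: Otsu thresholding refuses constant images;
  noise-free curves with `k·t½ ≳ 30` have a baseline rise below double
  precision, making the 5-SD threshold numerically undefined — oracle
  checks therefore draw assay-realistic parameters (half-rise within
  ~28 h), which is also where real seeded curves live.

## What a green test does and does not establish

The synthetic world reproduces the *measurement structure*: sigmoidal
curves with group-dependent lag, triplicate wells sharing a case draw,
countable non-overlapping particles in two size classes, cell fields with
a known flagged fraction, and a cohort whose qualitative group pattern
(higher F_max and shorter lag in Intermediate/Double-Positive versus
Double-Negative; no Intermediate-vs-Double-Positive difference in V_max)
matches the study's. It does **not** emulate overlapping or out-of-focus
particles, chromogen color variation, uneven illumination, dilution-
dependent kinetics, spectral properties of the dye, or cell morphology
beyond disks — so exact-recovery results certify the arithmetic of the
pipeline, not segmentation robustness on real scans. Thresholds for real
images remain the analyst's responsibility (the original ImageJ thresholds
are unrecorded).

## Worked example

```{r example, eval = FALSE}
run <- run_cohort(pipeline_config(seed = 1))
print(run)
run$stats$lag_h
```

## Known limitations

- Touching cells or particles merge under connected-component labelling.
- Censored wells enter group statistics at 52 h (the endpoint
  substitution); whether the original analysis instead excluded them is
  not stated, so `summarize_sample()` reports censoring counts to make
  sensitivity checks easy.
- The semi-quantitative 1–6 visual scale and actual FRET-ratio imaging are
  human/instrument work, out of scope by design.
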