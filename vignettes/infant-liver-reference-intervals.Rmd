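---
title: "Estimating infant liver-biochemistry reference intervals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating infant liver-biochemistry reference intervals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infantri)
library(dplyr)
```

## The problem

A reference interval is the central 95% range — the 2.5th to 97.5th
percentiles — of an analyte in a healthy reference population; a result
outside it flags possible disease. Liver biochemistry in the first
months of life sits systematically above the ranges derived from older
children, and the type of feeding (breastmilk vs formula) shifts several
analytes, so applying adult or childhood cut-offs to infants produces
spurious "elevated" results. `infantri` implements the full estimation
chain needed to derive age- and feeding-stratified intervals from
per-infant laboratory panels: exclusion of acute-phase subjects by CRP,
outlier screening, partition testing, three reference-limit estimators
with 90% confidence intervals, feeding-group comparison, and a
publication-style report.

Because real infant cohorts of this kind are not freely redistributable,
the package also ships a synthetic-cohort generator with the same
statistical structure, so every stage of the pipeline can be exercised,
calibrated and regression-tested end to end.

## Pipeline

1. **CRP exclusion** (`exclude_elevated_crp()`): subjects with CRP
   strictly above 4 mg/L are removed (acute infection). The boundary is
   strict — exactly 4 is kept — because the exclusion is defined with a
   strict inequality. CRP reported below the measuring range (`"<1"`)
   counts as non-elevated whenever its reporting limit does not exceed
   the threshold; a below-range CRP whose limit exceeds the threshold is
   indeterminate and rejected rather than silently kept. How below-range
   CRP interacts with the exclusion is a documented package choice, not
   an empirical fact about any particular laboratory.
2. **Series extraction** (`extract_series()`): one estimation series per
   analyte × age × group, where group is breastfed, not-breastfed, or
   both pooled.
3. **Outlier screening** (`dixon_screen()`), per series.
4. **Method selection and estimation** (`estimate_series()`).
5. **Feeding-group comparison** (`compare_all_feeding()`) and
   **reporting** (`build_report()`).

## Left-censored values

Analyzers report results below the measuring range only as "< LOQ"
(limit of quantitation), e.g. `"<9"` for ALT. The package never imputes
such values (no LOQ/2 substitution). Instead they enter every rank-based
procedure as a tied block at the LOQ, ordered below all observed values:

* a reference limit that resolves at or below the tied block is itself
  reported as "< LOQ";
* the Wilcoxon comparison gives the block a shared bottom mid-rank;
* the censoring *fraction* drives method selection (below).

## The three estimators

**Nonparametric** (`nonparametric_ri()`), for series of more than 120
values. The p-th percentile uses the rank convention `r = p(n + 1)` with
linear interpolation between adjacent order statistics and clamping to
the sample extremes. At least four percentile conventions exist and they
disagree exactly at tail ranks like 2.5%, so the convention is fixed and
documented; it coincides with `quantile(type = 6)`. This choice makes
the estimator unbiased on the probability scale: the expected population
mass below the estimated lower limit is 2.5% by construction
(`E[F(X(k))] = k/(n+1)`), which the calibration below verifies.

**Robust biweight** (`robust_ri()`), for smaller series. The location
`T_bi` is the Tukey biweight: starting from the median, with MAD as the
scale anchor, weights `w_i = (1 - u_i^2)^2` for `|u_i| < 1` (else 0)
with `u_i = (x_i - T)/(c_loc · MAD)`, iterated until
`|ΔT| < 1e-8 · MAD` or 100 iterations. The scale `s_bi` is the biweight
midvariance (Lax/Hoaglin form) centred at `T_bi`. The limits are
`T_bi ± t(0.975, n−1) · s_bi · sqrt(1 + 1/n)`. The tuning constants
(`c_location = 3.7`, `c_scale = 9`, both arguments of `robust_ri()`)
were fixed by the Gaussian-recovery requirement: over 500 replicates of
n = 60 standard-normal samples the mean estimated limits must reproduce
±1.96 within 0.1, which the test suite checks. Several published
variants of the robust procedure differ in exactly these constants; the
recovery property is the arbiter, and the constants stay visible in the
API.

**Direct percentiles** (`direct_percentile_ri()`), when at least half of
a series is below range (threshold exposed as `censoring_fallback`).
With the majority of the distribution unobserved, neither of the above
supports a meaningful confidence interval; the 2.5th/97.5th percentiles
are taken with the same rank convention and **no CIs are reported**.

The size rule reads "more than 120" strictly: n = 121 is the smallest
nonparametric series, n = 120 still estimates robustly.

## Confidence intervals

Both CI-bearing methods use the percentile bootstrap (default 2000
resamples, seeded) of the *whole* estimator — including the biweight
iteration in the robust case. A rank-table CI exists for the
nonparametric limits, but no closed form exists for the robust ones;
one mechanism for both keeps the report uniform. Percentile-bootstrap
intervals for extreme quantiles do not mathematically guarantee
containing the point estimate in every resample configuration, so each
CI is clipped to bracket its point limit; in practice the clip almost
never binds. Calibration (checked by the test suite and recomputed by
`scripts/acceptance.R` via `gaussian_calibration()`): over 1000
simulated Gaussian cohorts of n = 240, the 90% CI for the upper limit
covers the true 97.5th percentile in roughly 88–90% of replicates —
the familiar slight anti-conservatism of the percentile bootstrap at
tail quantiles — and the mean population mass below/above the estimated
limits is 2.5% within ±0.5 points.

## Outlier screening

`dixon_screen()` implements the one-third-of-range rule: after sorting,
delete the maximum when its gap to its neighbour exceeds one third of
the whole range, symmetrically for the minimum, and re-test after every
deletion. Unbounded iteration would eat far into a heavy tail, so
removals are capped at 5% of the original n. A zero-range sample is
left alone, and n < 3 warns (the ratio is undefined) rather than
errors. When both tails fire at once the larger gap ratio goes first
(high tail on an exact tie). Screening runs per estimation series,
after CRP exclusion and before estimation, and the removed counts are
carried into the report footnotes.

## Partitioning and group comparison

`harris_boyd()` tests whether two subgroups need separate intervals:
`z = |m1 − m2| / sqrt(s1²/n1 + s2²/n2)` against the size-scaled
critical value `z* = 3·sqrt(((n1+n2)/2)/120)`, plus the companion rule
flagging sd ratios above 1.5. `partition_test()` applies it across the
panel by feeding group or sex. The package reports the decision; it
does not silently re-stratify.

`compare_feeding_groups()` tests median differences with the two-sided
Wilcoxon rank-sum test (exact enumeration when the smaller group has at
most 10 values and no ties; otherwise normal approximation with tie and
continuity corrections), applying the same outlier screening as the
estimation path so both stages see the same samples. p-values are
reported raw per analyte — the conventional presentation for panel
tables — with optional Holm adjustment (`adjust = "holm"`). Displayed
p-values use two decimals, three below 0.01, and "< 0.001" below that.

## The synthetic cohort generator

`generate_cohort()` draws per-subject records with the structure the
analysis assumes:

* **Analytes are log-normal.** Right-skewed with positive support, and
  determined exactly by a "median (IQR)" summary via
  `fit_lognormal_median_iqr()`: the median fixes `log_median`, the IQR
  ratio fixes `log_sigma = log(q75/q25)/(2·z0.75)`. The default
  parameters (`default_analyte_specs()`) are fit from published-style
  summaries per analyte × age × feeding group (e.g. AST at 3 months,
  all infants, "51 (43–63)" gives `log_sigma ≈ 0.283`).
* **Censored summaries cannot be fit from the summary.** Where a
  quartile or the median itself is below the LOQ (total bilirubin in
  the not-breastfed groups, conjugated bilirubin everywhere), the
  generator refuses a median/IQR fit and the defaults carry explicit
  log-scale parameters instead, anchored on the visible upper quantile:
  `log_sigma = log(q75/median)/z0.75`, with sub-LOQ medians set once to
  1.5 µmol/L (printed "< 2" with q75 = 3) and 1.2 µmol/L (q75 = 2).
* **Left-censoring at the assay LOQ**: draws below the LOQ are stored
  as `"<loq"`. LOQs are 9 U/L (ALT), 7 (GGT), 3 µmol/L (BIL), 2
  (BIL-conj); albumin, AST and ALP get nominal LOQs far below their
  0.1th percentile, so they never censor in practice.
* **CRP contamination**: with probability 42/619 ≈ 6.8% a subject is an
  acute-phase contaminant, uniform on (4, 20] mg/L; the bulk is uniform
  on (0, 4], censored at 1 mg/L. Only exceedance of the threshold
  matters downstream, so the bulk shape is deliberately simple.
* **Group sizes** default to 226/50 (3 months, breastfed/not) and
  175/98 (6 months), with the feeding effect encoded purely through the
  separate per-group parameters, mirroring grouped reporting rather
  than an additive effect model.
* **Determinism**: one master seed, with per-group substreams derived
  from a stable hash of (age, feeding), so adding a group never
  perturbs the records of another.

What the generator does **not** emulate: longitudinal correlation
between a subject's 3- and 6-month samples (no published within-subject
correlation to parameterize it, so pairing is omitted rather than
invented); any sex effect; assay imprecision or drift; and any
departure of the true analyte distributions from log-normality. Passing
recovery tests on synthetic cohorts therefore validates the *machinery*
— ordering, censoring propagation, method routing, calibration — not
the distributional adequacy of log-normality for real sera.

## Numerical choices and degenerate inputs

* Biweight iteration tolerance `1e-8 · MAD`, cap 100 iterations.
* Zero MAD (more than half the series tied, e.g. extreme censoring that
  still routed robustly) degrades to the degenerate interval
  `[median, median]` with a warning instead of an error, so batch runs
  over a full panel always complete.
* Constant series give zero-width limits and zero-width CIs.
* Bootstrap seeds are scoped (`withr::with_seed`) and derived per
  series inside `estimate_reference_intervals()`, so a single pipeline
  seed reproduces the entire table without disturbing the caller's RNG.
* Mixture quantiles for pooled groups (`lognormal_mixture_quantile()`)
  are found by root-finding on the mixture CDF to `1e-10`.

## Known limitations

The robust method assumes an approximately symmetric underlying
distribution: `T_bi ± t·s_bi` cannot track the 97.5th percentile of a
strongly right-skewed distribution, and on log-normal series with
`log_sigma` above roughly 0.3 it systematically underestimates the
upper limit (and overestimates the lower). This is a property of the
method, not of the implementation — the same behaviour would affect any
small-sample series routed to the robust estimator whose data are far
from symmetric. The package intentionally does not transform data
before robust estimation; for skewed small groups the honest options
are a larger reference sample or reporting the direct percentiles. The
end-to-end recovery test in the suite documents exactly this: censored
limits and all nonparametric limits of well-behaved analytes recover
their generating quantiles, while small skewed groups exhibit the
expected robust-method bias.

Problem sizes used in the validation suite — 1000 replicates × n = 240
(nonparametric calibration), 500 × n = 60 (robust recovery), 2000
bootstrap resamples, one full synthetic grid plus 100 seeded
power-replicates — are the package's chosen defaults for a thorough yet
quick desk check.

## A worked run

```{r example, eval = FALSE}
cohort <- generate_cohort(default_cohort_config(seed = 7))
kept <- exclude_elevated_crp(cohort, threshold = 4)
results <- estimate_reference_intervals(cohort, seed = 1)
comparisons <- compare_all_feeding(kept)
report <- build_report(results, comparisons)
report
```

The printed table carries one row per analyte × age × group with
"median (IQR)", "LL (90% CI)" and "UL (90% CI)" cells — censored
entries shown as "< LOQ" — the per-analyte nutrition p-value, and
outlier footnotes.
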