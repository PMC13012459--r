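---
title: "Methods: longitudinal biomarker trajectories, regression to the mean, and polygenic stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal biomarker trajectories, regression to the mean, and polygenic stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

biotraj analyzes longitudinal cohorts from consumer digital-health
platforms: repeated blood-biomarker draws, daily wearable metrics,
genotype dosages, and engagement records. This vignette is the package's
account of the statistical machinery, the choices behind it, and what the
test-suite does and does not demonstrate.

```{r setup}
library(biotraj)
```

## Reference zones and the improvement outcome

Each biomarker value is classified into one of five ordinal zones by four
cut-points `c1 <= c2 < c3 <= c4` resolved per subject stratum (sex, age
interval, optionally ethnicity — the most specific matching stratum wins):

* low `(-Inf, c1)`, normal-low `[c1, c2)`, **optimal** `[c2, c3)`,
  normal-high `[c3, c4)`, high `[c4, Inf)`.

All intervals are lower-inclusive/upper-exclusive. The convention is
arbitrary but must be fixed once: zone counts, improvement percentages and
contingency tables are only reproducible under a stated boundary rule.
One-sided markers (e.g. LDL cholesterol, where no "too low" zone is
defined) set `c1 = c2 = -Inf`, which collapses the below-optimal zones to
empty sets.

Zones carry an ordinal *distance* from optimal (0, 1 or 2). A
baseline-to-follow-up transition counts as **improved** only when the
follow-up distance is strictly smaller than the baseline distance. The
strictness matters for overshoots: a subject moving from `high` to `low`
crossed the optimal zone but ends just as far from it, and calling that an
improvement would contradict what the outcome is meant to capture.
**Optimized** means the follow-up value landed inside the optimal zone;
optimized implies improved for any out-of-optimal baseline (asserted
exhaustively over all 5×5 zone pairs in the tests).

```{r}
spec <- zone_spec(40, 50, 71, 91)
classify_zone(c(45, 95), spec)
score_transition(95, 80, spec)
```

## Cohort preparation

*Inclusion*: a subject enters the longitudinal cohort with two or more
draws at least `min_gap_days = 90` days apart (inclusive). *Pairing*:
baseline is the earliest draw of a marker; the follow-up is the earliest
subsequent draw at least 90 days later. "Earliest qualifying" (rather than
latest) matches the at-least-90-days framing and maximizes the paired n;
it is a genuine free choice and is documented here rather than hidden.

*Outliers*: implausible values are removed with quartile fences
`[Q1 - k·IQR, Q3 + k·IQR]`, `k = 2`, computed **once per marker over the
whole cohort** in a single pass. Per-subject fences would be unstable at
2–5 draws per subject. Quartiles use linear interpolation between order
statistics (`stats::quantile` type 7); the quantile convention changes
which borderline points are removed, so it is pinned. Series with fewer
than four finite values are returned untouched.

*Matched panels*: long-term trajectories are computed on complete-case
subject × draw matrices ("the same users at every draw"), built greedily —
keep the baseline, then each next draw at least 90 days after the last
*retained* draw, until `n_draws` are collected. The 90-day gap is enforced
between every successive retained draw, not only baseline to draw 2; with
per-visit re-testing this is the reading that keeps draw indices
comparable across subjects, and the panel for `n_draws = 2` provably
reduces to the pairing above (tested).

*Wearable windows*: a draw is paired with the mean of each wearable metric
over the 90 days before it (30 days for responder baselines), `[date - w,
date)`, with per-metric coverage counts; zero coverage yields a missing
value, never zero.

## Paired tests

Baseline-to-follow-up change is tested with the two-tailed Wilcoxon
signed-rank test for paired samples. The package implements the statistic
directly: zero differences are dropped, tied absolute differences receive
mid-ranks, and for up to 25 non-zero pairs the p-value comes from the
exact permutation distribution of the positive-rank sum, computed by
convolution over doubled (hence integer) mid-ranks. Beyond 25 pairs a
normal approximation with the standard tie-corrected variance is used,
without continuity correction (the symmetric, simpler choice; at n > 25
the correction moves p-values in the third decimal). The exact branch is
validated against an exhaustive sign-flip enumeration and against
`stats::wilcox.test` on tie-free fixtures. An unpaired Mann-Whitney U
comparator (`mann_whitney_u_test()`) is provided alongside, since both
appear in practice for this contrast; the paired test is primary because
the data are paired.

Improvement summaries with fewer than `min_cohort = 200` out-of-range
pairs are computed but flagged `suppressed`: percentages on small
denominators invite over-reading. Benjamini–Hochberg adjustment is applied
across markers within an analysis family, and raw p-values are always kept
alongside.

## Regression to the mean

Selecting users *because* their baseline is out of range guarantees some
apparent improvement at retest even with no intervention at all. The
package quantifies that component explicitly. With reference-population
baseline mean $\mu$ and test–retest correlation $\rho_{1,2}$ between draws
1 and 2, the expected selection-attributable change for a subject with
baseline $x_1$ is

$$\Delta_{RTM} = (1 - \rho_{1,2})(\mu - x_1),$$

zero under perfect test–retest correlation and the full distance to the
mean under none. The cohort-level contribution is the average of
$\Delta_{RTM}$ over the analysis subcohort.

Two estimation choices matter and are configurable:

* $\mu$ and $\rho_{1,2}$ are estimated on **all** paired users of the
  marker, not only the out-of-range ones. Estimating $\rho$ on a
  tail-selected subcohort attenuates it and inflates the RTM estimate.
* The subcohort averaged over is exactly the cohort reported in the
  longitudinal analysis (the out-of-range users).

The machinery closes against theory: under the stationary Gaussian model
(`x2 = mu + rho (x1 - mu) + noise`) with selection $x_1 > c$, the expected
subcohort mean is the truncated-normal mean
$\mu + \sigma \phi(a)/(1 - \Phi(a))$, $a = (c-\mu)/\sigma$. For
$\mu = 100$, $\sigma = 15$, $\rho = 0.6$, $c = 115$ this gives
$\Delta_{RTM} = -9.15$; the estimator reproduces it, and — decisively —
the *observed* mean change in a zero-effect simulated subcohort equals the
RTM estimate. `closed_form_expectations()` carries these oracles.

```{r}
expected_rtm_individual(150, mu = 100, rho = 0.6)
```

## Polygenic scores

A polygenic score is the sum over variants of effect-allele dose times
GWAS beta. The surrounding contracts:

* Variants missing from the genotyping arrays are substituted by a
  linkage-disequilibrium proxy only when the proxy is itself genotyped and
  $r^2 > 0.8$; the proxy inherits the beta. Anything weaker is dropped and
  reported. Proxy maps are inputs; no LD computation happens here.
* A missing dose skips that variant for that subject (no mean imputation,
  which would require allele frequencies the pipeline does not demand);
  a subject with no scored variants gets a missing score, never zero.
* The GWAS p-value inclusion threshold is chosen from a standard grid
  (5e-8 … 1) by maximizing the absolute Pearson correlation between
  scores and the baseline phenotype, ties toward the more stringent
  threshold (prefer fewer variants when equal).

Scores are stratified at the 10th and 90th percentiles into T1 (lowest
10%), T2, T3 (highest 10%), boundary ties resolved toward the extreme
stratum. The 10/80/10 groups are often loosely called "tertiles" in this
literature; the labels T1–T3 are kept, the usage is nonstandard.
Phenotypic variance explained is the $R^2$ of a simple least-squares
regression of baseline level on score. Change across strata (on
out-of-range-at-baseline users) is tested by one-way ANOVA with pairwise
Welch t-tests; Welch because the stratum sizes are 10/80/10 by
construction and variance homogeneity is not guaranteed.

## Wearable responders and engagement

A **responder** improves by at least one zone toward optimal *or* changes
by ≥ 10% of baseline in the preferential direction (downward for
above-optimal baselines, upward for below-optimal). The percent basis uses
baseline as the denominator and is undefined at $x_1 = 0$, where only the
zone basis applies. Responder/non-responder wearable contrasts are
two-tailed Welch t-tests at the deliberately relaxed α = 0.1 — the
subgroups are small and daily wearable measures noisy, so the type-II risk
is priced in — and all outputs are labelled exploratory. Monthly series
use fixed 30-day blocks from the baseline draw; calendar months would add
edge cases without changing the picture.

Action-Plan engagement is an associational contrast: users with an AP
targeting the focal marker created within the closed `[baseline,
follow-up]` interval, versus users with **no** AP of any kind in that
window; users with APs only for other markers are excluded (they engaged,
just not with this marker, and belong to neither arm). The outcome is the
same strict zone-shift improvement used everywhere else, tested with
Pearson's chi-squared on the 2×2 table *without* continuity correction,
BH-adjusted across markers within each baseline stratum. Expected cells
below 1 flag the row rather than suppressing it.

## The synthetic cohort generator

Every analysis stage is exercised on generated cohorts whose defaults are
the study conditions: 64.2% male; age ~ Normal(47, 12²) truncated to
18–85; the published ethnicity mix; ~38% genotyped; ~35% with wearables;
draw gaps of 200 + U(0, 120) days so the first retest lands near 260 days
after baseline; 72% AP uptake among out-of-range users. Marker blocks
follow the stationary Gaussian model above with test–retest correlations
0.6–0.75 (plausible for these assays; the study does not print them) and
additive intervention effects sized to the observed median shifts (LDL −8
mg/dL, glucose −4 mg/dL, vitamin D +9 ng/mL, …), decaying by half at each
later draw so the largest improvement falls between baseline and first
follow-up. The polygenic block explains h² = 10% of baseline variance of
its linked marker (published trait-level estimates run ~5–13%), with
intervention effects multiplied per true stratum (T1 = 1.5×, T3 = 0.5×) so
low-genetic-risk users improve more. The wearable block gives latent
responders +950 steps/day after baseline on an 8700-step base (daily SD
2500) and 22% vs 18% REM sleep.

One global seed drives everything; per-subject streams are derived
arithmetically from it, so generation is byte-reproducible and adding
subjects never perturbs existing ones (both tested).

What the generator does **not** emulate: real marginal distributions
(several markers are right-skewed; the generator is Gaussian with a floor
at zero), assay batch effects, device heterogeneity in wearables,
missing-at-random vs informative missingness, linkage disequilibrium
between variants, and ancestry structure. Passing tests therefore show
that the estimators recover the parameters of this generative structure —
not that real cohorts satisfy it.

## Numerical and degenerate-input choices

* Dates are ISO-8601 calendar dates; all intervals are whole-day
  differences, and "90 days" is inclusive (`>= 90`).
* Missing numerics are empty cells end-to-end; no sentinel values.
* Duplicate (subject, date, marker) draw rows are rejected, not averaged:
  the resolution rule is unknowable from the data, and guessing silently
  would contaminate pairing.
* Constant series: IQR fences degenerate to the constant and remove
  nothing; correlation-based quantities (ρ, threshold selection, variance
  explained) are flagged degenerate rather than forced.
* All-tied paired samples report p = 1 with a degeneracy flag.
* Degenerate score distributions (all equal) stratify everyone into T1
  with a warning rather than fabricating spread.

## Problem sizes

The test-suite and the acceptance script run everything at desk scale,
chosen to keep Monte-Carlo error well inside each tolerance: RTM closure
at n = 5000 pairs × 10 seeds; heritability recovery at n = 2000 subjects ×
100 variants × 10 seeds (the h² check is on the seed-mean, whose standard
error is ~0.004 against a ±0.03 band); stratum-ANOVA detection over 200
replicates at 100 subjects/stratum; responder power over 200 and
calibration over 500 replicates; end-to-end pipeline demonstrations at
800–2000 subjects. Full-cohort reproduction of the published tables
requires the study's deposited dataset and zone tables as inputs via
`read_cohort_tables()` and `read_zone_table()`.

## Limitations

The pipeline is observational tooling: nothing here supports causal
claims, and the engagement outputs say so. The natural-history comparator
(optimal-at-baseline users) differs at baseline by construction and is
context, not a counterfactual. Zone tables are consumed as data; the
package takes no position on how optimal ranges should be derived.
Proxy-based score portability across ancestries is out of scope, and score
accuracy is expected to degrade away from the reference population the
weights came from.
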