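---
title: "Calling drug response from single-cell mass distributions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling drug response from single-cell mass distributions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(massresponse)
```

## The measurement problem

Functional drug-sensitivity testing measures the effect of a drug directly
on live tumor cells. A suspended microchannel resonator (SMR) weighs single
cells as they flow through a cantilever sensor, producing a few thousand
buoyant-mass values (picograms) per treated condition within hours of
dosing. Cell mass is an integrative phenotype: arrest, metabolic disruption
and death all move the mass distribution before viability markers change.
The statistical task is to decide, per drug condition, whether the treated
mass distribution differs from the vehicle-treated one by more than a
biologically meaningful margin — with samples that are heterogeneous,
contaminated by non-cell particles, and drifting ex vivo.

`massresponse` implements that decision procedure end to end: the
distribution-distance signal, its confidence interval, a bootstrap-t test
against a non-zero null, curation of measurements by particle class, and a
synthetic-experiment simulator used for calibration and validation.

## The mass-response signal

Let $X = (X_1 \le \dots \le X_N)$ be the sorted masses of a drug-treated
sample and $Z$ the sorted masses of the vehicle-treated *reference*
measured at the start of the session. The signal is a normalized Earth
Mover's Distance (Wasserstein-1):

$$\mathrm{MR}(X) \;=\; \frac{\mathrm{EMD}(X, Z)}{\sum_i Z_i}
 \;=\; \frac{\sum_i |X_i - Z_i|}{\sum_i Z_i},$$

the second form holding for equal sample sizes, where the order-statistic
pairing is the optimal 1-D transport plan (the test suite verifies this
against brute-force minimum-cost matching). For unequal sizes the package
integrates the absolute CDF difference over the merged sample support and
scales by $|Z|$, which reduces exactly to the sum form when sizes agree.
Normalizing by the reference mass makes MR unitless and invariant to a
common rescaling of all masses, so signals are comparable across cell types
with very different baseline mass. Two exact identities pin the scale: MR
of a sample against itself is 0, and MR of a uniformly shifted sample
$(1+s)Z$ against $Z$ is exactly $|s|$.

MR is always non-negative; even two independent samples of the same
population sit at a positive noise floor determined by the sample size.
With the default generator (below) that floor is about 3% of the reference
mean at 500 cells per sample and falls below 1.5% (SD below 1%) at 2500
cells, which is why inference uses $N = 2500$ cells per distribution.

## The test: a non-zero null and an embedded bootstrap

A session measures vehicle-treated cells twice — a *reference* $Z$ first
and a *control* $Y$ last — so the control-versus-reference distance
$\mathrm{MR}(Y)$ captures phenotypic drift plus the finite-sample noise
floor. The test statistic is

$$\theta(X, Y, Z) \;=\; \mathrm{MR}(X) - \mathrm{MR}(Y),$$

which may be negative. Because thousands of cells make even trivial
distribution differences statistically detectable, the null is not zero:
we test $H_0: \theta \le \theta_0$ against a *limit of decision*
$\theta_0 = 3\%$, defined as three standard deviations of the distance
between repeated 500-cell subsamples of one population —
`decision_limit()` recomputes it from data, and under the default
generator it lands on 3%.

Non-parametric testing of a non-zero null uses the bootstrap-t
(studentized pivot) construction:

$$t_{\mathrm{obs}} = \frac{\hat\theta - \theta_0}{S}, \qquad
  T^{*} = \frac{\hat\theta^{*} - \hat\theta}{S^{*}},$$

where $S$ is the standard deviation of $\hat\theta$ over $r = 19$ joint
with-replacement resamples of $(X, Y, Z)$, and each of $R = 999$ outer
replicates recomputes $\hat\theta^{*}$ on resampled data together with its
*own* inner-bootstrap standard error $S^{*}$ (again $r = 19$) — the
"embedded" bootstrap. The p-value is

$$p = \frac{1 + \#\{T^{*} \ge t_{\mathrm{obs}}\}}{1 + R},$$

with ties counted as exceedances, so the smallest attainable p-value at
$R = 999$ is exactly 0.001. The test is one-sided by construction; no
two-sided variant is offered. The final call is: *inconclusive* whenever
$\mathrm{MR}(Y) > 10\%$ (drift too high to interpret anything), otherwise
*response* if $p < 0.05$ and *no response* otherwise. The drift rule is
checked before the p-value and cannot be overridden by a strong signal.

Confidence intervals for MR use the bias-corrected and accelerated (BCa)
bootstrap with independent resampling of $X$ and $Z$ (sizes preserved),
$R_{ci} = 5000$ replicates, bias correction from the fraction of
replicates below the point estimate, and acceleration from the skewness of
combined delete-one jackknife values over both samples. A percentile
estimator is available as an alternative. The default level is 90%, with
95% supported through `ci_level`; both levels are in routine use for this
method and the package treats the choice as configuration rather than
resolving it.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `theta0` | 0.03 | fraction | limit of decision (three-sigma 500-cell resampling distance) |
| `alpha` | 0.05 | — | significance level of the one-sided test |
| `N` | 2500 | cells | cells per distribution; larger samples are subsampled once, seeded |
| `R_ci` | 5000 | — | bootstrap replicates for the CI |
| `R_test` | 999 | — | outer replicates of the embedded bootstrap (min p = 1/1000) |
| `r_inner` | 19 | — | inner replicates per standard-error estimate |
| `ci_level` | 0.90 | fraction | CI level (0.95 supported) |
| `drift_limit` | 0.10 | fraction | control drift above which every call is inconclusive |
| `min_n` | 100 | cells | below this, results carry a low-n flag rather than an error |

## Curation

Primary specimens contain debris and cell aggregates that mass alone
cannot distinguish from cells; inline imaging with a classifier labels each
event as intact cell, permeable cell, aggregate or debris. `curate()`
restricts analysis to accepted classes — by default intact *and* permeable
cells, since the intact/permeable split is a viability readout rather than
a quality filter; `curation_policy("intact")` gives the strict variant.
Curation only removes records; masses are never modified.

The benefit is quantified by `sampling_error()`: draw 1000-cell subsets of
a condition repeatedly, compute each subset's MR against the reference,
and report the dispersion (SD) of those values. On contaminated
measurements the per-subset contamination fraction varies, inflating this
dispersion; curation removes that variance component. The classifier
itself is out of scope — curation consumes labels from any source — and
`confusion_spec()` / `apply_confusion()` emulate an imperfect classifier
as a row-stochastic misclassification matrix for testing, with
`precision_recall()` recovering per-class performance.

## The synthetic-experiment generator

The simulator generates what the analysis assumes about SMR data, and is
the package's calibration and validation instrument:

- **Baseline**: intact-cell mass is lognormal with mean 60 pg and CV 0.35,
  plus additive Gaussian measurement noise of SD 0.5 pg (the sensor's mass
  precision), floored at a small positive mass. The lognormal family
  captures the right skew of real mass distributions; the CV is calibrated
  once so that the 500-cell baseline noise of MR sits at the 3% working
  level and the 2500-cell noise below 1.5% (SD below 1%) — the acceptance
  script recomputes all four quantities.
- **Contamination**: permeable cells are intact draws scaled by 0.5;
  aggregates are sums of 2–3 intact draws; debris is lognormal with mean
  8 pg and CV 0.8. Under these defaults the class mean masses are ordered
  aggregate > intact > permeable > debris, matching image-classified
  measurements.
- **Mechanism-of-action effects**: G1/G2 arrest are modeled as a mean
  rescale (0.75 / 1.4) plus CV shrink (0.6), implemented in log space so
  both moments hit their targets exactly — a minimal parameterization of
  distribution consolidation, not a mechanistic cell-cycle model.
  Catabolic/anabolic skews are pure mean scalings (0.90 / 1.10). Membrane
  loss sends an affected fraction (default 0.4) to a secondary mode at
  0.35 times the original mass, relabelled permeable. `uniform_shift` is
  the calibration effect with exactly known MR.
- **Sessions**: `simulate_experiment()` measures the reference at t = 0,
  test conditions at evenly staggered times, and the control at the
  session end (default 3 h). Phenotypic drift is multiplicative and linear
  in time, `mass * (1 - rate * t)`, applied to every particle by its
  measurement time; vehicle conditions never receive a drug effect.
- **Mixtures**: `mix_populations()` draws defined fractions from treated
  and vehicle pools. For the linearity study the responding phenotype is a
  20% uniform shift — the scale of a strong responder in mixing
  experiments — and all fractions are mixed from one treated and one
  vehicle pool against a common reference, as a bench mixing experiment
  would be; MR is then linear in the responding fraction because a uniform
  shift orders the CDFs everywhere.

What the generator does *not* emulate: mechanistic growth or cell-cycle
dynamics, dose–response kinetics, sensor physics beyond additive mass
noise, correlated measurement artifacts within a run, or the morphological
features an image classifier actually sees. Passing tests therefore
demonstrate that the statistics behave as designed under the assumed data
structure — right-skewed baselines, class contamination, multiplicative
effects, linear drift — not that any particular real specimen satisfies
those assumptions.

## Numerical and design choices

- **Resampling unit**: cells within each of $X, Y, Z$ independently,
  preserving each sample's size, for both the test and the CI.
- **Fixed-N subsampling**: samples above `N` are subsampled once, without
  replacement, under a seed derived from the master seed; smaller samples
  are used whole and flagged below `min_n` instead of erroring.
- **Nested RNG streams**: the master seed spawns one substream seed per
  outer replicate, so results are independent of execution order and
  bit-reproducible. The resampling kernels are compiled (Rcpp) and use a
  xoshiro256++ generator seeded per replicate with those substream seeds;
  sorted resamples are produced in O(n) by drawing per-position
  multiplicities rather than sorting draws.
- **Degenerate inner bootstrap**: $S = 0$ for the observed statistic is an
  error naming the zero-variance cause; $S^{*} = 0$ inside an outer
  replicate maps that replicate's $T^{*}$ to $\pm\infty$ by the sign of
  its numerator (0 if the numerator is 0), so it counts as an exceedance
  exactly when its direction says it should.
- **Ties in the p-value**: counted with $\ge$, exactly as the estimator is
  defined.
- **Limit of decision**: subsample pairs are drawn independently with
  replacement by default ("repeatedly sampled" from the population); a
  `disjoint = TRUE` flag draws the two members of each pair jointly
  without replacement for users who prefer disjoint subsets. The two
  conventions agree closely for populations much larger than the subsample.
- **BCa details**: tied bootstrap replicates contribute half their mass to
  the bias-correction fraction, which is clamped away from 0 and 1;
  acceleration uses the combined two-sample jackknife; quantiles use
  type 6. Degenerate bootstrap distributions return the zero-width
  interval at the point estimate, flagged.
- **Multi-instrument replicates** are analyzed per instrument (each with
  its own reference); pooling is the caller's explicit choice by
  concatenating records. Per-figure intervals in routine use of this
  method are per-instrument, and pooling across sensors would mix
  reference distributions.
- **No multiplicity correction** is applied to the per-condition calls; an
  optional, clearly labeled Benjamini–Hochberg column (`bh = TRUE`) is
  available in the report table as metadata.
- **Empty/invalid inputs**: rows with non-positive or non-finite mass are
  rejected at load with counts reported; curation that empties a condition
  names the condition; a control drift above the limit is a *result*
  (inconclusive), never an error.

## Problem sizes used in the test suite

Unit tests run on hundreds of cells with reduced replicate counts; the
whole-method checks use the method's operating conditions where they are
cheap (noise scans and the decision limit at 1000 repetitions; linearity
at 10000 cells per fraction) and scaled-down replicates where they are
not: the error-calibration study runs 200 null and 200 power experiments
at $N = 2500$ with $R = 199$ outer replicates, and the curation study 100
paired seeds. These sizes are the package's own validation design and are
stated here so they can be reproduced exactly.

## Known limitations

- The package analyzes mass tables; it does not parse instrument frequency
  traces or images, and classifier quality is taken as given.
- The limit of decision is a universal 3% default; drug- or
  malignancy-specific limits are configuration, not something the package
  estimates from clinical outcomes.
- MR is a magnitude: direction of mass change is reported only as a hint
  (sign of the mean difference), and the binary call does not grade depth
  of response.
- The bootstrap-t calibration assumes cells are exchangeable within a
  condition; structured within-run artifacts (e.g. slow sensor drift
  inside one measurement) are not modeled.

## A minimal session

```{r example, eval = FALSE}
records <- simulate_experiment(
  simulation_spec(class_weights = c(intact = 0.85, permeable = 0.05,
                                    aggregate = 0.05, debris = 0.05)),
  effects = list(trametinib = moa_effect("g1_arrest"),
                 dmso_extra = NULL),
  n_per_condition = 2500, seed = 11)

manifest <- run_pipeline(records, inference_config(), seed = 42)
manifest$table[, c("condition_id", "test_signal", "theta_hat",
                   "p_value", "call")]
```
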