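---
title: "Scanner-related reliability of brain morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanner-related reliability of brain morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphrel)
library(dplyr)
```

## The problem

Multicentre and longitudinal MRI studies pool structural scans acquired
on different scanners and at different sessions. Automated morphometry
(tissue volumes, the global sulcal index, per-sulcus surface area and
geodesic depth) then carries scanner-related variance on top of the
between-individual variance that cross-sectional comparisons rely on.
When the scanner contribution is large, small disease-related effects
are swamped. `morphrel` quantifies this with two complementary
analyses on a balanced crossed test-retest design in which the same
subjects are scanned twice at every centre:

1. **Fixed-effects ANCOVA**: are the values measured at different
   centres, or at different visits to the same centre, significantly
   different?
2. **Random-effects variance decomposition**: how large is each
   source of variance, and what fraction of the total is *not*
   attributable to centre (or visit)? That fraction is the
   between-centre (between-visit) reliability.

## The crossed random-effects model

For subject $s$, centre $c$, visit $v$ and hemisphere replicate $h$,

$$y_{scvh} = \mu + A_s + B_c + C_v + (AB)_{sc} + (AC)_{sv} + (BC)_{cv}
           + (ABC)_{scv} + \varepsilon_{scvh},$$

with every term an independent zero-mean Gaussian effect with its own
variance $\sigma^2$. The total variance is the sum of all components,
and the reliability associated with a factor is

$$R_{\text{factor}} = \frac{V_{\text{total}} - V_{\text{factor}}}{V_{\text{total}}},$$

where $V_{\text{factor}}$ sums the factor's own component and **every
interaction containing it**: for centre that is
$\sigma^2_{B} + \sigma^2_{AB} + \sigma^2_{BC} + \sigma^2_{ABC}$.
$R = 1$ means the factor contributes nothing; $R = 0$ means it is the
only source. Values are graded poor ($< 0.50$), moderate
($[0.50, 0.70)$), good ($[0.70, 0.90)$) and excellent ($\ge 0.90$).
The intervals are left-closed so that every value in $[0,1]$ receives
exactly one grade; the conventional rule of thumb is ambiguous at the
cut points and this convention is ours.

### Estimation: expected mean squares

For balanced data, `estimate_variance_components()` computes the
classical ANOVA sum of squares of every term by inclusion–exclusion
over cell means and solves the expected-mean-squares (EMS) linear
system of the fully crossed random model. With $n$ replicates per
subject × centre × visit cell,

$$\mathbb{E}(\mathrm{MS}_T) \;=\; \sigma^2_e \;+\;
  \sum_{U \supseteq T} n \prod_{f \notin U} \ell_f \; \sigma^2_U,$$

where $\ell_f$ is the number of levels of factor $f$. Hemisphere
observations serve as within-cell replicates by default, which makes
the three-way interaction estimable; with one observation per cell it
is confounded with residual error and reported as part of `residual`
(and then attributed to neither factor). Method-of-moments solutions
can be negative; raw values are reported for transparency
(`variance_raw`) and clamped to zero in the working estimates before
any reliability is formed — the classical convention. For unbalanced
data the function refuses and points to REML mixed models (`lme4`),
which is out of scope here; the test suite uses REML only as an
independent cross-check of the balanced estimator.

### Covariates in the random model

Whether covariates entered the original random-effects analyses of
this kind is typically undocumented. Our choice: when covariates are
requested, values are first residualized against them with a single
pooled least-squares fit (grand mean added back) and the residualized
values are decomposed. This keeps the variance model
covariate-adjusted and is recorded in the fitted object's metadata
(`$covariates`), so reports always disclose it.

### Per-sulcus analysis

Sulcal surface and depth vary enormously between sulci, so pooling
sulci into one decomposition would let between-sulcus size differences
masquerade as subject variance. `sulcal_reliability_summary()`
therefore estimates components independently per sulcus label and
hemisphere (a subject × centre × visit design with one observation per
cell) and averages reliabilities across sulci with equal weights.
Sulci that no longer support a crossed design are skipped and listed;
sulci analyzed on a reduced subject set are flagged.

## The ANCOVA engine

`f_test_effects()` fits
`value ~ subject + covariates + centre + visit + centre:visit`
by QR least squares and tests centre, visit and centre:visit with
$F = (\Delta SS/\Delta df)/\mathrm{MSE}$ against the full-model
residual. Two sums-of-squares conventions are offered:

* **adjusted** (default): drop-one SS, each effect adjusted for all
  other terms — the Type-III convention. This requires sum-to-zero
  (deviation) factor coding: under treatment coding, dropping a main
  effect while its interaction stays in the model changes meaning with
  the reference level, and the balanced-design equivalence below
  fails. We verified the implementation against `car::Anova(type = 3)`.
* **sequential**: incremental SS in fitting order (subject first, so
  scanner effects are always adjusted for between-individual
  differences).

On balanced designs without covariates the two coincide (the factor
spaces are orthogonal); this equality is asserted in the test suite at
`1e-8` relative. Covariates are mean-centered before entry, which
stabilizes the intercept and leaves all F-tests unchanged. Brain
(cerebral hemisphere) volume is the default covariate for tissue
volumes and GSI; sulcal measures additionally adjust for GSI.

Deliberate limitations, documented rather than hidden: all factors are
treated as fixed in this engine and every F uses the full-model
residual mean square — no quasi-F or Satterthwaite synthesis, so with
truly random large interactions the main-effect tests are
anti-conservative. P-values are never adjusted for multiple testing
and should be read descriptively. Covariate-by-factor interactions are
not modelled.

## Image quality metrics

Bias-field correction quality is assessed on a bias-corrected T1
volume with per-tissue masks (WM, GM, CSF):

* `coefficient_of_variation()` — SD/mean of grey levels within a mask
  (population SD by default; the masks of interest hold thousands of
  voxels, and the choice is configurable). Narrower within-tissue
  distributions mean better correction.
* `detect_peak()` — the mode of the within-mask grey-level
  distribution: histogram over the mask's [1st, 99th] percentile range
  (clipping outlier voxels), 128 bins, 3-bin moving-average smoothing,
  maximal bin center, ties broken toward the lower grey level. All
  knobs are arguments. Note the flat-top effect: for a wide unimodal
  distribution, adjacent bins near the mode differ by less than their
  count noise, so the estimate wanders over a few bins; a
  kernel-density mode would be smoother but is not what this estimator
  is.
* `wm_gm_contrast()` — ratio of the WM peak to the GM peak; higher is
  better-separated tissue intensities, and on T1-like data it exceeds 1.
* `intersect_masks()` — tissue masks from two segmentation methods are
  intersected before comparison to avoid favouring either method.

Metrics are computed over whichever mask is supplied; to follow the
whole-cerebrum convention, supply masks spanning both hemispheres (the
union-mask identity is tested).

## The synthetic generator

`simulate_morphometry()` draws the additive crossed model exactly as
written above, sharing each effect across the design (the centre
effect is identical for all subjects and visits at that centre). Its
defaults are the study conditions the package is designed around: 13
subjects × 3 centres × 2 visits × 2 hemispheres, mirroring a 1.5 T
multicentre cohort (use 11 × 5 × 2 × 2 for the 3 T-style cohort), a
grand mean of 300 (a typical tissue volume in cm³) and Gaussian
effects. One seed governs the whole draw via deterministic per-term
sub-streams, so enlarging one part of the design preserves the other
terms' draws. Fixed per-centre or per-visit shifts can be injected for
power checks, a subject-level covariate with a linear slope can be
added, and sulcal tables draw per-sulcus grand means once
(log-normal, SD 0.4 on the log scale) to emulate the large
between-sulcus size differences of real data. The returned `truth`
record carries the generating components and their analytic
reliabilities, enabling generator/estimator round-trip tests.

What the generator does **not** emulate: non-Gaussian or heavy-tailed
effects, drift within a session, correlated left/right hemispheres
beyond the shared cell effects, and any dependence of variance on the
mean. Passing tests therefore demonstrate correctness of the
estimators under the stated model, not robustness to real scanners'
misbehaviour.

`simulate_phantom()` builds a concentric-ellipsoid head: WM core, GM
shell, CSF outer shell, zero background, on a 64³ grid by default
(voxel counts are exact functions of the geometry, independent of the
seed). Grey levels default to WM/GM/CSF = 150/100/40, Gaussian noise
is added per tissue, and a multiplicative bias field $1 + \alpha
g(x)$ with $g \in [-1, 1]$ can be applied. The default field is a
separable product of per-axis cosine profiles at one full cycle per
axis — a zero-mean, low-frequency modulation. A half-cycle profile
would be nonnegative everywhere and inflate the within-tissue mean
more than its spread, which can *lower* the coefficient of variation;
a zero-mean modulation raises it in every tissue, which is what a real
inhomogeneity does to a histogram. A `radial` profile (coil-like,
increasing outward) is also provided; it inflates the outer GM shell
relative to the WM core and so degrades the apparent WM/GM contrast
toward 1.

```{r phantom-demo}
ph <- simulate_phantom(noise_sd = 5, seed = 1)
image_quality_metrics(ph$volume, ph$masks)
```

## Numerical choices and degenerate inputs

* Negative raw variance components are truncated at zero *after* the
  EMS solve and *before* any reliability; raw values stay visible.
* Zero total variance makes reliability undefined and errors rather
  than returning a conventional value.
* A constant response (zero residual mean square) is a degenerate fit
  and errors; so does a saturated model with no residual df.
* Rank deficiency in the design matrix is detected by QR and reported
  with the aliased columns named.
* Histogram-mode ties break toward the lower grey level; an all-equal
  mask returns that value directly.
* Validation excludes subjects listwise per measure (no imputation),
  mirroring the exclusion of participants without repeated scans at
  all centres.
* Whether hemisphere enters as replicates (default) or as a fixed
  factor is a model option; replicates make the three-way interaction
  estimable and match the pooled-hemisphere presentation of such
  studies.

## Problem sizes in the test suite

The shipped tests run the full pipeline at the study conditions above.
Monte-Carlo checks use 500 replicates of the 13 × 3 × 2 × 2 design for
reliability parameter recovery (tolerance ±0.03 on the mean), 2000
replicates for the type-I calibration of the centre F-test (rejection
rate within 0.05 ± 0.01, plus a Kolmogorov–Smirnov uniformity check of
the null p-values), and 200 replicates for the paired
method-of-moments vs REML comparison. Smaller mirrors of these checks
(40–300 replicates) run in the per-module tests.

## Known limitations

* Method-of-moments estimation requires a balanced, complete crossed
  design; unbalanced data are rejected rather than approximated.
* No confidence intervals on reliabilities (a bootstrap would be the
  natural extension).
* Fixed-effects F-tests against the residual only — see the ANCOVA
  section.
* Reports analyze cohorts fully independently; no cross-cohort
  variance comparison is attempted because cohorts differing in
  subjects, field strength and scanners confound every source at once.
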