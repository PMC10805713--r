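---
title: "Estimating annualized retinal thinning rates from macular thickness maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating annualized retinal thinning rates from macular thickness maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

```{r}
library(retinarate)
library(dplyr)
```

## The problem

Optical coherence tomography (OCT) measures retinal layer thickness with
micrometre precision, and the ganglion cell–inner plexiform layer (GCIPL)
of the macula is a candidate biomarker of neurodegeneration in Parkinson's
disease (PD). Because normal thickness varies widely across people and
devices, single measurements travel poorly between clinics; the *rate* of
thinning within a person is more transferable. `retinarate` implements the
full analysis chain for such a study:

1. **Map geometry** — normalize per-eye scattered thickness samples into
   fovea-centred, right-eye-oriented 200×200 grids over the 6×6 mm macular
   field.
2. **Sectorization** — reduce grids to concentric-ring and quadrant
   features; the headline scalar is the parafoveal GCIPL (**pfGCIPL**),
   the GCIPL mean over the ETDRS annulus of 1–3 mm *diameter*.
3. **Subgrouping** — classify subjects as low/high baseline pfGCIPL using
   the lower-quartile cutoff of an external reference population.
4. **Longitudinal models** — estimate annualized rates of change and their
   clinical associations with subject-level linear mixed models (LMMs).
5. **Synthetic cohort** — a generator that emulates the study's data
   structure with known ground truth, so every stage is testable without
   patient data.

## The statistical model

For outcome $y_{ij}$ of subject $i$ at visit time $t_{ij}$ (years since
baseline),

$$y_{ij} = \beta_0 + \beta_t\, t_{ij} + \beta_a\, \mathrm{age}_i +
\beta_s\, \mathrm{sex}_i + b_i + \varepsilon_{ij}, \qquad
b_i \sim N(0, \sigma_b^2),\ \varepsilon_{ij} \sim N(0, \sigma^2).$$

$\beta_t$ is the **annualized rate** (µm/year for retinal outcomes,
points/year for clinical scores). Cognitive outcomes are additionally
adjusted for years of education; `annualized_rate()` applies this rule
automatically via `cognitive_outcomes()`. Group contrasts enter as
`time × group` interactions (`group_interaction()`), whose coefficient is
the rate difference of the non-reference level; we fix `control` (or the
`high` pfGCIPL subgroup) as reference and print the contrast orientation
with every coefficient, because sign conventions are a classic source of
confusion when comparing against published tables.

Fitting is by REML through `lme4`. Where AICs are compared across
*different random-effects structures* (`compare_random_structures()`),
both models are refitted under ML, since REML likelihoods are not
comparable when the random-effects specification changes. That comparison
is restricted to subjects with at least three visits — with two
observations per subject a random slope is not identifiable — and probes
whether baseline thickness predicts the subsequent rate (a correlated
random intercept and slope) or not.

P-values for fixed effects use the large-sample Wald $z$ approximation by
default; `df_method = "satterthwaite"` switches to Satterthwaite
denominator degrees of freedom via `lmerTest`. At hundreds of subjects the
two agree to the third decimal; for size-calibration simulations (type-I
error of the interaction test) we use the Satterthwaite option, which is
the better-calibrated small-sample choice. Missing data are handled by
available-case likelihood under a missing-at-random assumption;
non-convergence and singular fits are flagged on the returned object.

## Map geometry and sectorization

Raw input is a per-eye table of scattered `(x, y, thickness)` samples.
`interpolate_to_grid()` performs piecewise-linear (barycentric)
interpolation over a Delaunay triangulation of the sample locations —
exact for affine fields, never exceeding the input value range, with nodes
outside the convex hull marked missing. The triangulation comes from
`deldir`; face assembly from its edge list is done in-package (for each
edge and side, the common neighbour maximizing the inscribed angle — the
empty-circumcircle vertex).

The foveal centre is located as the minimum of the Gaussian-smoothed total
retinal thickness map (`locate_fovea()`), refined to sub-node precision by
a local quadratic fit. The smoothing kernel scale is 0.25 mm — small
enough not to displace the pit, large enough to suppress measurement noise
at realistic levels (~3 µm); smoothing is boundary-corrected so constants
are preserved near edges and missing data. Degenerate maps (constant,
minimum on the boundary, non-convex refinement) yield a low-confidence
flag rather than a silent answer. `recenter()` then resamples the grid
about that centre (resampling, rather than coordinate relabeling, keeps
downstream pixel bookkeeping uniform; both views agree to interpolation
tolerance), and `flip_left_eye()` mirrors OS maps into right-eye
orientation.

Coordinates: x increases temporal→nasal in right-eye orientation, y
increases inferior→superior, origin at the fovea, units mm, nodes spanning
the full extent (spacing $6/199$ mm). Sector membership is by node centre
with half-open radial and angular intervals, so concentric rings and their
quadrants partition the nodes exactly — the count-weighted mean of the
four quadrants reproduces the ring mean to machine precision, which the
tests assert. Partial-pixel weighting is deliberately not used: at ~30 µm
node spacing the discretization error of an annulus mean is below 0.5%,
verified against closed-form integrals of radial fields. Angles within
$10^{-9}$ degrees of a quadrant boundary are wrapped consistently so that
diagonal nodes land in exactly one sector (floating-point absorption at
the ±45° diagonals can otherwise drop nodes).

The default concentric scheme is five rings 0.5 mm apart (radii 0–2.5 mm).
Whether such rings should instead be offset to reach the 3 mm field edge
is not determined by the ETDRS convention; we default to 0–2.5 mm with the
innermost sector a disc, and both choices are available through
`concentric_scheme()` / `etdrs_scheme()`. Ring dimensions elsewhere in the
package are *diameters* (ETDRS convention): the pfGCIPL annulus of 1–3 mm
diameter covers radii 0.5–1.5 mm. Features are averaged between eyes when
two eyes are present and passed through unchanged for single eyes
(`average_eyes()`). Peripapillary RNFL (pRNFL) sector values enter the
cohort table as device-computed means (mean + four quadrants); circular
B-scan processing is out of scope.

## Subgrouping

`derive_cutoff()` takes an *external* reference sample of control pfGCIPL
values and returns its 25th percentile under the linear-interpolation
quantile convention (`stats::quantile` type 7); the convention is recorded
in the rule because quantile estimators differ across software. The
pipeline never derives the cutoff from the analysis cohort itself.
Classification (`classify_pfgcipl()`) uses the baseline visit only and is
strict at the boundary: `low` iff baseline pfGCIPL < cutoff. Subjects with
a missing baseline value remain unclassified.

## The synthetic cohort generator

`simulate_cohort()` draws a long-format visit table from a generative law
whose defaults *are* the emulated study conditions:

* **Design**: 156 PD / 72 controls; visit schedules drawn from a template
  library — baseline/1y/2y, baseline/3y/5y, baseline/2y with weights
  0.10/0.20/0.70 plus ~0.1 y jitter — and 32% baseline-only subjects.
  The weights were chosen so followed subjects average 2.3 visits and
  roughly 2.6 years of follow-up; the template times themselves mirror
  the study's stated schedules, whose frequencies are not published.
* **Demographics**: age 64.8 (8.7) years in PD vs 61.4 (7.5) in controls;
  57.7% vs 34.8% female; education 12 (3.5) years.
* **Retinal law**: subject pfGCIPL level and slope deviations are
  bivariate normal (level SD 7.7 µm, slope SD 0.25 µm/y, correlation
  −0.5), measurement noise 1.5 µm. Sex is coded female = 1 (+1 µm); age
  is centred at the pooled mean before its −0.15 µm/year effect is
  applied. The control level mean (94.6 µm) was chosen so that the
  *measured* control law has its analytic lower quartile at ≈89.8 µm —
  the published cutoff scale — and `reference_quartile()` returns that
  analytic value by solving the sex-mixture CDF. The PD mean is 93.0 µm,
  a compromise between a near-null baseline group difference and the
  observed ≈40% low-subgroup share among PD.
* **True slopes** (µm/year): PD high −0.65, PD low −0.39, control high
  −0.29, control low −0.28. A subject's true subgroup is its latent
  (noise-free) baseline relative to the analytic reference quartile.
* **Clinical coupling**: MoCA slopes +0.04 (control), −0.14 (PD high),
  −0.45 (PD low) points/year with subgroup-specific baselines; H&Y is a
  monotone ordinal chain with 0.5-point Poisson increments at rates 0.16
  (high) and 0.06 (low) per year, i.e. linear-scale slopes ≈0.08 and
  0.03; UPDRS-III drifts ≈1.25 points/year in both subgroups.
* **pRNFL coupling**: subject pRNFL levels share variance with pfGCIPL
  levels such that the between-subject regression slope equals the
  configured coupling (0.35 µm/µm), and the within-subject pfGCIPL
  residual is the coupled fraction of the pRNFL fluctuation. The temporal
  sector carries an extra PD-specific decline, emulating preferential
  papillomacular-bundle involvement.

What the generator does **not** emulate: B-scan speckle and segmentation
error, device differences, OSCAR-IB quality exclusions, floor/ceiling
psychometrics beyond simple clamping of MoCA to [0, 30], and practice
effects. Passing recovery tests therefore demonstrates correctness of the
*estimation machinery* under the assumed data-generating law, not
robustness to every artefact of real OCT data.

One behaviour of the full pipeline is worth flagging: subgroups are
classified on the *observed* baseline, which is also the outcome's first
measurement. Selection on a noisy baseline induces regression-to-the-mean
in the subgroup-specific slopes (the low group's estimated rate is pulled
toward zero, the high group's away from it). The synthetic truth makes
this visible; any study using baseline-threshold stratification inherits
it. The qualitative ordering — low subgroup: slower retinal thinning,
faster cognitive decline — is preserved, and that ordering (not the
biased subgroup point estimates) is what the end-to-end test asserts.

`simulate_macular_scan()` provides the imaging counterpart: a GCIPL ring
profile $g(r) = f_0 + a\,r^2(2-r)^2$ (thin at the fovea, peak near 1 mm,
declining outward) scaled so its analytic 1–3 mm-diameter annulus mean
equals the requested pfGCIPL exactly, plus a plateau-with-Gaussian-pit
total-retinal-thickness field whose unique minimum sits at the configured
fovea offset, an odd nasal–temporal asymmetry term (which cannot shift
annulus means), and i.i.d. noise at scattered sample points. The exact
profile shape is immaterial: targets are defined by its closed-form
integrals. The default 8000 sample points keep the piecewise-linear
chord bias of the extracted pfGCIPL below 0.2 µm — at 3000 points the
profile's curvature (≈250 µm/mm² near the peak) already costs ≈0.4 µm.

## Numerical and design choices

* **Grid convention**: 200×200 nodes spanning the field inclusive of the
  edges, spacing `extent/(n-1)`; all geometry metadata travels with the
  `thickness_grid` object.
* **Tie-breaks**: a tied smoothed minimum is resolved toward the field
  centre; the quadratic refinement is clamped to one node spacing and
  rejected (flagged) when not convex.
* **Sector coverage**: means are over non-missing member nodes; sectors
  under 90% coverage are flagged, empty sectors return `NA`.
* **Quantile convention**: type 7, recorded in the rule's provenance.
* **Boundary rule**: value = cutoff classifies as `high`, forced by the
  "below cutoff" definition of the low group.
* **Reference levels**: `control` and `high` are model reference levels;
  every interaction row records `reference` and `contrast`.
* **Estimation**: REML for coefficient reporting, ML for AIC comparisons;
  Wald z p-values by default, Satterthwaite optional; disease-duration
  adjustment is available as an ordinary extra covariate in `fit_lmm()`.
* **Determinism**: all generators take explicit seeds;
  `run_pipeline(seed = )` drives every stage from one seed and logs each
  stage, skipping group comparisons (with a logged reason) when a group
  is empty.

## Problem sizes used in the checks

The test suite favours sizes that make Monte Carlo error small relative
to the asserted tolerances while keeping each simulation to a few
minutes: 100 replicates of the 150 PD / 70 control recovery design for
slope recovery (3 Monte Carlo SEs ≈ 0.03–0.04 µm/year), 1000 replicates
for the size of the interaction test (binomial 95% half-width ≈ 0.014),
50 replicates of a 300-subject three-visit design for random-structure
selection, and 2000 subjects for moment checks on the generator itself.
The acceptance script reports means over comparable replicate counts and
records the `n` used alongside every value.

## Worked example

```{r}
report <- run_pipeline(seed = 1)
report$headline
autoplot(report$rate_map)

# imaging stage on one synthetic eye
scan <- simulate_macular_scan(
  map_config(noise_sd = 2, fovea_offset = c(0.4, -0.3), laterality = "OS"),
  target_pfgcipl = 92, seed = 7
)
trt <- flip_left_eye(interpolate_to_grid(scan, trt))
gcipl <- flip_left_eye(interpolate_to_grid(scan, gcipl))
fovea <- locate_fovea(trt, smoothing = 0.25)
extract_pfgcipl(recenter(gcipl, fovea))
```

## Limitations

* Annualized retinal changes of a few tenths of a µm/year sit below
  single-scan precision; rates are only identified across repeated
  visits, and short, irregular follow-up widens all intervals.
* The low/high dichotomy is a pragmatic answer to sparse follow-up; where
  three or more visits per subject are available,
  `compare_random_structures()` supports modelling the level–rate
  relationship continuously instead.
* Subgroup slope estimates inherit baseline-selection bias (above); treat
  them as descriptive of the stratified design, not as causal rates.
* H&Y is treated with the same linear machinery as the other outcomes
  (matching the analysis being emulated) rather than an ordinal model.
* The generator's clinical trajectories are linear with Gaussian noise;
  floor effects in severe disease are only crudely approximated.
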