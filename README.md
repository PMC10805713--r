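# retinarate

Longitudinal analysis of retinal neurodegeneration from macular OCT
thickness maps, for researchers studying the retina as a biomarker of
Parkinson's disease (PD) and related disorders.

Optical coherence tomography measures the thickness of individual retinal
layers; the macular ganglion cell–inner plexiform layer (GCIPL) thins with
neurodegeneration. Because absolute thickness varies widely between people
and devices, the transferable quantity is the *annualized thinning rate*
within a person. `retinarate` implements the whole chain from raw per-eye
thickness samples to fitted rates:

- **Map geometry** — piecewise-linear interpolation of scattered samples
  onto a fovea-centred 200×200 grid over the 6×6 mm macular field
  (`interpolate_to_grid()`), foveal-pit localization on the smoothed total
  retinal thickness map (`locate_fovea()`), recentring and left-eye
  mirroring (`recenter()`, `flip_left_eye()`), eye averaging
  (`average_eyes()`).
- **Sectorization** — concentric rings 0.5 mm apart, ETDRS rings and
  quadrants (`concentric_scheme()`, `etdrs_scheme()`, `quadrant_split()`,
  `sector_mean()`), and the parafoveal GCIPL scalar — the GCIPL mean over
  the annulus of 1–3 mm diameter (`extract_pfgcipl()`).
- **Subgrouping** — low/high baseline stratification at the lower-quartile
  cutoff of an external reference population (`derive_cutoff()`,
  `classify_pfgcipl()`).
- **Longitudinal models** — linear mixed models with subject random
  effects, fitted with `lme4`:

  `y_ij = β0 + β_t · t_ij + β_age · age_i + β_sex · sex_i + b_i + ε_ij`

  `β_t` is the annualized rate (µm/year); group differences enter as
  `time × group` interactions (`annualized_rate()`,
  `group_interaction()`), random-effects structures are compared by ML
  AIC (`compare_random_structures()`), and concurrent change between two
  outcomes is estimated with `concurrent_change_model()`. Fitted objects
  have broom-style `tidy()`/`glance()` methods.
- **Synthetic cohort** — `simulate_cohort()` and `simulate_macular_scan()`
  generate a PD/control cohort and macular scans with known ground truth
  (correlated subject-level intercepts and slopes, subgroup-specific
  thinning and MoCA/H&Y/UPDRS trajectories, pRNFL coupling), making every
  stage testable without patient data.

## Worked example

```r
library(retinarate)

report <- run_pipeline(seed = 1)
report
#> <retina_report> seed 1: 228 subjects, 439 visits, cutoff 89.23 um
#> headline quantities:
#>                          metric   value
#>                         pd_rate -0.6043
#>                    control_rate -0.0154
#>        rate_ratio_pd_vs_control 39.1491
#>       interaction_pd_vs_control -0.5909
#>                     pd_low_rate -0.3159
#>                    pd_high_rate -0.7058
#>  relative_reduction_low_vs_high 55.2417
#>                   moca_rate_low -0.4104
#>                  moca_rate_high -0.1527
#>     moca_rate_ratio_low_vs_high  2.6880
#>             concurrent_pf_prnfl  0.3684
```

One seeded run simulates a 415-control reference population, derives the
pfGCIPL quartile cutoff (89.23 µm here), simulates the 156 PD / 72 control
cohort, classifies subgroups and fits the model battery. `pd_rate` and
`control_rate` are annualized pfGCIPL rates in µm/year (generating values
−0.65/−0.39 for PD high/low subgroups, ≈−0.29 for controls);
`interaction_pd_vs_control` is their adjusted difference. The low-baseline
PD subgroup shows *slower* retinal thinning (−0.32 vs −0.71 µm/year) but
*faster* cognitive decline (MoCA −0.41 vs −0.15 points/year), and
concurrent pfGCIPL/pRNFL changes couple at ≈0.37 µm/µm. Note the small
72-subject control arm makes single-cohort rate estimates noisy (here the
control draw lands near zero); the acceptance script reports averages over
replicate cohorts.

The imaging stage on one synthetic left eye:

```r
scan <- simulate_macular_scan(
  map_config(noise_sd = 2, fovea_offset = c(0.4, -0.3), laterality = "OS"),
  target_pfgcipl = 92, seed = 7
)
trt   <- flip_left_eye(interpolate_to_grid(scan, trt))
gcipl <- flip_left_eye(interpolate_to_grid(scan, gcipl))
fovea <- locate_fovea(trt, smoothing = 0.25)
fovea
#> # A tibble: 1 × 4
#>        x      y low_confidence reason
#>    <dbl>  <dbl> <lgl>          <chr>
#> 1 -0.399 -0.302 FALSE          <NA>
extract_pfgcipl(recenter(gcipl, fovea))
#> # A tibble: 1 × 3
#>   pfgcipl coverage low_coverage
#>     <dbl>    <dbl> <lgl>
#> 1    91.8        1 FALSE
```

The pit placed at native (0.4, −0.3) mm is recovered at (−0.399, −0.302)
in right-eye orientation (the x axis mirrors for OS), and the extracted
pfGCIPL recovers the 92 µm analytic target to within interpolation
tolerance.

See `vignettes/retinal-thinning-rates.Rmd` for the model, the generator's
assumptions and the package's numerical choices.

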