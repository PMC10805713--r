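#' Configuration of the synthetic longitudinal cohort
#'
#' Defines the generative law of the synthetic PD/control cohort: group
#' sizes, demographics, the visit-schedule library, the subject-level
#' bivariate (intercept, slope) law for parafoveal GCIPL thickness,
#' covariate effects, subgroup-specific true thinning rates, and the coupled
#' clinical and peripapillary RNFL trajectories. Defaults emulate the design
#' of a two-centre longitudinal PD cohort: 156 patients and 72 controls with
#' unequal age and sex, 2-3 visits over 1-5 years drawn from a small library
#' of schedule templates, about 32% baseline-only subjects, a control
#' pfGCIPL law whose lower quartile sits near 89.8 µm, subgroup-dependent
#' thinning rates, and MoCA / H&Y / UPDRS trajectories coupled to the
#' retinal subgroup.
#'
#' @param n_control,n_pd Group sizes.
#' @param visit_templates List of per-subject visit-time vectors in years
#'   (each starting at 0, strictly increasing).
#' @param template_weights Sampling weights of the templates (sum to 1).
#' @param p_baseline_only Probability a subject has only the baseline visit.
#' @param visit_jitter_sd SD (years) of jitter added to follow-up times.
#' @param age_baseline List with `control` and `pd` elements `c(mean, sd)`.
#' @param p_female Named vector: probability of female sex per group.
#' @param education `c(mean, sd)` of education years (shared).
#' @param intercept_mean Named vector (µm): mean baseline pfGCIPL per group.
#' @param intercept_sd Between-subject SD of the pfGCIPL level (µm).
#' @param slope_sd Between-subject SD of the pfGCIPL slope (µm/year).
#' @param intercept_slope_corr Correlation of subject level and slope
#'   deviations, in `[-1, 1]`.
#' @param residual_sd Within-subject measurement noise SD (µm).
#' @param true_slope List with `control` and `pd`, each either a single
#'   slope (µm/year) or `c(high = , low = )` subgroup-specific slopes.
#' @param age_effect µm per year of baseline age (age is centred at the
#'   pooled cohort mean before the effect is applied).
#' @param sex_effect µm for female sex (female coded 1).
#' @param subgroup_percentile Reference percentile defining the low/high
#'   split (default 25: lowest quartile).
#' @param clinical List of clinical-coupling settings: `moca_baseline`
#'   (per group/subgroup `c(mean, sd)`), `moca_slope` (points/year for
#'   `control`, `pd_high`, `pd_low`), `moca_resid`, `hy_rate` (expected
#'   0.5-step H&Y transitions per year for `high`/`low` PD),
#'   `updrs3_baseline`, `updrs3_slope`, `prnfl_coupling` (µm pfGCIPL per µm
#'   pRNFL of concurrent change), `prnfl_noise_sd`.
#' @param prnfl List: `mean`, `sd` (µm) of the subject-level mean pRNFL,
#'   `slope` per group (µm/year), per-quadrant `offsets` and `scales`, and
#'   `temporal_extra` additional temporal-sector slope per group.
#' @param rings List describing the five concentric GCIPL ring features:
#'   `means` (µm), `slope_mult` (per-ring multiplier of the subject pfGCIPL
#'   slope), `level_mult`, `resid_sd`.
#' @param seed Optional integer seed used by [simulate_cohort()].
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(
    n_control = 72,
    n_pd = 156,
    visit_templates = list(c(0, 1, 2), c(0, 3, 5), c(0, 2)),
    template_weights = c(0.10, 0.20, 0.70),
    p_baseline_only = 0.32,
    visit_jitter_sd = 0.1,
    age_baseline = list(control = c(mean = 61.4, sd = 7.5),
                        pd = c(mean = 64.8, sd = 8.7)),
    p_female = c(control = 0.577, pd = 0.348),
    education = c(mean = 12, sd = 3.5),
    intercept_mean = c(control = 94.6, pd = 93.0),
    intercept_sd = 7.7,
    slope_sd = 0.25,
    intercept_slope_corr = -0.5,
    residual_sd = 1.5,
    true_slope = list(control = c(high = -0.29, low = -0.28),
                      pd = c(high = -0.65, low = -0.39)),
    age_effect = -0.15,
    sex_effect = 1.0,
    subgroup_percentile = 25,
    clinical = list(),
    prnfl = list(),
    rings = list(),
    seed = NULL) {
  clinical_default <- list(
    moca_baseline = list(control = c(26.1, 2.4), pd_high = c(24.3, 4.1),
                         pd_low = c(22.0, 4.6)),
    moca_slope = c(control = 0.04, pd_high = -0.14, pd_low = -0.45),
    moca_resid = 1.2,
    hy_start = list(high = c(1.5, 2.0), low = c(2.0, 2.5)),
    hy_start_prob = list(high = c(0.4, 0.6), low = c(0.6, 0.4)),
    hy_rate = c(high = 0.16, low = 0.06),
    updrs3_baseline = list(high = c(23.3, 10.7), low = c(24.7, 12.0)),
    updrs3_slope = c(high = 1.24, low = 1.27),
    updrs3_resid = 3,
    prnfl_coupling = 0.35,
    prnfl_noise_sd = 0.5
  )
  prnfl_default <- list(
    mean = 97, sd = 9,
    slope = c(control = -0.20, pd = -0.46),
    offsets = c(superior = 23, inferior = 26, nasal = -22, temporal = -27),
    scales = c(superior = 1.3, inferior = 1.3, nasal = 0.8, temporal = 0.7),
    sector_resid = 1.5,
    temporal_extra = c(control = 0, pd = -0.49)
  )
  rings_default <- list(
    means = c(50, 95, 90, 75, 65),
    slope_mult = c(0.5, 1, 1, 0.7, 0.5),
    level_mult = 0.9,
    resid_sd = 1.5
  )
  cfg <- list(
    n_control = n_control, n_pd = n_pd,
    visit_templates = visit_templates,
    template_weights = template_weights / sum(template_weights),
    p_baseline_only = p_baseline_only,
    visit_jitter_sd = visit_jitter_sd,
    age_baseline = age_baseline, p_female = p_female, education = education,
    intercept_mean = intercept_mean, intercept_sd = intercept_sd,
    slope_sd = slope_sd, intercept_slope_corr = intercept_slope_corr,
    residual_sd = residual_sd, true_slope = true_slope,
    age_effect = age_effect, sex_effect = sex_effect,
    subgroup_percentile = subgroup_percentile,
    clinical = modifyList(clinical_default, clinical),
    prnfl = modifyList(prnfl_default, prnfl),
    rings = modifyList(rings_default, rings),
    seed = seed
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(paste0("Invalid cohort config: ", msg))
  chk(cfg$n_control >= 0 && cfg$n_pd >= 0, "group sizes must be >= 0.")
  chk(all(vapply(cfg$visit_templates, function(t) {
    t[1] == 0 && all(t >= 0) && all(diff(t) > 0)
  }, logical(1))),
  "visit templates must start at 0 and be strictly increasing.")
  chk(length(cfg$template_weights) == length(cfg$visit_templates) &&
        all(cfg$template_weights >= 0),
      "template weights must be non-negative, one per template.")
  chk(cfg$p_baseline_only >= 0 && cfg$p_baseline_only <= 1,
      "p_baseline_only must be in [0, 1].")
  chk(all(cfg$p_female >= 0 & cfg$p_female <= 1),
      "p_female must be in [0, 1].")
  sds <- c(cfg$intercept_sd, cfg$slope_sd, cfg$residual_sd,
           cfg$visit_jitter_sd, cfg$age_baseline$control["sd"],
           cfg$age_baseline$pd["sd"], cfg$education["sd"])
  chk(all(sds >= 0), "all SDs must be >= 0.")
  chk(abs(cfg$intercept_slope_corr) <= 1,
      "intercept_slope_corr must be in [-1, 1].")
  chk(cfg$subgroup_percentile > 0 && cfg$subgroup_percentile < 100,
      "subgroup_percentile must be in (0, 100).")
  invisible(cfg)
}

# subgroup-specific slope lookup: scalars recycle to both subgroups
slope_for <- function(true_slope, group, subgroup) {
  s <- true_slope[[tolower(group)]]
  if (length(s) == 1) return(unname(s[[1]]))
  unname(s[[subgroup]])
}

#' Analytic reference-population quartile of the control pfGCIPL law
#'
#' The generating law of a measured control baseline pfGCIPL value is a
#' two-component (sex) mixture of normals, each with variance
#' `intercept_sd^2 + (age_effect * age_sd)^2 + residual_sd^2`. This solves
#' the mixture CDF for the configured percentile, giving the cutoff the
#' reference-derivation step should recover up to Monte Carlo error.
#'
#' @param config A [cohort_config()].
#' @param percentile Percentile in (0, 100); defaults to the config's
#'   `subgroup_percentile`.
#' @return The analytic percentile of the control law (µm).
#' @export
reference_quartile <- function(config = cohort_config(), percentile = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  percentile <- percentile %||% config$subgroup_percentile
  p <- percentile / 100
  mu <- unname(config$intercept_mean["control"])
  sig <- sqrt(config$intercept_sd^2 +
                (config$age_effect * config$age_baseline$control[["sd"]])^2 +
                config$residual_sd^2)
  pf <- unname(config$p_female["control"])
  if (sig < 1e-12) {
    # degenerate (noise-free) law: two-point sex mixture
    vals <- c(mu, mu + config$sex_effect)
    probs <- c(1 - pf, pf)
    ord <- order(vals)
    cum <- cumsum(probs[ord])
    return(vals[ord][which(cum >= p - 1e-12)[1]])
  }
  cdf <- function(x) {
    pf * pnorm(x, mu + config$sex_effect, sig) + (1 - pf) * pnorm(x, mu, sig)
  }
  uniroot(function(x) cdf(x) - p,
          interval = mu + config$sex_effect * pf + c(-10, 10) * sig,
          tol = 1e-10)$root
}
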