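#' Simulate a longitudinal PD/control cohort
#'
#' Generates a long-format visit table with the statistical structure the
#' longitudinal analysis assumes: subject-level correlated random intercepts
#' and slopes on parafoveal GCIPL thickness, group- and subgroup-specific
#' mean thinning rates, covariate (age, sex) effects, irregular visit
#' schedules with a baseline-only fraction, coupled MoCA / H&Y / UPDRS
#' trajectories, concentric GCIPL ring features, and pRNFL sector values
#' whose within-subject fluctuations are coupled to pfGCIPL change.
#'
#' The per-subject ground truth (true level, slope and subgroup) is attached
#' as the `truth` attribute (see [cohort_truth()]) so parameter-recovery
#' checks can compare estimates against the generating values.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed; defaults to `config$seed`.
#' @return Tibble with one row per subject-visit. Key columns:
#'   `subject_id`, `group` (factor control/PD), `visit`, `visit_time`
#'   (years), `age_baseline`, `sex`, `education`, `pfgcipl`,
#'   `gcipl_ring1`..`gcipl_ring5`, `prnfl_mean`, `prnfl_superior`,
#'   `prnfl_inferior`, `prnfl_nasal`, `prnfl_temporal`, `moca`, `hy`,
#'   `updrs_i`..`updrs_iv`, `ledd`, `lcva`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- seed %||% config$seed
  if (is.null(seed)) generate_cohort(config) else {
    with_seed(as.integer(seed), generate_cohort(config))
  }
}

#' Ground truth of a simulated cohort
#'
#' @param cohort A tibble from [simulate_cohort()].
#' @return Tibble with one row per subject: `subject_id`, `group`,
#'   `subgroup_true`, `intercept_true` (latent baseline pfGCIPL, µm),
#'   `slope_true` (µm/year), `prnfl_level`, `moca_slope_true`, `template`.
#' @export
cohort_truth <- function(cohort) {
  tr <- attr(cohort, "truth")
  if (is.null(tr)) abort("`cohort` carries no ground-truth attribute.")
  tr
}

generate_cohort <- function(cfg) {
  n <- cfg$n_control + cfg$n_pd
  if (n == 0) abort("Empty cohort: both group sizes are zero.")
  group <- factor(rep(c("control", "PD"), c(cfg$n_control, cfg$n_pd)),
                  levels = c("control", "PD"))
  gkey <- ifelse(group == "PD", "pd", "control")
  subject_id <- sprintf("S%03d", seq_len(n))

  age <- rnorm(n,
               mean = vapply(gkey, function(g) cfg$age_baseline[[g]][["mean"]], 0),
               sd = vapply(gkey, function(g) cfg$age_baseline[[g]][["sd"]], 0))
  female <- rbinom(n, 1, unname(cfg$p_female[gkey]))
  sex <- factor(ifelse(female == 1, "female", "male"),
                levels = c("male", "female"))
  education <- pmin(pmax(rnorm(n, cfg$education[["mean"]],
                               cfg$education[["sd"]]), 5), 20)
  age_c <- age - mean(age)  # centred at the pooled mean

  # correlated subject-level (level, slope) deviations
  z1 <- rnorm(n); z2 <- rnorm(n)
  rho <- cfg$intercept_slope_corr
  d <- cfg$intercept_sd * z1
  s_dev <- cfg$slope_sd * (rho * z1 + sqrt(1 - rho^2) * z2)

  # latent baseline pfGCIPL and true subgroup vs the analytic control cutoff
  mu_g <- unname(cfg$intercept_mean[gkey])
  pf0 <- mu_g + d + cfg$age_effect * age_c + cfg$sex_effect * female
  cutoff <- reference_quartile(cfg)
  subgroup_true <- factor(ifelse(pf0 < cutoff, "low", "high"),
                          levels = c("high", "low"))
  slope <- vapply(seq_len(n), function(i) {
    slope_for(cfg$true_slope, gkey[i], as.character(subgroup_true[i]))
  }, 0) + s_dev

  # subject-level mean pRNFL, sharing level variation with pfGCIPL so the
  # between-subject regression of pfGCIPL on pRNFL has slope = coupling
  coupling <- cfg$clinical$prnfl_coupling
  var_b <- cfg$prnfl$sd^2
  c_lvl <- if (cfg$intercept_sd > 0) coupling * var_b / cfg$intercept_sd^2 else 0
  var_eb <- max(var_b - c_lvl^2 * cfg$intercept_sd^2, 0)
  b_lvl <- cfg$prnfl$mean + c_lvl * d + rnorm(n, 0, sqrt(var_eb))

  # visit schedules
  tmpl_idx <- sample.int(length(cfg$visit_templates), n, replace = TRUE,
                         prob = cfg$template_weights)
  baseline_only <- rbinom(n, 1, cfg$p_baseline_only) == 1
  times <- lapply(seq_len(n), function(i) {
    if (baseline_only[i]) return(0)
    t <- cfg$visit_templates[[tmpl_idx[i]]]
    if (cfg$visit_jitter_sd > 0 && length(t) > 1) {
      foll <- sort(pmax(t[-1] + rnorm(length(t) - 1, 0, cfg$visit_jitter_sd),
                        0.25))
      # enforce strictly increasing times with a minimal 0.05 y gap
      foll <- Reduce(function(a, b) max(b, a + 0.05), foll, accumulate = TRUE)
      t <- c(0, foll)
    }
    t
  })
  nv <- lengths(times)
  row_subj <- rep(seq_len(n), nv)
  t_ij <- unlist(times)
  visit <- unlist(lapply(nv, seq_len))
  m <- length(t_ij)

  cl <- cfg$clinical
  # shared within-subject fluctuation: enters pfGCIPL as its residual and
  # pRNFL scaled by 1/coupling, making concurrent changes couple at `coupling`
  omega <- rnorm(m, 0, cfg$residual_sd)
  pfgcipl <- pf0[row_subj] + slope[row_subj] * t_ij + omega
  prnfl_fluct <- if (coupling != 0) omega / coupling else rnorm(m, 0, 2)
  prnfl_mean <- b_lvl[row_subj] +
    unname(cfg$prnfl$slope[gkey[row_subj]]) * t_ij +
    prnfl_fluct + rnorm(m, 0, cl$prnfl_noise_sd)

  sector <- function(nm) {
    val <- cfg$prnfl$offsets[[nm]] + cfg$prnfl$mean +
      cfg$prnfl$scales[[nm]] * (prnfl_mean - cfg$prnfl$mean) +
      rnorm(m, 0, cfg$prnfl$sector_resid)
    if (nm == "temporal") {
      val <- val + unname(cfg$prnfl$temporal_extra[gkey[row_subj]]) * t_ij
    }
    val
  }

  rings <- lapply(1:5, function(k) {
    cfg$rings$means[k] + cfg$rings$level_mult * d[row_subj] +
      cfg$rings$slope_mult[k] * slope[row_subj] * t_ij +
      cfg$age_effect * age_c[row_subj] + cfg$sex_effect * female[row_subj] +
      rnorm(m, 0, cfg$rings$resid_sd)
  })

  # clinical trajectories
  clin_key <- ifelse(group == "control", "control",
                     paste0("pd_", as.character(subgroup_true)))
  moca_mu <- vapply(clin_key, function(k) cl$moca_baseline[[k]][1], 0)
  moca_sd <- vapply(clin_key, function(k) cl$moca_baseline[[k]][2], 0)
  moca0 <- rnorm(n, moca_mu, moca_sd)
  moca_slope <- unname(cl$moca_slope[clin_key])
  moca <- pmin(pmax(moca0[row_subj] + moca_slope[row_subj] * t_ij +
                      rnorm(m, 0, cl$moca_resid), 0), 30)

  is_pd <- group == "PD"
  sg <- as.character(subgroup_true)
  hy0 <- rep(NA_real_, n)
  hy0[is_pd] <- vapply(which(is_pd), function(i) {
    sample(cl$hy_start[[sg[i]]], 1, prob = cl$hy_start_prob[[sg[i]]])
  }, 0)
  # monotone non-decreasing ordinal chain: 0.5-step Poisson increments
  hy <- rep(NA_real_, m)
  for (i in which(is_pd)) {
    rows <- which(row_subj == i)
    t_prev <- 0; level <- hy0[i]
    for (r in rows) {
      dt <- t_ij[r] - t_prev
      if (dt > 0) level <- level + 0.5 * rpois(1, cl$hy_rate[[sg[i]]] * dt)
      hy[r] <- min(level, 5)
      t_prev <- t_ij[r]
    }
  }

  u3_mu <- vapply(sg, function(k) cl$updrs3_baseline[[k]][1], 0)
  u3_sd <- vapply(sg, function(k) cl$updrs3_baseline[[k]][2], 0)
  u30 <- pmax(rnorm(n, u3_mu, u3_sd), 0)
  updrs_iii <- ifelse(is_pd[row_subj],
                      pmax(u30[row_subj] +
                             unname(cl$updrs3_slope[sg[row_subj]]) * t_ij +
                             rnorm(m, 0, cl$updrs3_resid), 0),
                      NA_real_)
  u10 <- pmax(rnorm(n, 2.0, 1.7), 0)
  u20 <- pmax(rnorm(n, 9.7, 5.7), 0)
  u40 <- pmax(rnorm(n, 3.3, 3.3), 0)
  ledd0 <- pmax(rnorm(n, 607.6, 353.2), 0)
  lcva_mu <- ifelse(group == "control", 38.9,
                    ifelse(sg == "high", 30.2, 25.8))
  lcva0 <- rnorm(n, lcva_mu, 7)

  out <- tibble(
    subject_id = subject_id[row_subj],
    group = group[row_subj],
    visit = visit,
    visit_time = t_ij,
    age_baseline = age[row_subj],
    sex = sex[row_subj],
    education = education[row_subj],
    pfgcipl = pfgcipl,
    gcipl_ring1 = rings[[1]], gcipl_ring2 = rings[[2]],
    gcipl_ring3 = rings[[3]], gcipl_ring4 = rings[[4]],
    gcipl_ring5 = rings[[5]],
    prnfl_mean = prnfl_mean,
    prnfl_superior = sector("superior"),
    prnfl_inferior = sector("inferior"),
    prnfl_nasal = sector("nasal"),
    prnfl_temporal = sector("temporal"),
    moca = moca,
    hy = hy,
    updrs_i = ifelse(is_pd[row_subj],
                     pmax(u10[row_subj] + 0.1 * t_ij, 0), NA_real_),
    updrs_ii = ifelse(is_pd[row_subj],
                      pmax(u20[row_subj] + 0.3 * t_ij, 0), NA_real_),
    updrs_iii = updrs_iii,
    updrs_iv = ifelse(is_pd[row_subj], u40[row_subj], NA_real_),
    ledd = ifelse(is_pd[row_subj],
                  pmax(ledd0[row_subj] + 30 * t_ij, 0), NA_real_),
    lcva = ifelse(is_pd[row_subj], lcva0[row_subj] - 0.3 * t_ij,
                  lcva0[row_subj])
  )
  attr(out, "truth") <- tibble(
    subject_id = subject_id,
    group = group,
    subgroup_true = subgroup_true,
    intercept_true = pf0,
    slope_true = slope,
    prnfl_level = b_lvl,
    moca_slope_true = moca_slope,
    template = ifelse(baseline_only, 0L, tmpl_idx)
  )
  attr(out, "cutoff_analytic") <- cutoff
  attr(out, "config") <- cfg
  out
}

#' Simulate a reference control population of measured baseline pfGCIPL
#'
#' Draws independent single-visit pfGCIPL measurements from the control
#' generating law (level deviation + centred-age and sex effects +
#' measurement noise), as used to derive the subgroup cutoff.
#'
#' @param n Reference sample size (default 415).
#' @param config A [cohort_config()].
#' @param seed Optional integer seed.
#' @return Tibble with columns `pfgcipl` (µm), `age`, `sex`.
#' @export
simulate_reference <- function(n = 415, config = cohort_config(),
                               seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  run <- function() {
    age <- rnorm(n, config$age_baseline$control[["mean"]],
                 config$age_baseline$control[["sd"]])
    female <- rbinom(n, 1, unname(config$p_female["control"]))
    value <- unname(config$intercept_mean["control"]) +
      rnorm(n, 0, config$intercept_sd) +
      config$age_effect * (age - mean(age)) +
      config$sex_effect * female +
      rnorm(n, 0, config$residual_sd)
    tibble(
      pfgcipl = value, age = age,
      sex = factor(ifelse(female == 1, "female", "male"),
                   levels = c("male", "female"))
    )
  }
  if (is.null(seed)) run() else with_seed(as.integer(seed), run())
}

#' Write a simulated cohort as CSV with a JSON ground-truth sidecar
#'
#' @param cohort Tibble from [simulate_cohort()].
#' @param path CSV file path; the truth sidecar is written to
#'   `paste0(path, ".truth.json")`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  tr <- attr(cohort, "truth")
  if (!is.null(tr)) {
    jsonlite::write_json(as.data.frame(tr), paste0(path, ".truth.json"),
                         digits = NA)
  }
  invisible(path)
}
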