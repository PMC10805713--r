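#' Cognitive outcome columns
#'
#' Outcomes for which models are additionally adjusted for years of
#' education.
#'
#' @return Character vector of column names.
#' @export
cognitive_outcomes <- function() {
  c("moca", "blov", "spct", "sdmt", "tmt_a", "tmt_b", "wcst")
}

rate_adjusters <- function(outcome, adjust, cognitive, data) {
  cognitive <- cognitive %||% (outcome %in% cognitive_outcomes())
  if (cognitive && "education" %in% names(data)) {
    adjust <- union(adjust, "education")
  }
  adjust
}

assert_followup <- function(data, outcome, label = "subset") {
  ok <- data |>
    filter(!is.na(.data[[outcome]])) |>
    count(.data$subject_id) |>
    filter(.data$n >= 2)
  if (!nrow(data)) abort(sprintf("Empty %s: no rows.", label))
  if (!nrow(ok)) {
    abort(sprintf(
      "No follow-up visits with non-missing `%s` in %s.", outcome, label
    ))
  }
  invisible(TRUE)
}

#' Annualized rate of change of an outcome
#'
#' Estimates the annualized rate (the fixed-effect coefficient of years
#' since baseline) from a subject-random-intercept linear mixed model
#' adjusted for age at baseline and sex, fitted separately within each
#' level of `by` (e.g. per group, or per pfGCIPL subgroup). Cognitive
#' outcomes are additionally adjusted for years of education.
#'
#' @param data Long-format visit tibble.
#' @param outcome Outcome column name.
#' @param by Optional grouping column; when given, one model per level.
#' @param adjust Baseline covariates (default age at baseline and sex).
#' @param cognitive Force/disable education adjustment; default: `TRUE`
#'   for outcomes in [cognitive_outcomes()].
#' @param time Time column (years since baseline).
#' @param ... Passed to [fit_lmm()] (e.g. `df_method`).
#' @return Tibble with one row per `by` level: the level, `beta_time`
#'   (outcome units per year), `se`, `p_value`, `n_obs`, `n_subjects`,
#'   `converged`, `singular`.
#' @export
annualized_rate <- function(data, outcome, by = NULL,
                            adjust = c("age_baseline", "sex"),
                            cognitive = NULL, time = "visit_time", ...) {
  adjust <- rate_adjusters(outcome, adjust, cognitive, data)
  one <- function(d, label) {
    assert_followup(d, outcome, label = label)
    fit <- fit_lmm(d, outcome, fixed = c(time, adjust),
                   random = "intercept", time = time, ...)
    row <- filter(tidy(fit), .data$term == time)
    tibble(
      beta_time = row$estimate, se = row$std_error, p_value = row$p_value,
      n_obs = fit$n_obs, n_subjects = fit$n_subjects,
      converged = fit$converged, singular = fit$singular
    )
  }
  if (is.null(by)) {
    return(mutate(one(data, "data"), outcome = outcome, .before = 1))
  }
  if (!by %in% names(data)) abort(sprintf("`by` column `%s` not found.", by))
  levels_present <- data |>
    filter(!is.na(.data[[by]])) |>
    pull(.data[[by]])
  levels_present <- if (is.factor(levels_present)) {
    intersect(levels(levels_present), unique(as.character(levels_present)))
  } else {
    unique(as.character(levels_present))
  }
  out <- map(levels_present, function(lv) {
    d <- filter(data, as.character(.data[[by]]) == lv)
    mutate(one(d, sprintf("%s = %s", by, lv)), "{by}" := lv, .before = 1)
  })
  mutate(bind_rows(out), outcome = outcome, .before = 1)
}

#' Time-by-group interaction: difference in annualized rates
#'
#' Fits the joint mixed model with main effects of time and group, their
#' interaction, and the baseline adjusters, and returns the interaction
#' coefficient: the difference in annualized rate between the non-reference
#' and reference level. By convention the reference level is `control`
#' (for group) or `high` (for the pfGCIPL subgroup) when present; the
#' contrast orientation is recorded with the coefficient to avoid sign
#' ambiguity.
#'
#' @param data Long-format visit tibble.
#' @param outcome Outcome column name.
#' @param grouping Grouping column (default `group`).
#' @param ref Reference level; default `"control"`/`"high"` when present,
#'   else the factor's first level.
#' @param adjust,cognitive,time,... As in [annualized_rate()].
#' @return One-row tibble: `outcome`, `term`, `estimate` (units/year),
#'   `se`, `p_value`, `reference`, `contrast`, `n_obs`, `n_subjects`,
#'   `converged`, `singular`.
#' @export
group_interaction <- function(data, outcome, grouping = "group", ref = NULL,
                              adjust = c("age_baseline", "sex"),
                              cognitive = NULL, time = "visit_time", ...) {
  if (!grouping %in% names(data)) {
    abort(sprintf("Grouping column `%s` not found.", grouping))
  }
  adjust <- rate_adjusters(outcome, adjust, cognitive, data)
  d <- filter(data, !is.na(.data[[grouping]]))
  g <- factor(d[[grouping]])
  present <- unique(as.character(g))
  if (length(present) < 2) {
    abort(sprintf(
      "Need two `%s` levels with data; found: %s.", grouping,
      paste(present, collapse = ", ")
    ))
  }
  ref <- ref %||% intersect(c("control", "high"), present)[1] %||% present[1]
  if (is.na(ref)) ref <- present[1]
  d[[grouping]] <- stats::relevel(droplevels(g), ref = ref)
  assert_followup(d, outcome, label = "joint model")
  fixed <- c(sprintf("%s * %s", time, grouping), adjust)
  fit <- fit_lmm(d, outcome, fixed = fixed, random = "intercept",
                 time = time, ...)
  rows <- filter(tidy(fit), grepl(":", .data$term, fixed = TRUE) &
                   grepl(time, .data$term, fixed = TRUE))
  other <- setdiff(levels(d[[grouping]]), ref)
  tibble(
    outcome = outcome,
    term = rows$term,
    estimate = rows$estimate,
    se = rows$std_error,
    p_value = rows$p_value,
    reference = ref,
    contrast = paste(other, "-", ref),
    n_obs = fit$n_obs,
    n_subjects = fit$n_subjects,
    converged = fit$converged,
    singular = fit$singular
  )
}

#' Compare correlated vs uncorrelated random intercept-slope structures
#'
#' Restricts to subjects with at least `min_visits` non-missing
#' observations, fits the same fixed-effects structure under maximum
#' likelihood with (a) correlated and (b) uncorrelated subject-level random
#' intercept and slope on time, and compares AICs (ML is used because AIC
#' under REML is not comparable across random-effects structures). The
#' lower AIC is preferred.
#'
#' @param data Long-format visit tibble.
#' @param outcome Outcome column name.
#' @param fixed Fixed-effect terms (default time, age at baseline, sex).
#' @param min_visits Minimum visits per subject (default 3).
#' @param time,... As in [fit_lmm()].
#' @return One-row tibble: `aic_correlated`, `aic_uncorrelated`,
#'   `delta_aic` (correlated minus uncorrelated), `preferred`,
#'   `n_subjects`, `n_obs`, `singular_correlated`, `singular_uncorrelated`.
#' @export
compare_random_structures <- function(data, outcome,
                                      fixed = c("visit_time", "age_baseline",
                                                "sex"),
                                      min_visits = 3, time = "visit_time",
                                      ...) {
  keep <- data |>
    filter(!is.na(.data[[outcome]])) |>
    count(.data$subject_id) |>
    filter(.data$n >= min_visits) |>
    pull(.data$subject_id)
  if (length(keep) < 3) {
    abort(sprintf(
      "Insufficient repeated measures: only %d subject(s) with >= %d visits.",
      length(keep), min_visits
    ))
  }
  d <- filter(data, .data$subject_id %in% keep)
  f_corr <- fit_lmm(d, outcome, fixed = fixed, random = "intercept_slope",
                    time = time, method = "ML", ...)
  f_unc <- fit_lmm(d, outcome, fixed = fixed,
                   random = "intercept_slope_uncorrelated",
                   time = time, method = "ML", ...)
  tibble(
    outcome = outcome,
    aic_correlated = f_corr$aic,
    aic_uncorrelated = f_unc$aic,
    delta_aic = f_corr$aic - f_unc$aic,
    preferred = ifelse(f_corr$aic <= f_unc$aic, "correlated",
                       "uncorrelated"),
    n_subjects = f_corr$n_subjects,
    n_obs = f_corr$n_obs,
    singular_correlated = f_corr$singular,
    singular_uncorrelated = f_unc$singular
  )
}

#' Concurrent-change association between two longitudinal outcomes
#'
#' Mixed model of one outcome on the concurrent values of another, with a
#' subject random intercept and adjustment for age at baseline and sex:
#' the coefficient measures how changes in the two outcomes track each
#' other within subjects over shared visits.
#'
#' @param data Long-format visit tibble.
#' @param outcome Response column (e.g. `pfgcipl`).
#' @param predictor Concurrent predictor column (e.g. `prnfl_mean`).
#' @param adjust Baseline covariates (default age at baseline and sex).
#' @param ... Passed to [fit_lmm()].
#' @return One-row tibble: `outcome`, `predictor`, `estimate` (response
#'   units per predictor unit), `se`, `p_value`, `n_obs`, `n_subjects`,
#'   `converged`, `singular`.
#' @export
concurrent_change_model <- function(data, outcome, predictor,
                                    adjust = c("age_baseline", "sex"), ...) {
  shared <- filter(data, !is.na(.data[[outcome]]) & !is.na(.data[[predictor]]))
  if (!nrow(shared)) {
    abort(sprintf(
      "No shared visits with both `%s` and `%s` observed.", outcome, predictor
    ))
  }
  fit <- fit_lmm(shared, outcome, fixed = c(predictor, adjust),
                 random = "intercept", ...)
  row <- filter(tidy(fit), .data$term == predictor)
  tibble(
    outcome = outcome, predictor = predictor,
    estimate = row$estimate, se = row$std_error, p_value = row$p_value,
    n_obs = fit$n_obs, n_subjects = fit$n_subjects,
    converged = fit$converged, singular = fit$singular
  )
}

#' Baseline group comparisons with automatic test selection
#'
#' Compares baseline (first-visit) characteristics between two groups using
#' the conventional rules: Chi-square for categorical variables, switching
#' to Fisher's exact test when any expected cell count is below 5; t-test
#' for quantitative variables whose residual distribution passes a
#' Shapiro-Wilk normality check in both groups (at alpha 0.05), Wilcoxon
#' rank-sum otherwise. P-values are Bonferroni-adjusted across the declared
#' family of variables.
#'
#' @param data Long-format visit tibble.
#' @param vars Character vector of variables to compare.
#' @param group Grouping column (default `group`).
#' @param correct Multiplicity correction passed to [stats::p.adjust()]
#'   (default `"bonferroni"`; use `"none"` to disable).
#' @return Tibble with one row per variable: `variable`, `test`,
#'   `statistic`, `p_value`, `p_adjusted`.
#' @export
baseline_comparison <- function(data, vars, group = "group",
                                correct = "bonferroni") {
  if (!group %in% names(data)) {
    abort(sprintf("Grouping column `%s` not found.", group))
  }
  baseline <- data |>
    group_by(.data$subject_id) |>
    slice_min(.data$visit_time, n = 1, with_ties = FALSE) |>
    ungroup()
  g <- droplevels(factor(baseline[[group]]))
  if (nlevels(g) != 2 || any(table(g) == 0)) {
    abort("Baseline comparison needs exactly two non-empty groups.")
  }
  rows <- map(vars, function(v) {
    x <- baseline[[v]]
    ok <- !is.na(x) & !is.na(g)
    xv <- x[ok]; gv <- droplevels(g[ok])
    if (nlevels(gv) < 2) {
      return(tibble(variable = v, test = "not testable (one group)",
                    statistic = NA_real_, p_value = NA_real_))
    }
    if (is.numeric(xv) && length(unique(xv)) > 5) {
      normal <- all(tapply(xv, gv, function(z) {
        if (length(z) < 3 || length(z) > 5000 || sd(z) == 0) return(FALSE)
        shapiro.test(z)$p.value > 0.05
      }))
      if (normal) {
        tt <- t.test(xv ~ gv)
        tibble(variable = v, test = "t-test",
               statistic = unname(tt$statistic), p_value = tt$p.value)
      } else {
        wt <- suppressWarnings(wilcox.test(xv ~ gv))
        tibble(variable = v, test = "Wilcoxon",
               statistic = unname(wt$statistic), p_value = wt$p.value)
      }
    } else {
      tab <- table(factor(xv), gv)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        ft <- fisher.test(tab)
        tibble(variable = v, test = "Fisher exact",
               statistic = NA_real_, p_value = ft$p.value)
      } else {
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        tibble(variable = v, test = "Chi-square",
               statistic = unname(ct$statistic), p_value = ct$p.value)
      }
    }
  })
  out <- bind_rows(rows)
  out$p_adjusted <- p.adjust(out$p_value, method = correct)
  out
}
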