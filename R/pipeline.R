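#' Run the full simulate - extract - classify - model pipeline
#'
#' Orchestrates the whole analysis on a synthetic cohort: draws a reference
#' control population and derives the pfGCIPL quartile cutoff; simulates
#' the longitudinal cohort; classifies subjects into low/high baseline
#' subgroups; and fits the longitudinal model battery (group and subgroup
#' annualized pfGCIPL rates and interactions, MoCA / H&Y / UPDRS-III
#' subgroup rates, pRNFL sector models, the pfGCIPL-pRNFL concurrent-change
#' association, the correlated-vs-uncorrelated random-structure comparison,
#' the per-ring topographic rate map, and baseline group comparisons),
#' ending with the derived headline quantities (slope ratios and relative
#' reductions). The run is fully deterministic given `seed`.
#'
#' Group-comparison stages whose preconditions are unmet (e.g. an empty
#' group) are skipped with a logged reason; any other stage failure aborts
#' with a stage-tagged error.
#'
#' @param config A [cohort_config()].
#' @param reference_n Size of the simulated reference population
#'   (default 415).
#' @param seed Integer seed driving every random stage (default 1).
#' @return A `retina_report` list: `cohort`, `truth`, `rule`, `rates`,
#'   `interactions`, `clinical_rates`, `concurrent`, `prnfl_interactions`,
#'   `random_structures`, `rate_map`, `baseline`, `headline`, `log`,
#'   `seed`, `config`.
#' @export
run_pipeline <- function(config = cohort_config(), reference_n = 415,
                         seed = 1) {
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  stage <- function(name, ok, expr, skip_reason = NULL) {
    if (!ok) {
      note("SKIP  %s: %s", name, skip_reason %||% "preconditions unmet")
      return(NULL)
    }
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s': %s", name, conditionMessage(e)))
    })
    note("DONE  %s", name)
    res
  }
  note("retinarate pipeline, seed = %d", seed)

  reference <- stage("reference population", TRUE,
                     simulate_reference(reference_n, config, seed = seed))
  rule <- stage("cutoff derivation", TRUE, derive_cutoff(
    reference$pfgcipl, percentile = config$subgroup_percentile,
    provenance = sprintf("simulated reference population (n = %d)",
                         reference_n)
  ))
  note("      cutoff = %.2f um", rule$cutoff)
  cohort <- stage("cohort simulation", TRUE,
                  simulate_cohort(config, seed = seed + 1L))
  cohort <- stage("subgroup classification", TRUE,
                  suppressMessages(classify_pfgcipl(cohort, rule)))

  groups <- table(cohort_truth(cohort)$group)
  both_groups <- all(c("control", "PD") %in% names(groups)) &&
    all(groups[c("control", "PD")] > 0)
  pd <- filter(cohort, .data$group == "PD")
  pd_subgroups <- length(unique(na.omit(as.character(pd$pfgcipl_subgroup)))) == 2

  rates <- stage("annualized pfGCIPL rates per group", both_groups,
                 annualized_rate(cohort, "pfgcipl", by = "group"),
                 "a group is empty")
  interaction <- stage("time x group interaction", both_groups,
                       group_interaction(cohort, "pfgcipl"),
                       "a group is empty")
  sub_rates <- stage("PD subgroup pfGCIPL rates", pd_subgroups,
                     annualized_rate(pd, "pfgcipl", by = "pfgcipl_subgroup"),
                     "PD subgroups not both present")
  sub_inter <- stage("PD time x subgroup interaction", pd_subgroups,
                     group_interaction(pd, "pfgcipl",
                                       grouping = "pfgcipl_subgroup"),
                     "PD subgroups not both present")
  clinical <- stage("clinical rates per PD subgroup", pd_subgroups, {
    bind_rows(
      annualized_rate(pd, "moca", by = "pfgcipl_subgroup"),
      annualized_rate(pd, "hy", by = "pfgcipl_subgroup"),
      annualized_rate(pd, "updrs_iii", by = "pfgcipl_subgroup")
    )
  }, "PD subgroups not both present")
  concurrent <- stage("pfGCIPL ~ pRNFL concurrent change", TRUE,
                      concurrent_change_model(cohort, "pfgcipl",
                                              "prnfl_mean"))
  prnfl_inter <- stage("pRNFL sector interactions", both_groups, {
    sectors <- c("prnfl_mean", "prnfl_superior", "prnfl_inferior",
                 "prnfl_nasal", "prnfl_temporal")
    bind_rows(lapply(sectors, function(s) {
      group_interaction(cohort, s)
    }))
  }, "a group is empty")
  rnd <- stage("random-structure comparison (>= 3 visits)", {
    n3 <- cohort |>
      filter(!is.na(.data$pfgcipl)) |>
      count(.data$subject_id) |>
      filter(.data$n >= 3) |>
      nrow()
    n3 >= 10
  }, compare_random_structures(cohort, "pfgcipl"),
  "fewer than 10 subjects with 3 visits")
  rmap <- stage("topographic rate map", both_groups,
                rate_map(cohort), "a group is empty")
  baseline <- stage("baseline group comparisons", both_groups,
                    baseline_comparison(
                      cohort, c("age_baseline", "sex", "education", "moca",
                                "pfgcipl")
                    ), "a group is empty")

  headline <- stage("headline quantities", TRUE, {
    h <- list()
    if (!is.null(rates) && all(c("control", "PD") %in% rates$group)) {
      b <- setNames(rates$beta_time, rates$group)
      h$pd_rate <- unname(b["PD"])
      h$control_rate <- unname(b["control"])
      h$rate_ratio_pd_vs_control <- slope_ratio(b[["PD"]], b[["control"]])
    }
    if (!is.null(interaction)) h$interaction_pd_vs_control <-
      interaction$estimate[1]
    if (!is.null(sub_rates) &&
        all(c("high", "low") %in% sub_rates$pfgcipl_subgroup)) {
      s <- setNames(sub_rates$beta_time, sub_rates$pfgcipl_subgroup)
      h$pd_low_rate <- unname(s["low"])
      h$pd_high_rate <- unname(s["high"])
      h$relative_reduction_low_vs_high <-
        relative_reduction(s[["low"]], s[["high"]])
    }
    if (!is.null(clinical)) {
      mo <- filter(clinical, .data$outcome == "moca")
      if (all(c("high", "low") %in% mo$pfgcipl_subgroup)) {
        m <- setNames(mo$beta_time, mo$pfgcipl_subgroup)
        h$moca_rate_low <- unname(m["low"])
        h$moca_rate_high <- unname(m["high"])
        h$moca_rate_ratio_low_vs_high <- slope_ratio(m[["low"]], m[["high"]])
      }
    }
    if (!is.null(concurrent)) h$concurrent_pf_prnfl <- concurrent$estimate[1]
    tibble(metric = names(h), value = unname(unlist(h)))
  })

  structure(
    list(
      cohort = cohort, truth = cohort_truth(cohort), rule = rule,
      rates = rates, interactions = interaction,
      subgroup_rates = sub_rates, subgroup_interaction = sub_inter,
      clinical_rates = clinical, concurrent = concurrent,
      prnfl_interactions = prnfl_inter, random_structures = rnd,
      rate_map = rmap, baseline = baseline, headline = headline,
      log = log_lines, seed = seed, config = config
    ),
    class = "retina_report"
  )
}

#' @export
print.retina_report <- function(x, ...) {
  cat(sprintf(
    "<retina_report> seed %d: %d subjects, %d visits, cutoff %.2f um\n",
    x$seed, nrow(x$truth), nrow(x$cohort), x$rule$cutoff
  ))
  if (!is.null(x$headline) && nrow(x$headline)) {
    cat("headline quantities:\n")
    print(as.data.frame(x$headline), digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Write the report bundle to a directory
#'
#' Emits the machine-readable outputs of a pipeline run: the cohort table
#' (CSV + ground-truth JSON sidecar), the subgroup rule (JSON), the rate
#' and headline tables (CSV), the topographic rate map (CSV) and the run
#' log. Tables keep full precision; rounding is for display only.
#'
#' @param report A `retina_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "retina_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(report$cohort, file.path(dir, "cohort.csv"))
  write_rule(report$rule, file.path(dir, "subgroup_rule.json"))
  for (nm in c("rates", "subgroup_rates", "clinical_rates", "headline")) {
    if (!is.null(report[[nm]])) {
      write.csv(as.data.frame(report[[nm]]),
                file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
    }
  }
  if (!is.null(report$rate_map)) {
    write.csv(as.data.frame(report$rate_map), file.path(dir, "rate_map.csv"),
              row.names = FALSE)
  }
  writeLines(report$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
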