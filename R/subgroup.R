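#' Derive the pfGCIPL subgroup cutoff from a reference population
#'
#' The cutoff separating "low" from "high" baseline pfGCIPL is the upper
#' limit of the lowest quartile (by default) of a reference control sample,
#' estimated with the linear-interpolation quantile convention
#' (`stats::quantile` type 7). The reference sample is external: the cutoff
#' is never derived from the analysis cohort itself.
#'
#' @param reference Numeric vector of reference pfGCIPL values (µm), or a
#'   data frame with a `pfgcipl` column.
#' @param percentile Percentile in (0, 100); default 25.
#' @param min_n Minimum reference sample size (default 20).
#' @param provenance Free-text description of the reference sample.
#' @return A `subgroup_rule`: list with `cutoff` (µm), `percentile`,
#'   `reference_n`, `convention` and `provenance`.
#' @export
derive_cutoff <- function(reference, percentile = 25, min_n = 20,
                          provenance = "reference control sample") {
  if (is.data.frame(reference)) reference <- reference$pfgcipl
  reference <- as.numeric(reference)
  if (anyNA(reference) || any(!is.finite(reference))) {
    abort("Reference values must all be finite.")
  }
  if (length(reference) < min_n) {
    abort(sprintf(
      "Reference sample too small: %d values (< %d).",
      length(reference), min_n
    ))
  }
  if (any(reference <= 0)) abort("Reference thickness values must be > 0.")
  if (percentile <= 0 || percentile >= 100) {
    abort("`percentile` must be in (0, 100).")
  }
  cutoff <- unname(quantile(reference, percentile / 100, type = 7))
  structure(
    list(
      cutoff = cutoff,
      percentile = percentile,
      reference_n = length(reference),
      convention = "linear interpolation between order statistics (type 7)",
      provenance = provenance
    ),
    class = "subgroup_rule"
  )
}

#' @export
print.subgroup_rule <- function(x, ...) {
  cat(sprintf(
    "<subgroup_rule> cutoff %.2f um (%gth percentile of n = %d; %s)\n",
    x$cutoff, x$percentile, x$reference_n, x$provenance
  ))
  cat(sprintf("  convention: %s\n", x$convention))
  cat("  classification: low iff baseline pfGCIPL < cutoff\n")
  invisible(x)
}

#' Serialize / read a subgroup rule as JSON
#'
#' @param rule A `subgroup_rule`.
#' @param path File path.
#' @export
write_rule <- function(rule, path) {
  stopifnot(inherits(rule, "subgroup_rule"))
  jsonlite::write_json(unclass(rule), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rule
#' @export
read_rule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "subgroup_rule")
}

#' Classify subjects into low/high baseline-pfGCIPL subgroups
#'
#' Applies a [derive_cutoff()] rule to the baseline visit of each subject
#' (the row with the smallest `visit_time`, irrespective of row order):
#' subjects with baseline pfGCIPL strictly below the cutoff are `low`, those
#' at or above it are `high`. The label is attached to every visit row of
#' the subject. Subjects without a usable baseline value are left
#' unclassified (`NA`) with a message.
#'
#' @param data Long-format visit tibble with `subject_id`, `visit_time` and
#'   the value column.
#' @param rule A `subgroup_rule`.
#' @param value Column holding pfGCIPL values (default `pfgcipl`).
#' @return `data` with an added factor column `pfgcipl_subgroup`
#'   (levels `high`, `low`; `high` is the reference level).
#' @export
classify_pfgcipl <- function(data, rule, value = "pfgcipl") {
  stopifnot(inherits(rule, "subgroup_rule"))
  value <- as_name(enquo(value))
  if (!all(c("subject_id", "visit_time", value) %in% names(data))) {
    abort(sprintf(
      "`data` must have columns `subject_id`, `visit_time`, `%s`.", value
    ))
  }
  baseline <- data |>
    group_by(.data$subject_id) |>
    slice_min(.data$visit_time, n = 1, with_ties = FALSE) |>
    ungroup() |>
    transmute(
      .data$subject_id,
      pfgcipl_subgroup = factor(
        ifelse(.data[[value]] < rule$cutoff, "low", "high"),
        levels = c("high", "low")
      )
    )
  out <- left_join(data, baseline, by = "subject_id")
  n_un <- out |>
    distinct(.data$subject_id, .data$pfgcipl_subgroup) |>
    summarise(k = sum(is.na(.data$pfgcipl_subgroup))) |>
    pull(.data$k)
  if (n_un > 0) {
    inform(sprintf(
      "%d subject(s) left unclassified (no usable baseline %s).", n_un, value
    ))
  }
  out
}
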