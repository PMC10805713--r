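#' Average per-eye features into one value per subject and visit
#'
#' Retinal features extracted per eye are averaged between left and right
#' eyes to obtain a single value per subject and visit; when only one eye is
#' available its value is used unchanged. Eye records whose feature values
#' are all missing are dropped with a message, and subject-visits left with
#' zero usable eyes are dropped likewise.
#'
#' @param data Tibble with one row per eye per subject-visit, containing
#'   identifier columns and numeric feature columns.
#' @param id,time Identifier columns (defaults `subject_id`, `visit_time`).
#' @return Tibble with one row per subject-visit: the mean of each numeric
#'   feature over available eyes, plus `n_eyes`.
#' @export
average_eyes <- function(data, id = "subject_id", time = "visit_time") {
  id <- as_name(enquo(id))
  time <- as_name(enquo(time))
  if (!all(c(id, time) %in% names(data))) {
    abort(sprintf("`data` must have columns `%s` and `%s`.", id, time))
  }
  feature_cols <- setdiff(
    names(data)[vapply(data, is.numeric, logical(1))],
    c(id, time)
  )
  if (!length(feature_cols)) abort("No numeric feature columns to average.")
  usable <- rowSums(!is.na(as.data.frame(data)[, feature_cols, drop = FALSE])) > 0
  if (any(!usable)) {
    inform(sprintf(
      "Dropping %d eye record(s) with no usable feature values.",
      sum(!usable)
    ))
    data <- data[usable, , drop = FALSE]
  }
  if (!nrow(data)) {
    inform("No subject-visits with at least one usable eye remain.")
  }
  data |>
    group_by(across(all_of(c(id, time)))) |>
    summarise(
      n_eyes = dplyr::n(),
      across(all_of(feature_cols), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    mutate(across(all_of(feature_cols), ~ ifelse(is.nan(.x), NA_real_, .x)))
}
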