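#' Headline slope arithmetic
#'
#' `slope_ratio()` is the ratio of two annualized rates (e.g. "the thinning
#' rate was twice as high in PD"). `relative_reduction()` is the percentage
#' by which the magnitude of one rate falls short of another,
#' `100 * (1 - |slope_a| / |slope_b|)` (e.g. "40% slower atrophy in the low
#' subgroup"). Both are pure, unit-invariant functions: rescaling both
#' slopes by a common factor leaves them unchanged.
#'
#' @param slope_a,slope_b Annualized rates in any common unit per year.
#' @return `slope_ratio`: `slope_a / slope_b`; `relative_reduction`: a
#'   percentage. `NA` (with a warning) when `slope_b` is zero, or — for
#'   `relative_reduction` — when the slopes have opposite signs.
#' @export
slope_ratio <- function(slope_a, slope_b) {
  out <- slope_a / slope_b
  bad <- slope_b == 0
  if (any(bad, na.rm = TRUE)) {
    warn("slope_ratio undefined for zero denominator; returning NA.")
    out[bad] <- NA_real_
  }
  out
}

#' @rdname slope_ratio
#' @export
relative_reduction <- function(slope_a, slope_b) {
  out <- 100 * (1 - abs(slope_a) / abs(slope_b))
  bad <- slope_b == 0
  opp <- !bad & !is.na(slope_a) & sign(slope_a) * sign(slope_b) < 0
  if (any(bad, na.rm = TRUE)) {
    warn("relative_reduction undefined for zero denominator; returning NA.")
    out[bad] <- NA_real_
  }
  if (any(opp)) {
    warn("relative_reduction undefined for opposite-sign slopes; returning NA.")
    out[opp] <- NA_real_
  }
  out
}

#' Topographic map of annualized thinning rates per concentric ring
#'
#' Fits, for each concentric-ring feature column, the per-group annualized
#' rate models and the time-by-group interaction (all adjusted for age at
#' baseline and sex), and assembles them into a topographic rate map: the
#' absolute rate per group, the relative increase of the non-reference over
#' the reference group, and the interaction p-value, per ring.
#'
#' @param data Long-format visit tibble with ring feature columns.
#' @param scheme A `sector_scheme` describing the ring geometry (default
#'   [concentric_scheme()]).
#' @param prefix Ring feature columns are `paste0(prefix, ring_number)`
#'   (default `"gcipl_ring"`).
#' @param grouping Grouping column (default `group`).
#' @param ... Passed to the model fits.
#' @return A `retina_rate_map` tibble: one row per ring and group with
#'   `beta_time`, `se`, `p_value`, plus per-ring `relative_increase` (%)
#'   and `p_interaction`. Rings whose fit fails are flagged in `note`.
#' @export
rate_map <- function(data, scheme = concentric_scheme(),
                     prefix = "gcipl_ring", grouping = "group", ...) {
  stopifnot(inherits(scheme, "sector_scheme"))
  ref <- intersect(c("control", "high"),
                   unique(as.character(data[[grouping]])))[1]
  rows <- map(seq_len(nrow(scheme)), function(i) {
    s <- scheme[i, ]
    col <- paste0(prefix, s$ring)
    if (!col %in% names(data)) {
      return(tibble(
        sector = s$sector, ring = s$ring,
        r_inner = s$r_inner, r_outer = s$r_outer,
        level = NA_character_, beta_time = NA_real_, se = NA_real_,
        p_value = NA_real_, relative_increase = NA_real_,
        p_interaction = NA_real_,
        note = sprintf("feature column `%s` missing", col)
      ))
    }
    res <- try({
      per_group <- annualized_rate(data, col, by = grouping, ...)
      inter <- group_interaction(data, col, grouping = grouping, ...)
      beta_ref <- per_group$beta_time[per_group[[grouping]] == ref]
      rel <- per_group |>
        mutate(relative_increase = ifelse(
          .data[[grouping]] == ref, NA_real_,
          100 * (.data$beta_time / beta_ref - 1)
        ))
      if (!is.na(beta_ref) && abs(beta_ref) < 1e-8) {
        rel$relative_increase <- NA_real_
        note <- "reference rate is zero: relative increase undefined"
      } else {
        note <- NA_character_
      }
      tibble(
        sector = s$sector, ring = s$ring,
        r_inner = s$r_inner, r_outer = s$r_outer,
        level = as.character(rel[[grouping]]),
        beta_time = rel$beta_time, se = rel$se, p_value = rel$p_value,
        relative_increase = rel$relative_increase,
        p_interaction = inter$p_value[1],
        note = note
      )
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      tibble(
        sector = s$sector, ring = s$ring,
        r_inner = s$r_inner, r_outer = s$r_outer,
        level = NA_character_, beta_time = NA_real_, se = NA_real_,
        p_value = NA_real_, relative_increase = NA_real_,
        p_interaction = NA_real_,
        note = paste("fit failed:", attr(res, "condition")$message)
      )
    } else {
      res
    }
  })
  out <- bind_rows(rows)
  attr(out, "reference") <- ref
  attr(out, "grouping") <- grouping
  class(out) <- c("retina_rate_map", class(out))
  out
}

#' @rdname rate_map
#' @param object A `retina_rate_map`.
#' @export
autoplot.retina_rate_map <- function(object, ...) {
  df <- filter(object, !is.na(.data$level))
  ggplot(df) +
    geom_rect(aes(
      xmin = 0, xmax = 360,
      ymin = .data$r_inner, ymax = .data$r_outer,
      fill = .data$beta_time
    )) +
    coord_polar(theta = "x") +
    facet_wrap(~level) +
    scale_fill_viridis_c(name = "µm/year", direction = -1) +
    labs(
      title = "Annualized thinning rate by fovea-centred ring",
      y = "radius (mm)", x = NULL
    ) +
    theme_minimal() +
    theme(axis.text.x = element_blank())
}

#' Spaghetti plot of longitudinal trajectories
#'
#' @param data Long-format visit tibble.
#' @param outcome Outcome column (default `pfgcipl`).
#' @param colour Column mapped to colour (default `group`).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(data, outcome = "pfgcipl", colour = "group") {
  ggplot(
    filter(data, !is.na(.data[[outcome]])),
    aes(.data$visit_time, .data[[outcome]],
        group = .data$subject_id, colour = .data[[colour]])
  ) +
    geom_line(alpha = 0.35) +
    geom_point(size = 0.7, alpha = 0.5) +
    labs(x = "years since baseline", y = outcome) +
    theme_minimal()
}
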