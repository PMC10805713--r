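#' Concentric-ring sector scheme
#'
#' Builds the fovea-centred concentric sectorization used for topographic
#' analysis: `n_rings` contiguous annuli of radial width `step`, the
#' innermost being a disc. The default (5 rings, 0.5 mm apart) spans radii
#' 0 to 2.5 mm; ring geometry is stored as radii in mm.
#'
#' @param n_rings Number of rings (default 5).
#' @param step Radial width of each ring in mm (default 0.5).
#' @param extent Field width in mm the scheme must fit inside (default 6).
#' @return A `sector_scheme`: a tibble with columns `sector`, `ring`,
#'   `r_inner`, `r_outer` (mm) and `theta_min`, `theta_max` (degrees; `NA`
#'   for full annuli).
#' @export
concentric_scheme <- function(n_rings = 5, step = 0.5, extent = 6) {
  if (!is.numeric(n_rings) || n_rings < 1 || n_rings != round(n_rings)) {
    abort("`n_rings` must be a positive integer.")
  }
  if (!is.numeric(step) || step <= 0) abort("`step` must be > 0 (mm).")
  if (n_rings * step > extent / 2 + 1e-12) {
    abort("Scheme exceeds the field: n_rings * step must be <= extent / 2.")
  }
  out <- tibble(
    sector = paste0("ring", seq_len(n_rings)),
    ring = seq_len(n_rings),
    r_inner = (seq_len(n_rings) - 1) * step,
    r_outer = seq_len(n_rings) * step,
    theta_min = NA_real_,
    theta_max = NA_real_
  )
  new_sector_scheme(out)
}

#' ETDRS macular sector scheme
#'
#' The conventional ETDRS macular rings by *diameter*: central 1 mm disc,
#' parafoveal 1-3 mm ring and perifoveal 3-6 mm ring (radii 0-0.5, 0.5-1.5
#' and 1.5-3 mm).
#'
#' @return A `sector_scheme` (see [concentric_scheme()]).
#' @export
etdrs_scheme <- function() {
  out <- tibble(
    sector = c("central", "parafoveal", "perifoveal"),
    ring = 1:3,
    r_inner = c(0, 0.5, 1.5),
    r_outer = c(0.5, 1.5, 3),
    theta_min = NA_real_,
    theta_max = NA_real_
  )
  new_sector_scheme(out)
}

new_sector_scheme <- function(df) {
  if (anyDuplicated(df$sector)) abort("Sector names must be unique.")
  if (any(df$r_inner < 0) || any(df$r_outer <= df$r_inner)) {
    abort("Sector radii must satisfy 0 <= r_inner < r_outer.")
  }
  class(df) <- c("sector_scheme", class(df))
  df
}

#' Split the annuli of a scheme into anatomical quadrants
#'
#' Each annulus is divided into superior, inferior, nasal and temporal
#' quadrants by the +-45 degree diagonal boundaries, in right-eye orientation
#' (x temporal to nasal, y inferior to superior): nasal spans -45 to 45
#' degrees, superior 45 to 135, temporal 135 to 225 and inferior 225 to 315.
#' A central disc (r_inner = 0), if present, is kept whole.
#'
#' @param scheme A full-circle `sector_scheme`.
#' @return A `sector_scheme` with quadrant sectors.
#' @export
quadrant_split <- function(scheme) {
  stopifnot(inherits(scheme, "sector_scheme"))
  if (any(!is.na(scheme$theta_min))) {
    abort("Scheme is already split into angular sectors.")
  }
  quads <- tibble(
    quadrant = c("nasal", "superior", "temporal", "inferior"),
    theta_min = c(-45, 45, 135, 225),
    theta_max = c(45, 135, 225, 315)
  )
  pieces <- lapply(seq_len(nrow(scheme)), function(i) {
    row <- scheme[i, ]
    if (row$r_inner == 0) return(as_tibble(row))
    tibble(
      sector = paste0(row$sector, "_", quads$quadrant),
      ring = row$ring,
      r_inner = row$r_inner,
      r_outer = row$r_outer,
      theta_min = quads$theta_min,
      theta_max = quads$theta_max
    )
  })
  new_sector_scheme(bind_rows(pieces))
}

#' Sector means of a fovea-centred grid
#'
#' Averages grid nodes over each sector of a scheme. Membership is by node
#' centre: a node belongs to a sector when its radius satisfies
#' `r_inner <= r < r_outer` and (for quadrant sectors) its angle falls in
#' the sector's angular range. Means are unweighted over non-missing member
#' nodes; per-sector coverage (fraction of member nodes that are
#' non-missing) is reported and sectors under `min_coverage` are flagged.
#'
#' @param grid A fovea-centred, right-eye-oriented [thickness_grid()].
#' @param scheme A `sector_scheme`.
#' @param min_coverage Coverage below which a sector is flagged
#'   (default 0.9).
#' @return Tibble with one row per sector: `sector`, `ring`, `r_inner`,
#'   `r_outer`, `mean` (µm; `NA` for empty sectors), `n` (non-missing
#'   nodes), `n_nodes` (member nodes), `coverage`, `low_coverage`.
#' @export
sector_mean <- function(grid, scheme, min_coverage = 0.9) {
  stopifnot(inherits(grid, "thickness_grid"), inherits(scheme, "sector_scheme"))
  if (!grid$centered) {
    warn("Grid is not flagged fovea-centred; sector geometry assumes it is.")
  }
  if (grid$orientation != "right") {
    warn("Grid is not in right-eye orientation; apply flip_left_eye() first.")
  }
  ax <- grid_axes(grid)
  px <- rep(ax$x, times = length(ax$y))
  py <- rep(ax$y, each = length(ax$x))
  r <- sqrt(px^2 + py^2)
  theta <- atan2(py, px) * 180 / pi  # (-180, 180]
  v <- as.vector(grid$values)
  rows <- lapply(seq_len(nrow(scheme)), function(i) {
    s <- scheme[i, ]
    member <- r >= s$r_inner - 1e-12 & r < s$r_outer - 1e-12
    if (!is.na(s$theta_min)) {
      # half-open [theta_min, theta_max); angles within 1e-9 deg of the
      # 360 wrap count as 0 so boundary nodes land in exactly one sector
      th <- (theta - s$theta_min) %% 360
      span <- s$theta_max - s$theta_min
      member <- member & (th < span - 1e-9 | th >= 360 - 1e-9)
    }
    vals <- v[member]
    n_nodes <- sum(member)
    n_ok <- sum(!is.na(vals))
    tibble(
      sector = s$sector, ring = s$ring,
      r_inner = s$r_inner, r_outer = s$r_outer,
      mean = if (n_ok > 0) mean(vals, na.rm = TRUE) else NA_real_,
      n = n_ok, n_nodes = n_nodes,
      coverage = if (n_nodes > 0) n_ok / n_nodes else 0,
      low_coverage = n_nodes == 0 || n_ok / n_nodes < min_coverage
    )
  })
  bind_rows(rows)
}

#' Parafoveal GCIPL thickness of a centred GCIPL map
#'
#' The pfGCIPL is the mean GCIPL thickness over the ETDRS parafoveal
#' annulus: inner diameter 1 mm, outer diameter 3 mm (radii 0.5-1.5 mm)
#' centred on the fovea.
#'
#' @param gcipl_grid A fovea-centred, right-eye-oriented GCIPL
#'   [thickness_grid()].
#' @param min_coverage Coverage below which the value is flagged
#'   (default 0.9).
#' @return One-row tibble with columns `pfgcipl` (µm), `coverage` and
#'   `low_coverage`.
#' @export
extract_pfgcipl <- function(gcipl_grid, min_coverage = 0.9) {
  scheme <- new_sector_scheme(tibble(
    sector = "pfgcipl", ring = 1L, r_inner = 0.5, r_outer = 1.5,
    theta_min = NA_real_, theta_max = NA_real_
  ))
  sm <- sector_mean(gcipl_grid, scheme, min_coverage = min_coverage)
  tibble(
    pfgcipl = sm$mean,
    coverage = sm$coverage,
    low_coverage = sm$low_coverage
  )
}

#' Serialize / read a sector scheme as JSON
#'
#' @param scheme A `sector_scheme`.
#' @param path File path.
#' @return `write_scheme` returns `path` invisibly; `read_scheme` returns
#'   the `sector_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "sector_scheme"))
  jsonlite::write_json(as.data.frame(scheme), path, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  df <- as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  for (col in c("theta_min", "theta_max")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- as.numeric(df[[col]])
  }
  new_sector_scheme(df)
}
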