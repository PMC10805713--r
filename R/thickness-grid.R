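#' Regular thickness grid over the macular field
#'
#' A `thickness_grid` is a square regular grid of layer thickness values (in
#' micrometres) covering the scanned macular field. Node `[i, j]` sits at
#' `(grid_axes(g)$x[i], grid_axes(g)$y[j])` in millimetres, with the field
#' centre at `(0, 0)`; nodes span the full extent, so the spacing is
#' `extent / (n - 1)`. `NA` values mark nodes without scan support (e.g.
#' outside the convex hull of the acquired samples, or margins exposed by
#' recentring).
#'
#' Orientation bookkeeping follows the usual OCT conventions: `laterality` is
#' the scanned eye (`"OD"` right, `"OS"` left) and `orientation` records
#' whether the map is currently in right-eye orientation (x increasing
#' temporal to nasal). [flip_left_eye()] converts left-eye maps. `centered`
#' is set by [recenter()] once the foveal centre has been moved to the grid
#' origin.
#'
#' @param values Square numeric matrix of thickness values (µm); rows index x,
#'   columns index y.
#' @param extent Field width in mm (default 6, i.e. a 6x6 mm field).
#' @param laterality `"OD"` or `"OS"`.
#' @param orientation `"right"` or `"left"` eye orientation of the x axis.
#'   Defaults to the native orientation of `laterality`.
#' @param centered Logical; `TRUE` once the fovea is at the grid origin.
#' @param layer Optional layer label (e.g. `"gcipl"`, `"trt"`).
#'
#' @return An object of class `thickness_grid`.
#' @seealso [interpolate_to_grid()], [locate_fovea()], [recenter()],
#'   [flip_left_eye()], [sector_mean()]
#' @export
thickness_grid <- function(values, extent = 6, laterality = c("OD", "OS"),
                           orientation = NULL, centered = FALSE,
                           layer = NULL) {
  laterality <- match.arg(laterality)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    abort("`values` must be a square matrix.")
  }
  if (!is.numeric(extent) || length(extent) != 1 || extent <= 0) {
    abort("`extent` must be a single positive number (mm).")
  }
  orientation <- orientation %||% if (laterality == "OD") "right" else "left"
  structure(
    list(
      values = values,
      extent = extent,
      laterality = laterality,
      orientation = orientation,
      centered = isTRUE(centered),
      layer = layer
    ),
    class = "thickness_grid"
  )
}

#' @export
print.thickness_grid <- function(x, ...) {
  n <- nrow(x$values)
  cat(sprintf(
    "<thickness_grid> %dx%d nodes, %.1f mm field, %s (%s-eye oriented)%s\n",
    n, n, x$extent, x$laterality, x$orientation,
    if (x$centered) ", fovea-centred" else ""
  ))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf(
    "  values: %.1f-%.1f um, %d missing node(s)%s\n",
    rng[1], rng[2], sum(is.na(x$values)),
    if (is.null(x$layer)) "" else sprintf(", layer: %s", x$layer)
  ))
  invisible(x)
}

#' Node coordinates of a thickness grid
#'
#' @param grid A [thickness_grid()].
#' @return List with numeric vectors `x` and `y` (mm) and the node `spacing`.
#' @export
grid_axes <- function(grid) {
  stopifnot(inherits(grid, "thickness_grid"))
  n <- nrow(grid$values)
  ax <- seq(-grid$extent / 2, grid$extent / 2, length.out = n)
  list(x = ax, y = ax, spacing = grid$extent / (n - 1))
}

#' @export
as_tibble.thickness_grid <- function(x, ...) {
  ax <- grid_axes(x)
  vals <- as.vector(x$values)
  tibble(
    x = rep(ax$x, times = length(ax$y)),
    y = rep(ax$y, each = length(ax$x)),
    value = vals
  )
}

#' @rdname thickness_grid
#' @param object,... Passed to `autoplot`.
#' @export
autoplot.thickness_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    coord_equal() +
    scale_fill_viridis_c(name = "µm", na.value = "grey90") +
    labs(
      x = "x (mm)", y = "y (mm)",
      title = sprintf(
        "%s map (%s)", object$layer %||% "thickness", object$laterality
      )
    ) +
    theme_minimal()
}

#' Evaluate a grid by bilinear interpolation
#'
#' Interpolates grid values at arbitrary points inside the field. Points
#' outside the field, or in cells with any missing corner, return `NA`.
#'
#' @param grid A [thickness_grid()].
#' @param x,y Numeric vectors of coordinates (mm).
#' @return Numeric vector of interpolated values (µm).
#' @export
grid_eval <- function(grid, x, y) {
  ax <- grid_axes(grid)
  n <- length(ax$x)
  h <- ax$spacing
  fx <- (x - ax$x[1]) / h
  fy <- (y - ax$y[1]) / h
  i0 <- pmin(pmax(floor(fx), 0), n - 2)
  j0 <- pmin(pmax(floor(fy), 0), n - 2)
  tx <- fx - i0
  ty <- fy - j0
  outside <- fx < -1e-9 | fx > n - 1 + 1e-9 | fy < -1e-9 | fy > n - 1 + 1e-9
  v <- grid$values
  idx <- function(i, j) v[cbind(i + 1L, j + 1L)]
  z <- (1 - tx) * (1 - ty) * idx(i0, j0) +
    tx * (1 - ty) * idx(i0 + 1L, j0) +
    (1 - tx) * ty * idx(i0, j0 + 1L) +
    tx * ty * idx(i0 + 1L, j0 + 1L)
  z[outside] <- NA_real_
  z
}

#' Mirror a grid about its vertical midline
#'
#' Low-level horizontal mirror (x -> -x). This is an involution:
#' applying it twice returns the original array. Used by [flip_left_eye()]
#' to bring left-eye maps into right-eye orientation.
#'
#' @param grid A [thickness_grid()].
#' @return The mirrored grid, with the `orientation` flag toggled.
#' @export
mirror_horizontal <- function(grid) {
  stopifnot(inherits(grid, "thickness_grid"))
  grid$values <- grid$values[rev(seq_len(nrow(grid$values))), , drop = FALSE]
  grid$orientation <- if (grid$orientation == "right") "left" else "right"
  grid
}

#' Normalize a map to right-eye orientation
#'
#' Left-eye (OS) maps are mirrored about the vertical midline so that the x
#' axis runs temporal to nasal, matching right eyes; maps already in right-eye
#' orientation (all OD maps, and OS maps already flipped) pass through
#' unchanged.
#'
#' @param grid A [thickness_grid()] with known laterality.
#' @return A right-eye-oriented `thickness_grid`.
#' @export
flip_left_eye <- function(grid) {
  stopifnot(inherits(grid, "thickness_grid"))
  if (is.null(grid$laterality) || is.na(grid$laterality) ||
      !grid$laterality %in% c("OD", "OS")) {
    abort("Unknown laterality: cannot normalize eye orientation.")
  }
  if (grid$orientation == "right") {
    return(grid)
  }
  mirror_horizontal(grid)
}

#' Interpolate scattered thickness samples onto a regular grid
#'
#' Builds the standard analysis grid (default 200x200 nodes over the 6x6 mm
#' field) from scattered per-eye point samples by piecewise-linear
#' (barycentric) interpolation over a Delaunay triangulation of the sample
#' locations. The interpolant reproduces affine fields exactly and never
#' produces values outside the range of the input values; grid nodes outside
#' the convex hull of the samples are marked missing.
#'
#' @param data Data frame of samples with coordinate columns `x`, `y` (mm).
#' @param value Column holding the thickness values (µm); default `value`.
#' @param n Grid resolution per side (default 200).
#' @param extent Field width in mm (default: from `attr(data, "extent")`,
#'   else 6).
#' @param laterality `"OD"` or `"OS"` (default: from
#'   `attr(data, "laterality")`, else `"OD"`).
#' @param layer Optional layer label (default: the name of `value`).
#' @return A [thickness_grid()].
#' @export
interpolate_to_grid <- function(data, value = "value", n = 200,
                                extent = NULL, laterality = NULL,
                                layer = NULL) {
  value <- as_name(enquo(value))
  if (!all(c("x", "y", value) %in% names(data))) {
    abort(sprintf("`data` must have columns `x`, `y` and `%s`.", value))
  }
  extent <- extent %||% attr(data, "extent") %||% 6
  laterality <- laterality %||% attr(data, "laterality") %||% "OD"
  px <- data$x
  py <- data$y
  pz <- data[[value]]
  keep <- is.finite(px) & is.finite(py) & is.finite(pz)
  px <- px[keep]; py <- py[keep]; pz <- pz[keep]
  if (length(px) < 3) {
    abort("Need at least 3 finite sample points to interpolate.")
  }
  # collinearity check: rank of centred coordinates
  cx <- px - mean(px); cy <- py - mean(py)
  cross <- sum(cx^2) * sum(cy^2) - sum(cx * cy)^2
  if (cross <= 1e-12 * (sum(cx^2) + sum(cy^2))^2) {
    abort("Sample points are (nearly) collinear: degenerate geometry.")
  }
  ax <- seq(-extent / 2, extent / 2, length.out = n)
  z <- linear_scatter_interp(px, py, pz, ax, ax)
  thickness_grid(z, extent = extent, laterality = laterality,
                 layer = layer %||% value)
}

# Triangle faces of a deldir Delaunay triangulation, assembled from its
# edge list. For every edge and every side, the face-adjacent vertex is the
# common graph neighbour maximizing the inscribed angle at that vertex
# (equivalently: minimal circumcircle, the Delaunay empty-circle property);
# each face is then found from all three of its edges and deduplicated.
# This is algebraically the same set of triangles deldir::triMat() returns
# but runs in vectorized time.
delaunay_faces <- function(dd, x, y) {
  e <- as.matrix(dd$delsgs[, c("ind1", "ind2")])
  dir_edges <- rbind(e, e[, 2:1, drop = FALSE])
  # candidate triples (i, j, k): k adjacent to both i and j, (i, j) an edge
  df <- data.frame(k = dir_edges[, 2], v = dir_edges[, 1])
  m <- merge(df, df, by = "k")
  i <- m$v.x; j <- m$v.y; k <- m$k
  keep <- i < j
  i <- i[keep]; j <- j[keep]; k <- k[keep]
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  keep <- paste(i, j) %in% ekey
  i <- i[keep]; j <- j[keep]; k <- k[keep]
  cross <- (x[j] - x[i]) * (y[k] - y[i]) - (y[j] - y[i]) * (x[k] - x[i])
  side <- sign(cross)
  ok <- side != 0
  i <- i[ok]; j <- j[ok]; k <- k[ok]; side <- side[ok]
  ax <- x[i] - x[k]; ay <- y[i] - y[k]
  bx <- x[j] - x[k]; by <- y[j] - y[k]
  cosang <- (ax * bx + ay * by) /
    sqrt((ax^2 + ay^2) * (bx^2 + by^2))
  grp <- paste(i, j, side)
  ord <- order(grp, cosang)
  sel <- ord[!duplicated(grp[ord])]
  a <- i[sel]; b <- j[sel]; cc <- k[sel]
  lo <- pmin(a, b, cc); hi <- pmax(a, b, cc); mid <- a + b + cc - lo - hi
  tri <- cbind(lo, mid, hi)
  tri[!duplicated(paste(lo, mid, hi)), , drop = FALSE]
}

# Piecewise-linear interpolation of scattered (x, y, z) onto the grid
# xo x yo: Delaunay triangulation via deldir, then vectorized barycentric
# evaluation per triangle. Duplicated locations are averaged first.
linear_scatter_interp <- function(x, y, z, xo, yo) {
  key <- paste(signif(x, 12), signif(y, 12))
  if (anyDuplicated(key)) {
    agg <- tapply(z, key, mean)
    first <- !duplicated(key)
    ord <- key[first]
    x <- x[first]; y <- y[first]; z <- as.numeric(agg[ord])
  }
  dd <- deldir::deldir(x, y, suppressMsge = TRUE)
  tri <- delaunay_faces(dd, x, y)
  nx <- length(xo)
  ny <- length(yo)
  out <- matrix(NA_real_, nx, ny)
  tol <- 1e-9
  for (k in seq_len(nrow(tri))) {
    i <- tri[k, ]
    x1 <- x[i[1]]; x2 <- x[i[2]]; x3 <- x[i[3]]
    y1 <- y[i[1]]; y2 <- y[i[2]]; y3 <- y[i[3]]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(det) < 1e-300) next
    ix <- which(xo >= min(x1, x2, x3) - tol & xo <= max(x1, x2, x3) + tol)
    iy <- which(yo >= min(y1, y2, y3) - tol & yo <= max(y1, y2, y3) + tol)
    if (!length(ix) || !length(iy)) next
    px <- rep(xo[ix], times = length(iy))
    py <- rep(yo[iy], each = length(ix))
    l1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / det
    l2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / det
    l3 <- 1 - l1 - l2
    ok <- l1 >= -tol & l2 >= -tol & l3 >= -tol
    if (any(ok)) {
      v <- l1 * z[i[1]] + l2 * z[i[2]] + l3 * z[i[3]]
      w <- which(ok)
      out[cbind(ix[(w - 1L) %% length(ix) + 1L],
                iy[(w - 1L) %/% length(ix) + 1L])] <- v[ok]
    }
  }
  out
}

#' Recentre a grid on the foveal centre
#'
#' Resamples the grid so that the node at the grid origin corresponds to the
#' located foveal centre, establishing the fovea-centred coordinate system
#' used for sectorization. Margins shifted outside the original field are
#' marked missing.
#'
#' @param grid A [thickness_grid()].
#' @param fovea Foveal centre: numeric `c(x, y)` in mm, or a one-row data
#'   frame with columns `x` and `y` as returned by [locate_fovea()].
#' @return A fovea-centred `thickness_grid` (`centered = TRUE`).
#' @export
recenter <- function(grid, fovea) {
  stopifnot(inherits(grid, "thickness_grid"))
  if (is.data.frame(fovea)) fovea <- c(fovea$x[1], fovea$y[1])
  fovea <- as.numeric(fovea)
  if (length(fovea) != 2 || !all(is.finite(fovea))) {
    abort("`fovea` must be finite coordinates c(x, y) in mm.")
  }
  if (any(abs(fovea) > grid$extent / 2)) {
    abort("Foveal centre lies outside the field: cannot recentre.")
  }
  ax <- grid_axes(grid)
  if (all(abs(fovea) < 1e-12)) {
    grid$centered <- TRUE
    return(grid)
  }
  pts <- expand.grid(x = ax$x, y = ax$y)
  z <- grid_eval(grid, pts$x + fovea[1], pts$y + fovea[2])
  grid$values <- matrix(z, length(ax$x), length(ax$y))
  grid$centered <- TRUE
  grid
}
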