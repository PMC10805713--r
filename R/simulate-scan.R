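#' Configuration for synthetic macular scans
#'
#' Parameters of the synthetic scattered-thickness generator. The GCIPL
#' field is a smooth unimodal ring profile (thin at the fovea, peaking near
#' 1 mm radius, declining outward) plus an optional linear nasal-temporal
#' asymmetry; the total-retinal-thickness (TRT) field is a plateau with a
#' Gaussian foveal pit whose unique minimum sits at `fovea_offset`. Both
#' fields are sampled at scattered points with i.i.d. Gaussian noise.
#'
#' @param extent Field width in mm (default 6, i.e. 6x6 mm).
#' @param n_points Number of scattered sample points (default 8000).
#' @param pit_depth Depth of the foveal pit in the TRT field (µm).
#' @param pit_radius Gaussian radius of the pit (mm); must be > 0.
#' @param trt_base TRT plateau level (µm).
#' @param gcipl_floor GCIPL level at the fovea and beyond 2 mm radius (µm).
#' @param asymmetry Linear nasal-temporal GCIPL gradient (µm per mm, in
#'   right-eye orientation). Being odd about the fovea it does not change
#'   any full-annulus mean.
#' @param noise_sd Measurement noise SD (µm); >= 0.
#' @param laterality `"OD"` or `"OS"`. Left-eye scans are generated in
#'   their native (mirrored) coordinates.
#' @param fovea_offset Displacement `c(x, y)` of the true pit centre from
#'   the field centre, in the eye's native coordinates (mm).
#' @return A `map_config` list.
#' @export
map_config <- function(extent = 6, n_points = 8000, pit_depth = 100,
                       pit_radius = 0.6, trt_base = 320, gcipl_floor = 40,
                       asymmetry = 1.5, noise_sd = 0,
                       laterality = c("OD", "OS"), fovea_offset = c(0, 0)) {
  laterality <- match.arg(laterality)
  if (extent <= 0) abort("`extent` must be > 0.")
  if (pit_radius <= 0) abort("`pit_radius` must be > 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (length(fovea_offset) != 2 || !all(is.finite(fovea_offset))) {
    abort("`fovea_offset` must be finite c(x, y) in mm.")
  }
  structure(
    list(
      extent = extent, n_points = n_points, pit_depth = pit_depth,
      pit_radius = pit_radius, trt_base = trt_base,
      gcipl_floor = gcipl_floor, asymmetry = asymmetry,
      noise_sd = noise_sd, laterality = laterality,
      fovea_offset = fovea_offset
    ),
    class = "map_config"
  )
}

# Ring-shaped radial basis b(r) = r^2 (2 - r)^2 on [0, 2], 0 beyond.
# Its mean over the annulus of radii 0.5-1.5 mm has the closed form
# (2 / (r2^2 - r1^2)) * int_{r1}^{r2} r^3 (2 - r)^2 dr = 0.84583333...
gcipl_basis <- function(r) {
  ifelse(r < 2, r^2 * (2 - r)^2, 0)
}

gcipl_basis_annulus_mean <- function(r1 = 0.5, r2 = 1.5) {
  prim <- function(r) r^4 - 0.8 * r^5 + r^6 / 6
  2 * (prim(r2) - prim(r1)) / (r2^2 - r1^2)
}

#' Radial GCIPL profile of the synthetic scan
#'
#' The noise-free GCIPL field as a function of distance `r` from the foveal
#' centre, scaled so that its analytic mean over the parafoveal annulus
#' (radii 0.5-1.5 mm) equals `target_pfgcipl` exactly.
#'
#' @param r Radii in mm.
#' @param target_pfgcipl Target parafoveal annulus mean (µm); must be > 0.
#' @param gcipl_floor Level at the fovea and periphery (µm).
#' @return GCIPL thickness values (µm).
#' @export
gcipl_profile <- function(r, target_pfgcipl, gcipl_floor = 40) {
  if (target_pfgcipl <= 0) abort("`target_pfgcipl` must be > 0.")
  a <- (target_pfgcipl - gcipl_floor) / gcipl_basis_annulus_mean()
  gcipl_floor + a * gcipl_basis(r)
}

#' Simulate a scattered macular thickness scan
#'
#' Generates per-eye scattered samples of a GCIPL field and a
#' total-retinal-thickness (TRT) field over the macular square. The
#' noise-free analytic mean of the GCIPL field over the 1-3 mm-diameter
#' annulus centred on the (offset) fovea equals `target_pfgcipl` exactly, so
#' the downstream grid + sectorization pipeline can be checked against a
#' closed-form truth.
#'
#' @param config A [map_config()].
#' @param target_pfgcipl Parafoveal GCIPL annulus mean to generate (µm).
#' @param seed Optional integer seed for reproducibility.
#' @return Tibble with columns `x`, `y` (mm, native eye coordinates),
#'   `gcipl` and `trt` (µm), carrying attributes `extent`, `laterality` and
#'   `truth` (list with the target, the native-frame `fovea_offset` and the
#'   config).
#' @export
simulate_macular_scan <- function(config = map_config(), target_pfgcipl = 92,
                                  seed = NULL) {
  stopifnot(inherits(config, "map_config"))
  if (target_pfgcipl <= 0) abort("`target_pfgcipl` must be > 0.")
  run <- function() {
    half <- config$extent / 2
    x <- runif(config$n_points, -half, half)
    y <- runif(config$n_points, -half, half)
    f <- scan_fields(config, target_pfgcipl, x, y)
    gcipl <- f$gcipl + rnorm(config$n_points, 0, config$noise_sd)
    trt <- f$trt + rnorm(config$n_points, 0, config$noise_sd)
    out <- tibble(x = x, y = y, gcipl = gcipl, trt = trt)
    attr(out, "extent") <- config$extent
    attr(out, "laterality") <- config$laterality
    attr(out, "truth") <- list(
      target_pfgcipl = target_pfgcipl,
      fovea_offset = config$fovea_offset,
      config = config
    )
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Noise-free field values at native coordinates (x, y). Internally the
# field lives in right-eye orientation; OS scans are evaluated through the
# mirror so that OD/OS pairs with mirrored offsets are exact mirror images.
scan_fields <- function(config, target_pfgcipl, x, y) {
  os <- config$laterality == "OS"
  u <- if (os) -x else x
  u0 <- if (os) -config$fovea_offset[1] else config$fovea_offset[1]
  v0 <- config$fovea_offset[2]
  du <- u - u0
  dv <- y - v0
  r <- sqrt(du^2 + dv^2)
  gcipl <- gcipl_profile(r, target_pfgcipl, config$gcipl_floor) +
    config$asymmetry * du
  trt <- config$trt_base -
    config$pit_depth * exp(-r^2 / (2 * config$pit_radius^2))
  list(gcipl = gcipl, trt = trt)
}

#' Read / write scattered thickness samples as delimited text
#'
#' Scans are stored as a plain CSV of `x, y, <layers...>` plus a JSON
#' sidecar (same path with extension `.json`) holding the geometry metadata
#' (field extent and laterality).
#'
#' @param data A scan tibble (see [simulate_macular_scan()]).
#' @param path CSV file path.
#' @return `write_scatter` returns `path` invisibly; `read_scatter` returns
#'   the scan tibble with its attributes restored.
#' @export
write_scatter <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE)
  meta <- list(
    extent = attr(data, "extent") %||% 6,
    laterality = attr(data, "laterality") %||% "OD"
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scatter
#' @export
read_scatter <- function(path) {
  out <- as_tibble(read.csv(path))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(out, "extent") <- meta$extent
    attr(out, "laterality") <- meta$laterality
  }
  out
}
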