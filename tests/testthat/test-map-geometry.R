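test_that("interpolation reproduces gridded input exactly", {
  ax <- seq(-3, 3, length.out = 40)
  pts <- expand.grid(x = ax, y = ax)
  pts$value <- sin(pts$x) + cos(pts$y) + 100
  g <- interpolate_to_grid(pts, value, n = 40)
  expect_equal(g$values, matrix(pts$value, 40, 40), tolerance = 1e-12)
  expect_equal(sum(is.na(g$values)), 0)
})

test_that("interpolation is exact for affine fields", {
  set.seed(101)
  pts <- tibble::tibble(x = runif(1000, -3, 3), y = runif(1000, -3, 3))
  pts$value <- 2 * pts$x + 3 * pts$y + 80
  g <- interpolate_to_grid(pts, value, n = 120)
  ax <- grid_axes(g)
  truth <- outer(ax$x, ax$y, function(a, b) 2 * a + 3 * b + 80)
  err <- abs(g$values - truth)
  expect_lt(max(err, na.rm = TRUE), 1e-9)
  # corners outside the convex hull are missing, interior is covered
  expect_gt(sum(is.na(g$values)), 0)
  expect_false(anyNA(g$values[40:80, 40:80]))
})

test_that("interpolation preserves constants and the input value range", {
  set.seed(102)
  pts <- tibble::tibble(x = runif(300, -3, 3), y = runif(300, -3, 3),
                        value = 89.8)
  g <- interpolate_to_grid(pts, value, n = 60)
  expect_lt(max(abs(na.omit(as.vector(g$values)) - 89.8)), 1e-10)
  pts$value <- rnorm(300, 90, 10)
  g2 <- interpolate_to_grid(pts, value, n = 60)
  expect_gte(min(g2$values, na.rm = TRUE), min(pts$value))
  expect_lte(max(g2$values, na.rm = TRUE), max(pts$value))
})

test_that("degenerate scatter geometry is rejected", {
  expect_error(
    interpolate_to_grid(tibble::tibble(x = 1:2, y = 1:2, value = 1:2)),
    "at least 3"
  )
  expect_error(
    interpolate_to_grid(
      tibble::tibble(x = seq(-2, 2, length.out = 20),
                     y = 2 * seq(-2, 2, length.out = 20), value = 1:20)
    ),
    "collinear"
  )
})

test_that("horizontal mirroring is an involution and flips orientation", {
  set.seed(103)
  g <- thickness_grid(matrix(rnorm(900, 90, 5), 30, 30), laterality = "OS")
  m <- mirror_horizontal(g)
  expect_false(identical(m$values, g$values))
  expect_identical(mirror_horizontal(m)$values, g$values)
  expect_identical(m$orientation, "right")
})

test_that("flip_left_eye normalizes OS maps and passes OD maps through", {
  set.seed(104)
  vals <- matrix(rnorm(900, 90, 5), 30, 30)
  od <- thickness_grid(vals, laterality = "OD")
  expect_identical(flip_left_eye(od), od)
  os <- thickness_grid(vals[rev(seq_len(30)), ], laterality = "OS")
  flipped <- flip_left_eye(os)
  expect_identical(flipped$values, vals)
  expect_identical(flipped$orientation, "right")
  # already-normalized maps are not flipped again
  expect_identical(flip_left_eye(flipped), flipped)
  bad <- od
  bad$laterality <- NA
  expect_error(flip_left_eye(bad), "laterality")
})

test_that("recentring translates the field and inverts up to border loss", {
  f <- function(x, y) 100 + 3 * x - 2 * y
  g <- grid_from_function(f, n = 101)
  g$centered <- FALSE
  h <- grid_axes(g)$spacing
  shift <- c(5 * h, -3 * h)  # exactly k node spacings
  rc <- recenter(g, shift)
  ax <- grid_axes(g)
  truth <- outer(ax$x, ax$y, function(a, b) f(a + shift[1], b + shift[2]))
  interior <- !is.na(rc$values)
  expect_lt(max(abs(rc$values - truth)[interior]), 1e-9)
  expect_true(rc$centered)
  # identity when the fovea is already central
  expect_identical(recenter(g, c(0, 0))$values, g$values)
  # shift then inverse shift recovers the interior
  back <- recenter(rc, -shift)
  interior2 <- !is.na(back$values)
  expect_lt(max(abs(back$values - g$values)[interior2]), 1e-9)
  expect_error(recenter(g, c(4, 0)), "outside the field")
})

test_that("fovea localization recovers symmetric and offset pits", {
  pit <- function(cx, cy) {
    function(x, y) {
      320 - 100 * exp(-((x - cx)^2 + (y - cy)^2) / (2 * 0.6^2))
    }
  }
  g0 <- grid_from_function(pit(0, 0))
  fv0 <- locate_fovea(g0)
  expect_lt(sqrt(fv0$x^2 + fv0$y^2), grid_axes(g0)$spacing)
  expect_false(fv0$low_confidence)

  set.seed(105)
  gn <- grid_from_function(pit(0.4, -0.3))
  gn$values <- gn$values + matrix(rnorm(200 * 200, 0, 3), 200, 200)
  fv <- locate_fovea(gn, smoothing = 0.25)
  expect_lt(sqrt((fv$x - 0.4)^2 + (fv$y + 0.3)^2), 0.15)
})

test_that("degenerate maps are flagged or rejected by fovea localization", {
  flat <- grid_from_function(function(x, y) 0 * x + 250)
  fv <- locate_fovea(flat)
  expect_true(fv$low_confidence)
  expect_match(fv$reason, "no unique minimum")
  ramp <- grid_from_function(function(x, y) 200 + 10 * x)
  fvr <- locate_fovea(ramp)
  expect_true(fvr$low_confidence)
  expect_match(fvr$reason, "boundary")
  empty <- thickness_grid(matrix(NA_real_, 20, 20))
  expect_error(locate_fovea(empty), "missing")
})

test_that("smoothing is unbiased on constants and respects missingness", {
  g <- grid_from_function(function(x, y) 0 * x + 137.5, n = 60)
  g$values[1:5, 1:5] <- NA
  sm <- smooth_grid(g, sigma = 0.3)
  expect_lt(max(abs(na.omit(as.vector(sm$values)) - 137.5)), 1e-9)
  expect_true(all(is.na(sm$values[1:5, 1:5])))
})

test_that("eye averaging follows the one-or-two-eye rule", {
  eyes <- tibble::tibble(
    subject_id = c("A", "A", "B", "C", "C"),
    visit_time = 0,
    pfgcipl = c(90, 94, 88.2, 91, 91)
  )
  out <- average_eyes(eyes)
  expect_equal(out$pfgcipl[out$subject_id == "A"], 92)
  expect_equal(out$pfgcipl[out$subject_id == "B"], 88.2)
  expect_equal(out$pfgcipl[out$subject_id == "C"], 91)
  expect_equal(out$n_eyes, c(2L, 1L, 2L))
  # records with no usable values are dropped with a message
  eyes2 <- dplyr::bind_rows(
    eyes, tibble::tibble(subject_id = "D", visit_time = 0, pfgcipl = NA_real_)
  )
  expect_message(out2 <- average_eyes(eyes2), "no usable")
  expect_false("D" %in% out2$subject_id)
})
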