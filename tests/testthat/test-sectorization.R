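test_that("concentric schemes have the stated ring boundaries", {
  sc <- concentric_scheme(5, 0.5)
  expect_equal(sc$r_inner, c(0, 0.5, 1.0, 1.5, 2.0))
  expect_equal(sc$r_outer, c(0.5, 1.0, 1.5, 2.0, 2.5))
  one <- concentric_scheme(1, 3)
  expect_equal(nrow(one), 1)
  expect_equal(one$r_outer, 3)
  expect_error(concentric_scheme(5, 1), "exceeds the field")
  expect_error(concentric_scheme(0, 0.5), "positive integer")
})

test_that("quadrant splitting keeps the central disc whole", {
  sc <- quadrant_split(concentric_scheme(2, 0.5))
  expect_equal(nrow(sc), 5)  # disc + 4 quadrants of the outer ring
  expect_equal(sum(is.na(sc$theta_min)), 1)
  expect_setequal(
    sc$sector[!is.na(sc$theta_min)],
    paste0("ring2_", c("nasal", "superior", "temporal", "inferior"))
  )
  expect_error(quadrant_split(sc), "already split")
})

test_that("sector means conserve constants and sit within pixel bounds", {
  g <- grid_from_function(function(x, y) 0 * x + 89.8)
  sm <- sector_mean(g, quadrant_split(concentric_scheme()))
  expect_equal(sm$mean, rep(89.8, nrow(sm)), tolerance = 1e-12)
  set.seed(31)
  g2 <- grid_from_function(function(x, y) 90 + 0 * x)
  g2$values <- g2$values + matrix(rnorm(200 * 200, 0, 5), 200, 200)
  sm2 <- sector_mean(g2, concentric_scheme())
  expect_true(all(sm2$mean >= min(g2$values) & sm2$mean <= max(g2$values)))
})

test_that("the radial-field annulus mean matches the closed form", {
  # f(r) = r over the 1-3 mm-diameter annulus:
  # (2/3)(r2^3 - r1^3)/(r2^2 - r1^2) = 1.08333...
  g <- grid_from_function(function(x, y) sqrt(x^2 + y^2))
  pf <- extract_pfgcipl(g)
  closed_form <- (2 / 3) * (1.5^3 - 0.5^3) / (1.5^2 - 0.5^2)
  expect_equal(pf$pfgcipl, closed_form, tolerance = 0.005)
})

test_that("quadrant means are antisymmetric for a linear field", {
  g <- grid_from_function(function(x, y) x + 0 * y)
  sm <- sector_mean(g, quadrant_split(concentric_scheme(3, 0.5)))
  ring3 <- sm[sm$ring == 3 & !is.na(sm$mean), ]
  nasal <- ring3$mean[grepl("nasal", ring3$sector)]
  temporal <- ring3$mean[grepl("temporal", ring3$sector)]
  superior <- ring3$mean[grepl("superior", ring3$sector)]
  inferior <- ring3$mean[grepl("inferior", ring3$sector)]
  expect_equal(nasal, -temporal, tolerance = 1e-9)
  expect_gt(nasal, 0)
  # superior and inferior cancel; each is near zero up to the handful of
  # diagonal boundary nodes
  expect_equal(superior, -inferior, tolerance = 1e-9)
  expect_lt(abs(superior), 0.05)
})

test_that("quadrants partition each ring: areas and weighted means", {
  set.seed(33)
  g <- grid_from_function(function(x, y) 90 + x - 2 * y)
  g$values <- g$values + matrix(rnorm(200 * 200), 200, 200)
  rings <- sector_mean(g, concentric_scheme())
  quads <- sector_mean(g, quadrant_split(concentric_scheme()))
  for (k in 2:5) {
    qk <- quads[quads$ring == k, ]
    rk <- rings[rings$ring == k, ]
    # pixel counts per quadrant within 1% of a quarter of the ring
    expect_true(all(abs(qk$n_nodes / (rk$n_nodes / 4) - 1) < 0.01))
    # area(count)-weighted quadrant mean reproduces the ring mean exactly
    expect_equal(sum(qk$mean * qk$n) / sum(qk$n), rk$mean,
                 tolerance = 1e-12)
    expect_equal(sum(qk$n_nodes), rk$n_nodes)
  }
})

test_that("sector means agree with the per-pixel membership oracle", {
  set.seed(34)
  scheme <- quadrant_split(concentric_scheme(3, 0.5))
  for (i in 1:5) {
    g <- grid_from_function(function(x, y) 90 + rnorm(1) * x + rnorm(1) * y,
                            n = 60)
    g$values <- g$values + matrix(rnorm(60 * 60, 0, 3), 60, 60)
    got <- sector_mean(g, scheme)
    oracle <- brute_sector_means(g, scheme)
    expect_equal(got$mean, unname(oracle[got$sector]), tolerance = 1e-12)
  }
})

test_that("pfGCIPL extraction flags low coverage and handles constants", {
  g <- grid_from_function(function(x, y) 0 * x + 89.8)
  pf <- extract_pfgcipl(g)
  expect_equal(pf$pfgcipl, 89.8, tolerance = 1e-12)
  expect_false(pf$low_coverage)
  # knock out a fifth of the annulus
  ax <- grid_axes(g)
  g$values[ax$x > 0 & ax$x < 1.2, ] <- NA
  pf2 <- extract_pfgcipl(g)
  expect_true(pf2$low_coverage)
  expect_lt(pf2$coverage, 0.9)
})

test_that("empty sectors yield missing means with flags", {
  g <- grid_from_function(function(x, y) 0 * x + 90, n = 30)
  g$values[] <- NA
  g$values[15, 15] <- 90
  sm <- sector_mean(g, concentric_scheme())
  expect_true(all(sm$low_coverage[sm$n == 0]))
  expect_true(all(is.na(sm$mean[sm$n == 0])))
})

test_that("sector schemes serialize to JSON and back", {
  sc <- quadrant_split(concentric_scheme())
  path <- withr::local_tempfile(fileext = ".json")
  write_scheme(sc, path)
  back <- read_scheme(path)
  expect_equal(as.data.frame(back), as.data.frame(sc))
})
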