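test_that("box counts enumerate occupied lattice cells", {
  ln <- make_curve("line", image_side = 64)
  expect_equal(box_count(ln, 8), 8L)
  expect_equal(box_count(ln, 64), 1L)
  m <- make_mask(shape_spec("irregular", roughness = 0.4, seed = 4,
                            image_side = 128, base_radius = 32))
  b <- suppressWarnings(fuzzedge_filter(m)) > 0
  N <- vapply(c(2, 4, 8, 16, 32), function(e) box_count(b, e), 1L)
  expect_true(all(diff(N) < 0))
  expect_error(box_count(matrix(FALSE, 4, 4), 2), "empty")
})

test_that("fractal dimension recovers analytic values", {
  ln <- make_curve("line", image_side = 64)
  expect_equal(fractal_dimension(ln), 1.0, tolerance = 0.05)
  # straight-edged boundary of a filled square behaves like a line cover
  # (boxes well below the side length: a coarse lattice only quantises the
  # square's bounding box and inflates the slope through the corner deficit)
  sq <- make_mask(shape_spec("square", image_side = 512, base_radius = 128))
  border <- morph_gradient(sq) & sq
  expect_equal(fractal_dimension(border, sizes = c(2, 4, 8)), 1.0,
               tolerance = 0.05)
  # Koch curve at its self-similar scales
  k <- make_curve("koch", level = 4, image_side = 729)
  expect_equal(fractal_dimension(k, sizes = c(3, 9, 27, 81)),
               log(4) / log(3), tolerance = 0.1)
  expect_error(fractal_dimension(ln, sizes = c(2, 4)), "3 box sizes")
})

test_that("estimated dimension is stable under doubled resolution", {
  k3 <- make_curve("koch", level = 3, image_side = 243)
  k3b <- make_curve("koch", level = 3, image_side = 486)
  d1 <- fractal_dimension(k3, sizes = c(3, 9, 27))
  d2 <- fractal_dimension(k3b, sizes = c(6, 18, 54))
  expect_lt(abs(d1 - d2), 0.05)
})

test_that("convexity is exactly 1 for an axis-aligned square", {
  sq <- make_mask(shape_spec("square", image_side = 64, base_radius = 16))
  expect_equal(convexity(sq), 1.0, tolerance = 1e-6)
})

test_that("convexity matches the gift-wrapping hull oracle", {
  for (s in c(1, 6)) {
    m <- make_mask(shape_spec("irregular", roughness = 0.5, seed = s,
                              image_side = 128, base_radius = 32))
    ct <- fmlp:::trace_contour(m)
    oracle <- giftwrap_hull_perimeter(unique(ct)) / fmlp:::contour_perimeter(ct)
    expect_equal(convexity(m), oracle, tolerance = 1e-9)
    expect_lt(convexity(m), 0.97)
  }
})

test_that("disk convexity reflects only the digital-perimeter bias", {
  side <- 128; ctr <- (side + 1) / 2; r <- 50
  xy <- expand.grid(row = 1:side, col = 1:side)
  disk <- matrix(sqrt((xy$row - ctr)^2 + (xy$col - ctr)^2) <= r, side, side)
  cv <- convexity(disk)
  # hull perimeter ~ true circumference, while the (1, sqrt 2) chain-code
  # length overestimates a digital straight line of slope theta by the factor
  # cos(theta) + (sqrt(2)-1) sin(theta) <= 1.0824 (worst at 22.5 degrees)
  expect_gt(cv, 1 / 1.0824)
  expect_lte(cv, 1 + 0.05)
  ct <- fmlp:::trace_contour(disk)
  hull <- giftwrap_hull_perimeter(unique(ct))
  expect_equal(hull, 2 * pi * r, tolerance = 0.02 * 2 * pi * r)
})

test_that("convexity decreases as roughness grows", {
  cvs <- vapply(c(0, 0.2, 0.4, 0.6), function(rg) {
    sp <- shape_spec(if (rg == 0) "regular" else "irregular",
                     image_side = 128, base_radius = 32,
                     roughness = rg, seed = 21)
    convexity(make_mask(sp))
  }, 1.0)
  expect_true(all(diff(cvs) < 0))
})

test_that("multi-component masks fall back to the largest with a warning", {
  m <- matrix(FALSE, 40, 40)
  m[5:20, 5:20] <- TRUE
  m[30:32, 30:32] <- TRUE
  expect_warning(cv <- convexity(m), "largest")
  expect_equal(cv, 1.0, tolerance = 1e-6)
  expect_error(convexity(matrix(FALSE, 5, 5)), "empty")
})

test_that("feature vectors route fractal dimension to the border and convexity to the mask", {
  sq <- make_mask(shape_spec("square", image_side = 256, base_radius = 64))
  border <- extract_border(suppressWarnings(fuzzedge_filter(sq)))
  bmask <- matrix(FALSE, 256, 256)
  bmask[border] <- TRUE
  fv <- extract_features(sq, bmask, id = "sq", fd_sizes = c(2, 4, 8))
  expect_equal(fv$convexity, 1.0, tolerance = 1e-6)
  expect_equal(fv$fractal_dimension, 1.0, tolerance = 0.1)
  expect_identical(fv, extract_features(sq, bmask, id = "sq", fd_sizes = c(2, 4, 8)))
})

test_that("regular and irregular fixtures separate on both measures", {
  ft <- small_features()
  reg <- ft[ft$label == 1L, ]
  irr <- ft[ft$label == 0L, ]
  expect_gt(mean(irr$fractal_dimension), mean(reg$fractal_dimension))
  expect_gt(mean(reg$convexity), mean(irr$convexity))
  expect_gt(min(reg$convexity), max(irr$convexity))
})

test_that("class separation holds in the mean over many seeds", {
  seeds <- 1:50
  reg <- t(vapply(seeds, function(s) {
    m <- make_mask(shape_spec("regular", seed = s))
    b <- suppressWarnings(fuzzedge_filter(m)) > 0
    c(fractal_dimension(b, c(2, 4, 8, 16)), convexity(m))
  }, c(0, 0)))
  irr <- t(vapply(seeds, function(s) {
    m <- make_mask(shape_spec("irregular", roughness = 0.3, seed = s))
    b <- suppressWarnings(fuzzedge_filter(m)) > 0
    c(fractal_dimension(b, c(2, 4, 8, 16)), convexity(m))
  }, c(0, 0)))
  expect_gt(mean(irr[, 1]), mean(reg[, 1]))   # FD higher for irregular
  expect_gt(mean(reg[, 2]), mean(irr[, 2]))   # convexity higher for regular
  # estimated dimensions stay in the plausible band for closed borders
  expect_true(all(c(reg[, 1], irr[, 1]) > 0.9 & c(reg[, 1], irr[, 1]) < 2.1))
})
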