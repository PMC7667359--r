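test_that("slice decomposition preserves indexing and flags empty slices", {
  mask <- array(FALSE, dim = c(4, 5, 10))
  mask[2, 3, 7] <- TRUE
  img <- lesion_image(mask, c(1, 1, 5))
  sl <- slice_masks(img)
  expect_length(sl, 10)
  expect_equal(vapply(sl, `[[`, integer(1), "slice_index"), 1:10)
  expect_true(all(vapply(sl[-7], `[[`, logical(1), "empty")))
  expect_false(sl[[7]]$empty)
  expect_true(sl[[7]]$mask[2, 3])
})

test_that("a single pixel measures its physical diagonal for both a and b", {
  m <- matrix(FALSE, 3, 3); m[2, 2] <- TRUE
  f <- max_feret_diameter(slice_mask(m, c(1, 1)))
  expect_equal(f$length_cm, sqrt(2) / 10, tolerance = 1e-12)
  img <- array(FALSE, dim = c(3, 3, 2)); img[2, 2, 1] <- TRUE
  meas <- select_measurement_slice(lesion_image(img, c(1, 1, 5)))
  expect_equal(meas$a_cm, sqrt(2) / 10, tolerance = 1e-12)
  expect_equal(meas$b_cm, sqrt(2) / 10, tolerance = 1e-12)
})

test_that("axis-aligned rectangle: Feret is the corner diagonal, b the height", {
  m <- matrix(FALSE, 60, 30)
  m[6:55, 6:25] <- TRUE  # 50 x 20 pixels at 1 mm
  sl <- slice_mask(m, c(1, 1))
  f <- max_feret_diameter(sl)
  expect_equal(f$length_cm, sqrt(50^2 + 20^2) / 10, tolerance = 1e-12)
  expect_equal(f$length_cm, naive_feret_mm(m, c(1, 1)) / 10, tolerance = 1e-12)
  b <- orthogonal_diameter(sl, c(1, 0))  # along the 50 mm axis
  expect_equal(b$length_cm, 2.0, tolerance = 1e-12)
  expect_equal(abs(sum(b$direction * c(1, 0))), 0, tolerance = 1e-12)
})

test_that("rotated digital ellipse recovers its analytic axes", {
  sl <- digital_ellipse_slice(46, 24, theta = 30 * pi / 180)
  f <- max_feret_diameter(sl)
  expect_equal(f$length_cm, 9.2, tolerance = 0.15 / 9.2)
  b <- orthogonal_diameter(sl, f$direction)
  expect_equal(b$length_cm, 4.8, tolerance = 0.15 / 4.8)
  # against the exhaustive oracle, exactly
  expect_equal(f$length_cm, naive_feret_mm(sl$mask, sl$spacing) / 10,
               tolerance = 1e-12)
  expect_equal(b$length_cm,
               naive_perp_width_mm(sl$mask, sl$spacing, f$direction) / 10,
               tolerance = 1e-12)
})

test_that("a thin line measured along itself has single-pixel width", {
  m <- matrix(FALSE, 5, 34)
  m[3, 3:32] <- TRUE  # 30-pixel line
  b <- orthogonal_diameter(slice_mask(m, c(1, 1)), c(0, 1))
  expect_equal(b$length_cm, 0.1, tolerance = 1e-12)
})

test_that("hull-based Feret equals the exhaustive corner-pair maximum", {
  set.seed(101)
  for (rep in 1:60) {
    m <- random_mask(sample(3:40, 1), sample(3:40, 1), sample(1:80, 1))
    sp <- c(runif(1, 0.5, 2), runif(1, 0.5, 2))
    sl <- slice_mask(m, sp)
    expect_equal(max_feret_diameter(sl)$length_cm,
                 naive_feret_mm(m, sp) / 10, tolerance = 1e-12)
    expect_equal(feret_diameter_brute(sl)$length_cm,
                 naive_feret_mm(m, sp) / 10, tolerance = 1e-12)
  }
})

test_that("Feret dominates the orthogonal width in any direction", {
  set.seed(202)
  for (rep in 1:25) {
    sl <- slice_mask(random_mask(25, 25, sample(2:60, 1)), c(1, 1.3))
    f <- max_feret_diameter(sl)
    ang <- runif(4, 0, pi)
    for (a in ang) {
      b <- orthogonal_diameter(sl, c(cos(a), sin(a)))
      expect_lte(b$length_cm, f$length_cm + 1e-12)
    }
  }
})

test_that("Feret is rotation-invariant within two pixel diagonals", {
  lens <- vapply(seq(0, pi * 7 / 8, length.out = 8), function(th)
    max_feret_diameter(digital_ellipse_slice(30, 18, th))$length_cm,
    numeric(1))
  expect_lt(max(lens) - min(lens), 2 * sqrt(2) / 10)
  expect_true(all(abs(lens - 6.0) < 2 * sqrt(2) / 10))
})

test_that("adding lesion pixels never decreases the Feret diameter", {
  set.seed(303)
  m <- random_mask(30, 30, 5)
  prev <- max_feret_diameter(slice_mask(m, c(1, 1)))$length_cm
  for (rep in 1:30) {
    m[sample(which(!m), 3)] <- TRUE
    cur <- max_feret_diameter(slice_mask(m, c(1, 1)))$length_cm
    expect_gte(cur, prev - 1e-12)
    prev <- cur
  }
})

test_that("anisotropic spacing scales the measured extent", {
  m <- matrix(FALSE, 3, 12)
  m[2, 2:11] <- TRUE  # 10-pixel row along the column axis
  w1 <- orthogonal_diameter(slice_mask(m, c(1, 1)), c(1, 0))$length_cm
  w2 <- orthogonal_diameter(slice_mask(m, c(1, 2)), c(1, 0))$length_cm
  expect_equal(w1, 1.0, tolerance = 1e-12)
  expect_equal(w2, 2.0, tolerance = 1e-12)
})

test_that("measurement slice selection maximizes Feret and breaks ties low", {
  # axis-aligned ellipsoid: equatorial slice wins, a within one pixel of 2p
  img <- rasterize_lesion(lesion_spec(c(30, 18, 20), spacing = c(1, 1, 5),
                                      seed = 11))
  meas <- select_measurement_slice(img)
  per_slice <- vapply(Filter(function(s) !s$empty, slice_masks(img)),
                      function(s) max_feret_diameter(s)$length_cm, numeric(1))
  expect_equal(meas$a_cm, max(per_slice))
  expect_equal(meas$slice_index, (dim(img$mask)[3] + 1) / 2)
  expect_lt(abs(meas$a_cm - 6.0), sqrt(2) / 10)
  expect_gte(meas$a_cm, meas$b_cm)
  # duplicated slices tie to the lowest index
  m <- matrix(FALSE, 8, 8); m[3:6, 3:5] <- TRUE
  two <- array(FALSE, dim = c(8, 8, 4))
  two[, , 2] <- m; two[, , 4] <- m
  expect_equal(select_measurement_slice(lesion_image(two, c(1, 1, 5)))$slice_index, 2L)
})

test_that("slice counting ignores gaps and volumetry is count times voxel volume", {
  arr <- array(FALSE, dim = c(6, 6, 7))
  arr[3, 3, c(2, 5)] <- TRUE
  img <- lesion_image(arr, c(1, 1, 4))
  expect_equal(count_lesion_slices(img), 2L)
  expect_equal(volumetric_volume(img), 2 * 4 / 1000)
  cube <- lesion_image(array(TRUE, dim = c(10, 10, 10)), c(1, 1, 1))
  expect_equal(volumetric_volume(cube), 1.0)
  empty <- lesion_image(array(FALSE, dim = c(4, 4, 4)), c(1, 1, 1))
  expect_equal(count_lesion_slices(empty), 0L)
  expect_equal(volumetric_volume(empty), 0)
  expect_error(select_measurement_slice(empty), "empty")
})

test_that("degenerate inputs error explicitly", {
  sl <- slice_mask(matrix(FALSE, 3, 3), c(1, 1))
  expect_error(max_feret_diameter(sl), "empty")
  full <- slice_mask(matrix(TRUE, 2, 2), c(1, 1))
  expect_error(orthogonal_diameter(full, c(0, 0)), "nonzero")
  expect_error(lesion_image(array(0.5, dim = c(2, 2, 2)), c(1, 1, 1)))
  expect_error(lesion_image(array(0, dim = c(2, 2, 2)), c(1, 0, 1)))
})
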