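# Lumen volumetry, percent-change bookkeeping, Feret diameters

test_that("voxelized cylinder volume converges to pi r^2 L", {
  st <- make_segmentation_stack("cylinder", radius_mm = 10, length_mm = 100,
                                slice_thickness_mm = 0.5, pixel_mm = 0.5)
  v_exact <- pi * 1^2 * 10                      # 31.416 mL
  expect_rel(lumen_volume(st, 1L), v_exact, 0.01)
  # convergence: error shrinks with pixel size (non-special radius so the
  # rasterization error does not accidentally coincide across grids)
  err <- function(px) {
    s <- make_segmentation_stack("cylinder", 9.7, 20, 1, pixel_mm = px)
    abs(lumen_volume(s, 1L) - pi * 0.97^2 * 2)
  }
  e <- c(err(2), err(0.8), err(0.25))
  expect_lt(e[2], e[1])
  expect_lt(e[3], e[2])
})

test_that("volume is additive over slices and handles absent labels", {
  one <- make_segmentation_stack("cylinder", 8, 1, slice_thickness_mm = 1,
                                 pixel_mm = 0.5)
  two <- make_segmentation_stack("cylinder", 8, 2, slice_thickness_mm = 1,
                                 pixel_mm = 0.5)
  expect_equal(lumen_volume(two, 1L), 2 * lumen_volume(one, 1L),
               tolerance = 1e-12)
  expect_warning(v <- lumen_volume(one, 7L), "absent")
  expect_equal(v, 0)
})

test_that("percent change and multiplicative composition are mutually consistent", {
  expect_equal(percent_change(100, 120), 20)
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(50, 50 * 1.203), 20.3, tolerance = 1e-12)
  expect_error(percent_change(0, 10))
  expect_equal(compose_changes(c(20.3, -6.2)), 100 * (1.203 * 0.938 - 1),
               tolerance = 1e-12)
  expect_equal(compose_changes(5.5), 5.5)
  expect_equal(compose_changes(c(10, -10)), -1, tolerance = 1e-12)
  expect_error(compose_changes(c(10, -100)))
  # order independence and associativity
  set.seed(1)
  cs <- stats::runif(5, -30, 30)
  expect_equal(compose_changes(cs), compose_changes(rev(cs)),
               tolerance = 1e-12)
  expect_equal(compose_changes(c(compose_changes(cs[1:2]), cs[3:5])),
               compose_changes(cs), tolerance = 1e-12)
  # round-trip through volumes to machine precision
  a <- 37.2; b <- 45.1; c <- 41.8
  expect_equal(compose_changes(c(percent_change(a, b), percent_change(b, c))),
               percent_change(a, c), tolerance = 1e-12)
})

test_that("Feret diameter recovers circle and ellipse axes within the pixel diagonal", {
  # corner-based caliper of the rasterized region deviates from the
  # continuous diameter by at most the pixel diagonal
  px <- 0.5
  st <- make_segmentation_stack("cylinder", radius_mm = 10, length_mm = 2,
                                slice_thickness_mm = 1, pixel_mm = px)
  d <- max_diameter(st, 1L)
  expect_lt(abs(d$max_mm - 20), px * sqrt(2) + 1e-9)
  # ellipse with semi-axes a > b: maximum diameter is 2a
  n <- 101
  cc <- (seq_len(n) - (n + 1) / 2) * px
  ell <- outer(cc^2 / 12^2, cc^2 / 5^2, "+") < 1
  vol <- array(0L, dim = c(n, n, 1)); vol[, , 1][ell] <- 1L
  d2 <- max_diameter(vol, 1L, pixel_mm = px)
  expect_lt(abs(d2$max_mm - 24), px * sqrt(2) + 1e-9)
  # single pixel: pixel diagonal by convention
  vp <- array(0L, dim = c(5, 5, 1)); vp[3, 3, 1] <- 1L
  expect_equal(max_diameter(vp, 1L, pixel_mm = px)$max_mm, px * sqrt(2))
  expect_error(max_diameter(vp, 2L, pixel_mm = px), "absent")
})

test_that("label volumes round-trip through NIfTI and summarise correctly", {
  st <- make_segmentation_stack("two_lumen", radius_mm = 10, length_mm = 10,
                                slice_thickness_mm = 1, pixel_mm = 0.5,
                                septum_mm = 2)
  f <- tempfile(fileext = ".nii.gz")
  write_labels_nifti(st, f)
  st2 <- read_labels_nifti(f)
  expect_equal(st2$labels, st$labels, ignore_attr = TRUE)
  expect_equal(st2$pixel_mm, 0.5, tolerance = 1e-6)
  m <- lumen_morphology(st)
  expect_equal(m$tl_volume_mL, m$fl_volume_mL, tolerance = 1e-12) # symmetric
  expect_true(m$tl_maxdiam_mm < 21 && m$tl_maxdiam_mm > 15)
})
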