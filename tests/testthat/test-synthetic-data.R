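# Synthetic acquisition generators

test_that("inlet waveform peaks at mid-systole and has the half-sine mean", {
  w <- make_inlet_waveform(0.78, 10, 0.35, 20)
  expect_equal(w$period_s, 0.78)
  expect_true(all(w$flow >= 0))
  # peak at mid-systole within one sample of the analytic maximum
  ts <- 0.35 * 0.78
  expect_lt(abs(w$time_s[which.max(w$flow)] - ts / 2), 0.78 / 20 + 1e-12)
  expect_lte(max(w$flow), 10)
  expect_gt(max(w$flow), 9.5)   # a sample lands close to the peak
  # analytic cycle mean of the half-sine: peak * 2 * frac / pi; converges
  # with frame count (trapezoid consistency)
  w2 <- make_inlet_waveform(1, 6, 0.5, 10000)
  expect_equal(cycle_mean(w2), 6 / pi, tolerance = 1e-6)
  tt <- c(w2$time_s, 1)
  expect_equal(pracma::trapz(tt, c(w2$flow, w2$flow[1])), 6 / pi,
               tolerance = 1e-6)
  # degenerate inputs
  expect_equal(max(abs(make_inlet_waveform(1, 0, 0.4, 8)$flow)), 0)
  expect_error(make_inlet_waveform(1, 5, 0.4, 3))
})

test_that("phantom generation is deterministic given the seed", {
  a <- make_phantom_field(phantom_spec(rng_seed = 5, kind = "straight_tube"),
                          acquisition_params(frames_per_cycle = 4))
  b <- make_phantom_field(phantom_spec(rng_seed = 5, kind = "straight_tube"),
                          acquisition_params(frames_per_cycle = 4))
  expect_identical(a$field$v, b$field$v)
  d <- make_phantom_field(phantom_spec(rng_seed = 6, kind = "straight_tube"),
                          acquisition_params(frames_per_cycle = 4))
  expect_false(identical(a$field$v, d$field$v))
})

test_that("velocity respects the mask before noise and zero flow gives zero field", {
  ph <- tube_field(frames = 4)
  bg <- ph$field$mask == 0L
  for (k in 1:4) for (c3 in 1:3)
    expect_true(all(ph$field$v[, , , k, c3][bg] == 0))
  z <- make_phantom_field(phantom_spec(kind = "straight_tube",
                                       peak_inlet_flow_L_min = 0,
                                       rng_seed = 1),
                          acquisition_params(frames_per_cycle = 4,
                                             noise_sd_fraction_of_venc = 0))
  expect_true(all(z$field$v == 0))
})

test_that("grid coarser than 8 voxels across the diameter is rejected", {
  expect_error(
    make_phantom_field(phantom_spec(kind = "straight_tube", radius_mm = 6),
                       acquisition_params(voxel_mm = 2)),
    "too coarse")
})

test_that("segmentation stack volume matches the analytic cylinder", {
  st <- make_segmentation_stack("cylinder", radius_mm = 10, length_mm = 100,
                                slice_thickness_mm = 0.5, pixel_mm = 0.5)
  expect_rel(lumen_volume(st, 1L), pi * 1^2 * 10, 0.01)  # 31.416 mL
  # zero length -> zero volume
  st0 <- make_segmentation_stack("cylinder", radius_mm = 10, length_mm = 0)
  expect_equal(dim(st0$labels)[3], 0)
  # two-lumen: TL/FL volume ratio equals the constant area ratio exactly
  st2 <- make_segmentation_stack("two_lumen", radius_mm = 10, length_mm = 20,
                                 slice_thickness_mm = 1, pixel_mm = 0.25,
                                 septum_mm = 1)
  a_tl <- sum(st2$labels[, , 1] == 1L)
  a_fl <- sum(st2$labels[, , 1] == 2L)
  expect_equal(lumen_volume(st2, 1L) / lumen_volume(st2, 2L), a_tl / a_fl,
               tolerance = 1e-12)
})

test_that("scenario cases have the right open-tear structure", {
  s1 <- make_case("S1-like")
  s2 <- make_case("S2-like")
  s2m <- make_case("S2mod-like")
  expect_equal(sum(s1$tears$open), 2)   # entry + naturally formed distal
  expect_equal(sum(s2$tears$open), 4)   # all four tears
  expect_equal(sum(s2m$tears$open), 3)
  # S2mod differs from S2 only in one open flag
  diff_cols <- s2$tears$open != s2m$tears$open
  expect_equal(sum(diff_cols), 1)
  expect_equal(s2$tears$id[diff_cols], "reentry21")
  s2a <- s2; s2a$tears$open <- s2m$tears$open
  expect_identical(unclass(s2a)[c("segments", "tears")],
                   unclass(s2m)[c("segments", "tears")])
  expect_error(make_case("S5"))
})

test_that("case JSON and waveform CSV round-trip", {
  tmp <- tempfile(fileext = ".json")
  cs <- make_case("S2mod-like")
  write_case_json(cs, tmp)
  cs2 <- read_case_json(tmp)
  expect_equal(cs2$tears$open, cs$tears$open)
  expect_equal(cs2$segments$radius_mm, cs$segments$radius_mm)
  w <- make_inlet_waveform(0.78, 10, 0.35, 16)
  f <- tempfile(fileext = ".csv")
  write_waveform_csv(w, f)
  w2 <- read_waveform_csv(f)
  expect_equal(w2$flow, w$flow)
  expect_equal(w2$period_s, w$period_s)
})

test_that("velocity fields round-trip through NIfTI", {
  ph <- tube_field(frames = 4, voxel_mm = 3)
  pre <- tempfile()
  write_field_nifti(ph$field, pre)
  f2 <- read_field_nifti(pre, origin_mm = ph$field$origin_mm)
  expect_equal(f2$v, ph$field$v, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(f2$mask, ph$field$mask, ignore_attr = TRUE)
  expect_equal(f2$voxel_mm, ph$field$voxel_mm, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(f2$period_s, ph$field$period_s, tolerance = 1e-5)
})
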