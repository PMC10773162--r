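#' 4D-flow style acquisition parameters
#'
#' Describes the synthetic "scanner": temporal resolution, frames per cycle,
#' voxel size, velocity-encoding limit (VENC) and the noise level expressed as
#' a fraction of VENC, mimicking velocity-encoded phase-contrast MRI noise.
#' Defaults follow a clinical 4D-flow protocol: 39.2 ms temporal resolution,
#' 20 frames/cycle, 2 mm isotropic voxels, VENC 150 cm/s.
#'
#' @param temporal_resolution_s Nominal temporal resolution in seconds.
#' @param frames_per_cycle Number of reconstructed cardiac phases (>= 2).
#' @param voxel_mm Voxel edge lengths in mm (length 1 or 3).
#' @param venc_cm_s Velocity encoding limit in cm/s.
#' @param noise_sd_fraction_of_venc Gaussian noise SD as a fraction of VENC,
#'   in `[0, 1)`. 0 disables noise.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(temporal_resolution_s = 0.0392,
                               frames_per_cycle = 20L,
                               voxel_mm = 2,
                               venc_cm_s = 150,
                               noise_sd_fraction_of_venc = 0.05) {
  stopifnot(frames_per_cycle >= 2, temporal_resolution_s > 0,
            all(voxel_mm > 0), venc_cm_s > 0,
            noise_sd_fraction_of_venc >= 0, noise_sd_fraction_of_venc < 1)
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  stopifnot(length(voxel_mm) == 3)
  structure(list(temporal_resolution_s = temporal_resolution_s,
                 frames_per_cycle = as.integer(frames_per_cycle),
                 voxel_mm = voxel_mm, venc_cm_s = venc_cm_s,
                 noise_sd_fraction_of_venc = noise_sd_fraction_of_venc),
            class = "acquisition_params")
}

#' Dissection phantom specification
#'
#' Geometry and driving waveform of the digital flow phantom: either a
#' straight circular tube or a two-lumen "dissected" tube in which a flat
#' septum splits the circular cross-section into a true lumen (TL) and a
#' false lumen (FL). Tear stations default to 70/210/260/320 mm from the
#' proximal end with ~5 mm diameters, matching a dissection with a proximal
#' entry tear, two mid re-entry tears and a distal re-entry tear.
#'
#' @param kind `"straight_tube"` or `"two_lumen_dissection"`.
#' @param radius_mm Outer lumen radius in mm.
#' @param septum_mm Full thickness of the dissection flap in mm (two-lumen
#'   kind only); flap voxels are background.
#' @param length_mm Tube length in mm.
#' @param tear_positions_mm Tear centres, mm from the proximal end, strictly
#'   increasing and inside the tube.
#' @param tear_diameters_mm Tear diameters in mm, recycled to the positions.
#' @param cycle_period_s Cardiac cycle period in seconds.
#' @param peak_inlet_flow_L_min Peak systolic inlet flow in L/min.
#' @param systolic_fraction Fraction of the cycle occupied by systole, (0,1).
#' @param tl_flow_fraction Fraction of through-plane flow carried by the TL
#'   (two-lumen kind), in (0,1).
#' @param rng_seed Integer seed making the generated noise reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("straight_tube", "two_lumen_dissection"),
                         radius_mm = 12, septum_mm = 2, length_mm = 60,
                         tear_positions_mm = c(70, 210, 260, 320),
                         tear_diameters_mm = 5,
                         cycle_period_s = 0.78,
                         peak_inlet_flow_L_min = 10,
                         systolic_fraction = 0.35,
                         tl_flow_fraction = 0.56,
                         rng_seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(radius_mm > 0, length_mm > 0, septum_mm >= 0,
            cycle_period_s > 0, peak_inlet_flow_L_min >= 0,
            systolic_fraction > 0, systolic_fraction < 1,
            tl_flow_fraction > 0, tl_flow_fraction < 1,
            all(tear_diameters_mm > 0))
  if (length(tear_positions_mm) &&
      any(diff(tear_positions_mm) <= 0))
    stop("tear positions must be strictly increasing")
  structure(list(kind = kind, radius_mm = radius_mm, septum_mm = septum_mm,
                 length_mm = length_mm,
                 tear_positions_mm = tear_positions_mm,
                 tear_diameters_mm = rep_len(tear_diameters_mm,
                                             length(tear_positions_mm)),
                 cycle_period_s = cycle_period_s,
                 peak_inlet_flow_L_min = peak_inlet_flow_L_min,
                 systolic_fraction = systolic_fraction,
                 tl_flow_fraction = tl_flow_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Half-sine inlet flow waveform
#'
#' Builds the canonical pulsatile inlet waveform: a half-sine systolic pulse
#' of duration `systolic_fraction * period` peaking at `peak_flow`, followed
#' by zero diastolic flow. The analytic cycle mean is
#' `peak_flow * 2 * systolic_fraction / pi`.
#'
#' @param period_s Cycle period in seconds.
#' @param peak_flow_L_min Peak systolic flow in L/min (0 gives an all-zero
#'   waveform).
#' @param systolic_fraction Fraction of the cycle in systole, (0,1).
#' @param frames Number of samples over the cycle (>= 4).
#' @return A [flow_waveform()].
#' @examples
#' w <- make_inlet_waveform(0.78, 10, 0.35, 20)
#' max(w$flow)      # peak near 10 L/min
#' cycle_mean(w)
#' @export
make_inlet_waveform <- function(period_s, peak_flow_L_min,
                                systolic_fraction = 0.35, frames = 20L) {
  stopifnot(period_s > 0, peak_flow_L_min >= 0,
            systolic_fraction > 0, systolic_fraction < 1)
  if (frames < 4) stop("frames must be >= 4")
  t <- (seq_len(frames) - 1) * period_s / frames
  ts <- systolic_fraction * period_s
  q <- ifelse(t < ts, peak_flow_L_min * sin(pi * t / ts), 0)
  flow_waveform(t, q, period_s = period_s)
}

#' Time-resolved velocity field on a voxel grid
#'
#' The in-memory stand-in for a 4D-flow MRI acquisition: a 5-D array of the
#' three velocity components (cm/s) on a regular grid over cardiac phases,
#' plus an integer lumen mask (0 background, 1 TL, 2 FL). World coordinates
#' are voxel-centre positions: `x_i = origin + (i - 1) * voxel`, in mm.
#'
#' @param v Numeric array `[nx, ny, nz, nt, 3]`, velocities in cm/s.
#' @param mask Integer array `[nx, ny, nz]` with labels 0/1/2.
#' @param voxel_mm Voxel edge lengths (mm), length 3.
#' @param time_s Frame times in seconds (length `nt`).
#' @param period_s Cycle period in seconds.
#' @param origin_mm World position of the centre of voxel (1,1,1), mm.
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(v, mask, voxel_mm, time_s, period_s,
                           origin_mm = c(0, 0, 0)) {
  stopifnot(length(dim(v)) == 5, dim(v)[5] == 3,
            all(dim(v)[1:3] == dim(mask)), dim(v)[4] == length(time_s),
            length(voxel_mm) == 3, all(voxel_mm > 0), period_s > 0)
  structure(list(v = v, mask = mask, voxel_mm = as.numeric(voxel_mm),
                 time_s = as.numeric(time_s), period_s = period_s,
                 origin_mm = as.numeric(origin_mm)),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$v)
  cat(sprintf("Velocity field: %d x %d x %d voxels (%.3g x %.3g x %.3g mm), %d frames over %.4g s\n",
              d[1], d[2], d[3], x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3],
              d[4], x$period_s))
  cat(sprintf("  lumen voxels: TL %d, FL %d; |v| max %.3g cm/s\n",
              sum(x$mask == 1L), sum(x$mask == 2L), max(abs(x$v))))
  invisible(x)
}

#' Generate a pulsatile phantom velocity field with lumen masks
#'
#' Builds the tube (or two-lumen) geometry on the acquisition grid, assigns a
#' quasi-parabolic (Poiseuille-shaped) axial profile in each lumen, and
#' rescales the profile every frame so that the discrete through-plane flow
#' rate (midpoint sum over voxel centres) equals the half-sine inlet waveform
#' exactly. For the two-lumen kind, the flow is split `tl_flow_fraction` /
#' `1 - tl_flow_fraction` between TL and FL. Velocity is exactly zero on
#' background voxels before noise; optional Gaussian noise with SD
#' `noise_sd_fraction_of_venc * venc` is then added to every component of
#' every voxel.
#'
#' The tube axis is the z axis; the grid spans the lumen diameter with a one
#' voxel margin. At least 8 voxels must resolve the diameter.
#'
#' @param spec A [phantom_spec()].
#' @param acq An [acquisition_params()].
#' @return A list with elements `field` (a [velocity_field()]) and
#'   `waveform` (the prescribed inlet [flow_waveform()]).
#' @export
make_phantom_field <- function(spec, acq = acquisition_params()) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(acq, "acquisition_params"))
  vox <- acq$voxel_mm
  if (2 * spec$radius_mm / vox[1] < 8 || 2 * spec$radius_mm / vox[2] < 8)
    stop(sprintf(paste0("grid too coarse: %.3g mm voxels resolve the %.3g mm",
                        " diameter with < 8 voxels; refine voxel_mm"),
                 max(vox[1:2]), 2 * spec$radius_mm))

  R <- spec$radius_mm
  nx <- ceiling(2 * (R + vox[1]) / vox[1])
  ny <- ceiling(2 * (R + vox[2]) / vox[2])
  nz <- max(2L, ceiling(spec$length_mm / vox[3]))
  # voxel-centre coordinates, tube axis through (0, 0)
  xc <- (seq_len(nx) - (nx + 1) / 2) * vox[1]
  yc <- (seq_len(ny) - (ny + 1) / 2) * vox[2]
  r2 <- outer(xc^2, yc^2, "+")
  inside <- r2 < R^2

  mask2d <- matrix(0L, nx, ny)
  if (spec$kind == "straight_tube") {
    mask2d[inside] <- 1L
  } else {
    half <- spec$septum_mm / 2
    tl <- inside & (matrix(xc, nx, ny) > half)
    fl <- inside & (matrix(xc, nx, ny) < -half)
    mask2d[tl] <- 1L
    mask2d[fl] <- 2L
  }

  profile <- pmax(1 - r2 / R^2, 0)  # unnormalised Poiseuille shape
  vox_area_mm2 <- vox[1] * vox[2]
  # discrete flow of the unit profile in each lumen: sum(profile) * area
  # (cm/s * mm^2 -> L/min conversion factor)
  cmmm2_to_Lmin <- 1e-2 * 1e-6 * 60000  # cm/s * mm^2 -> L/min
  wave <- make_inlet_waveform(spec$cycle_period_s, spec$peak_inlet_flow_L_min,
                              spec$systolic_fraction, acq$frames_per_cycle)
  nt <- acq$frames_per_cycle
  v <- array(0, dim = c(nx, ny, nz, nt, 3))
  labels <- if (spec$kind == "straight_tube") 1L else c(1L, 2L)
  fracs <- if (spec$kind == "straight_tube") 1 else
    c(spec$tl_flow_fraction, 1 - spec$tl_flow_fraction)
  for (li in seq_along(labels)) {
    sel <- mask2d == labels[li]
    unit_q <- sum(profile[sel]) * vox_area_mm2 * cmmm2_to_Lmin
    if (unit_q <= 0) stop("lumen ", labels[li], " contains no voxels")
    prof_l <- ifelse(sel, profile, 0)
    for (k in seq_len(nt)) {
      scale_k <- fracs[li] * wave$flow[k] / unit_q   # cm/s per unit profile
      if (scale_k != 0)
        v[, , , k, 3] <- v[, , , k, 3] +
          array(rep(prof_l * scale_k, nz), dim = c(nx, ny, nz))
    }
  }

  mask <- array(rep(mask2d, nz), dim = c(nx, ny, nz))
  if (acq$noise_sd_fraction_of_venc > 0) {
    set.seed(spec$rng_seed)
    v <- v + stats::rnorm(length(v),
                          sd = acq$noise_sd_fraction_of_venc * acq$venc_cm_s)
  }
  origin <- c(xc[1], yc[1], vox[3] / 2)
  fld <- velocity_field(v, mask, vox, wave$time_s, spec$cycle_period_s, origin)
  list(field = fld, waveform = wave)
}

#' Voxelized segmentation stack for morphometry
#'
#' Generates a label volume of a cylinder (label 1) or a two-lumen dissected
#' cylinder (TL 1, FL 2 split by a flat septum) using centre-sampling: a pixel
#' carries the label if its centre lies inside the shape. The analytic volume
#' of the cylinder is `pi * r^2 * L`.
#'
#' @param shape `"cylinder"` or `"two_lumen"`.
#' @param radius_mm Radius in mm.
#' @param length_mm Length in mm (0 gives zero slices).
#' @param slice_thickness_mm Slice thickness in mm.
#' @param pixel_mm In-plane pixel size in mm.
#' @param septum_mm Flap thickness for the two-lumen shape.
#' @return An object of class `label_volume`: list with `labels`
#'   (`[nx, ny, nslice]` integer array), `pixel_mm`, `slice_thickness_mm`.
#' @export
make_segmentation_stack <- function(shape = c("cylinder", "two_lumen"),
                                    radius_mm, length_mm,
                                    slice_thickness_mm = 1,
                                    pixel_mm = 0.5, septum_mm = 2) {
  shape <- match.arg(shape)
  stopifnot(radius_mm > 0, length_mm >= 0, slice_thickness_mm > 0,
            pixel_mm > 0)
  n <- ceiling(2 * (radius_mm + pixel_mm) / pixel_mm)
  cc <- (seq_len(n) - (n + 1) / 2) * pixel_mm
  r2 <- outer(cc^2, cc^2, "+")
  inside <- r2 < radius_mm^2
  sl <- matrix(0L, n, n)
  if (shape == "cylinder") {
    sl[inside] <- 1L
  } else {
    half <- septum_mm / 2
    sl[inside & matrix(cc, n, n) > half] <- 1L
    sl[inside & matrix(cc, n, n) < -half] <- 2L
  }
  nslice <- floor(length_mm / slice_thickness_mm)
  labels <- array(rep(sl, max(nslice, 0)), dim = c(n, n, nslice))
  structure(list(labels = labels, pixel_mm = pixel_mm,
                 slice_thickness_mm = slice_thickness_mm),
            class = "label_volume")
}

#' Dissection scenario case definitions
#'
#' Builds the tear-configuration cases used throughout the package, mirroring
#' a longitudinal dissection experiment: a baseline state with a proximal
#' entry tear and one naturally formed distal re-entry tear (`"S1-like"`), a
#' state after creation of two additional mid re-entry tears (`"S2-like"`,
#' 4 open tears), and a counterfactual in which the first mid tear is
#' occluded (`"S2mod-like"`, 3 open tears). Tear stations sit at 70, 210,
#' 260 and 320 mm from the arch. The created mid re-entry tears are 5 mm in
#' diameter; the entry tear and the naturally formed distal tear are larger
#' (default 22 and 12 mm), reflecting their measured axial extents.
#'
#' @param scenario One of `"S1-like"`, `"S2-like"`, `"S2mod-like"`.
#' @param tl_radius_mm,fl_radius_mm Lumped lumen radii in mm.
#' @param total_length_mm Length of the dissected aorta segment in mm.
#' @param tear_diameters_mm Diameters of the entry, two mid re-entry, and
#'   distal tears, mm.
#' @param branch_areas_mm2 Cross-sectional areas of the three lumped arch
#'   branches, mm^2.
#' @return An object of class `case_definition`: segment list, tear list
#'   (with `open` flags), branch areas and scenario label.
#' @export
make_case <- function(scenario = c("S1-like", "S2-like", "S2mod-like"),
                      tl_radius_mm = 7, fl_radius_mm = 9,
                      total_length_mm = 400,
                      tear_diameters_mm = c(22, 5, 5, 12),
                      branch_areas_mm2 = c(60, 30, 30)) {
  scenario <- match.arg(scenario)
  stations <- c(70, 210, 260, 320)
  open <- switch(scenario,
                 "S1-like"    = c(TRUE, FALSE, FALSE, TRUE),
                 "S2-like"    = c(TRUE, TRUE, TRUE, TRUE),
                 "S2mod-like" = c(TRUE, FALSE, TRUE, TRUE))
  tears <- data.frame(id = c("entry", "reentry21", "reentry26", "distal"),
                      position_mm = stations,
                      diameter_mm = rep_len(tear_diameters_mm, 4),
                      kind = c("entry", "re-entry", "re-entry", "re-entry"),
                      open = open, stringsAsFactors = FALSE)
  # TL: arch->70, 70->210, 210->260, 260->320, 320->distal end
  tl_breaks <- c(0, stations, total_length_mm)
  segments <- data.frame(
    from = c(paste0("tl", head(tl_breaks, -1))),
    to = c(paste0("tl", tl_breaks[-1])),
    length_mm = diff(tl_breaks),
    radius_mm = tl_radius_mm,
    lumen = "TL", stringsAsFactors = FALSE)
  fl_breaks <- stations
  fl_seg <- data.frame(
    from = paste0("fl", head(fl_breaks, -1)),
    to = paste0("fl", fl_breaks[-1]),
    length_mm = diff(fl_breaks),
    radius_mm = fl_radius_mm,
    lumen = "FL", stringsAsFactors = FALSE)
  structure(list(scenario = scenario,
                 segments = rbind(segments, fl_seg),
                 tears = tears,
                 branch_areas_mm2 = branch_areas_mm2,
                 tl_radius_mm = tl_radius_mm, fl_radius_mm = fl_radius_mm,
                 total_length_mm = total_length_mm),
            class = "case_definition")
}

#' @export
print.case_definition <- function(x, ...) {
  cat(sprintf("Dissection case %s: %d segments, %d tears (%d open)\n",
              x$scenario, nrow(x$segments), nrow(x$tears), sum(x$tears$open)))
  invisible(x)
}

#' Write / read a case definition as JSON
#' @param case A [make_case()] object.
#' @param path File path.
#' @return The case (read) or `path` invisibly (write).
#' @export
write_case_json <- function(case, path) {
  stopifnot(inherits(case, "case_definition"))
  jsonlite::write_json(unclass(case), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_case_json
#' @export
read_case_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$segments <- as.data.frame(x$segments)
  x$tears <- as.data.frame(x$tears)
  structure(x, class = "case_definition")
}
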