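#' Analysis plane through a velocity field
#'
#' A plane perpendicular to the vessel centerline on which flow rates, peak
#' velocities and lumen flow splits are evaluated. The unit normal points
#' distally along the centerline and defines the positive (forward) flow
#' direction.
#'
#' @param origin_mm A point on the plane, world coordinates in mm.
#' @param normal Plane normal (length 3); normalised internally, must be
#'   non-zero.
#' @param pitch_mm In-plane sampling pitch in mm.
#' @param lumen Which lumen to integrate over: `"TL"`, `"FL"` or `"both"`.
#' @param label Optional plane label (e.g. `"P2"`) used in messages.
#' @return An object of class `analysis_plane`.
#' @export
analysis_plane <- function(origin_mm, normal = c(0, 0, 1), pitch_mm = 0.5,
                           lumen = c("both", "TL", "FL"), label = "plane") {
  lumen <- match.arg(lumen)
  stopifnot(length(origin_mm) == 3, length(normal) == 3, pitch_mm > 0)
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("plane normal must be non-zero")
  structure(list(origin_mm = as.numeric(origin_mm),
                 normal = as.numeric(normal) / nn,
                 pitch_mm = pitch_mm, lumen = lumen, label = label),
            class = "analysis_plane")
}

# labels selected by a lumen choice
lumen_labels <- function(lumen)
  switch(lumen, TL = 1L, FL = 2L, both = c(1L, 2L))

# Trilinear interpolation of a 3-D array at continuous voxel indices
# (1-based). idx: n x 3 matrix. Out-of-grid indices are clamped.
interp3 <- function(a, idx) {
  d <- dim(a)
  ix <- pmin(pmax(idx[, 1], 1), d[1])
  iy <- pmin(pmax(idx[, 2], 1), d[2])
  iz <- pmin(pmax(idx[, 3], 1), d[3])
  x0 <- pmin(floor(ix), d[1] - 1); y0 <- pmin(floor(iy), d[2] - 1)
  z0 <- pmin(floor(iz), d[3] - 1)
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  g <- function(i, j, k) a[cbind(i, j, k)]
  v000 <- g(x0, y0, z0);     v100 <- g(x0 + 1, y0, z0)
  v010 <- g(x0, y0 + 1, z0); v110 <- g(x0 + 1, y0 + 1, z0)
  v001 <- g(x0, y0, z0 + 1); v101 <- g(x0 + 1, y0, z0 + 1)
  v011 <- g(x0, y0 + 1, z0 + 1); v111 <- g(x0 + 1, y0 + 1, z0 + 1)
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
  (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
  (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
  (v011 * (1 - fx) + v111 * fx) * fy * fz
}

# world mm -> continuous voxel index (1-based)
world_to_index <- function(field, pts) {
  sweep(sweep(pts, 2, field$origin_mm, "-"), 2, field$voxel_mm, "/") + 1
}

# masked (indicator-normalised) trilinear interpolation: interpolating
# v * 1_lumen and dividing by the interpolated indicator prevents the
# zero-velocity background from bleeding into near-wall samples
interp3_masked <- function(v3d, ind, idx) {
  w <- interp3(ind, idx)
  num <- interp3(v3d * ind, idx)
  ifelse(w > 1e-9, num / pmax(w, 1e-9), 0)
}

lumen_indicator <- function(field, lumen) {
  array(as.numeric(field$mask %in% lumen_labels(lumen)), dim = dim(field$mask))
}

# nearest-voxel mask label at world points
mask_at <- function(field, pts) {
  idx <- round(world_to_index(field, pts))
  d <- dim(field$mask)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
        idx[, 2] >= 1 & idx[, 2] <= d[2] &
        idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- rep(-1L, nrow(pts))
  if (any(ok)) out[ok] <- field$mask[idx[ok, , drop = FALSE]]
  out
}

# sample points of a plane covering the field's bounding box; returns the
# in-lumen points (mask-gated at voxel-centre nearest neighbour)
plane_sample_points <- function(field, plane) {
  n <- plane$normal
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * n) * n; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  ext <- dim(field$mask)[1:3] * field$voxel_mm
  half <- sqrt(sum(ext^2)) / 2
  u <- seq(-half, half, by = plane$pitch_mm)
  uv <- as.matrix(expand.grid(u = u, v = u))
  pts <- matrix(plane$origin_mm, nrow(uv), 3, byrow = TRUE) +
    uv[, 1] %*% t(e1) + uv[, 2] %*% t(e2)
  lab <- mask_at(field, pts)
  keep <- lab %in% lumen_labels(plane$lumen)
  list(pts = pts[keep, , drop = FALSE], n_total = nrow(pts))
}

#' Through-plane flow rate waveform
#'
#' Integrates the normal velocity component over the selected lumen's
#' intersection with the plane, per cardiac phase. The plane is resampled at
#' `pitch_mm` with trilinear interpolation of the velocity and
#' nearest-neighbour mask gating (midpoint rule in space).
#'
#' @param field A [velocity_field()].
#' @param plane An [analysis_plane()].
#' @return A [flow_waveform()] in L/min; positive flow is along the plane
#'   normal.
#' @export
plane_flow_rate <- function(field, plane) {
  stopifnot(inherits(field, "velocity_field"), inherits(plane, "analysis_plane"))
  sp <- plane_sample_points(field, plane)
  if (nrow(sp$pts) == 0)
    stop("plane '", plane$label, "' has empty intersection with lumen '",
         plane$lumen, "'")
  idx <- world_to_index(field, sp$pts)
  ind <- lumen_indicator(field, plane$lumen)
  nt <- dim(field$v)[4]
  q <- numeric(nt)
  area <- plane$pitch_mm^2              # mm^2 per sample point
  cmmm2_to_Lmin <- 1e-2 * 1e-6 * 60000  # cm/s * mm^2 -> L/min
  for (k in seq_len(nt)) {
    vn <- interp3_masked(field$v[, , , k, 1], ind, idx) * plane$normal[1] +
          interp3_masked(field$v[, , , k, 2], ind, idx) * plane$normal[2] +
          interp3_masked(field$v[, , , k, 3], ind, idx) * plane$normal[3]
    q[k] <- sum(vn) * area * cmmm2_to_Lmin
  }
  flow_waveform(field$time_s, q, period_s = field$period_s)
}

#' Reverse flow index (RFI) of a waveform
#'
#' The percentage of time-integrated flow moving against the forward
#' direction over one cycle:
#' \deqn{RFI = 100 \frac{|\int Q_{rev}\,dt|}{|\int Q_{rev}\,dt| + |\int Q_{fwd}\,dt|}}
#' with \eqn{Q_{fwd} = \max(Q, 0)}, \eqn{Q_{rev} = \min(Q, 0)} and trapezoid
#' integration over one period. An all-zero waveform returns 0 by convention
#' (the 0/0 case).
#'
#' @param w A [flow_waveform()] with at least 4 samples.
#' @return RFI in percent, in `[0, 100]`.
#' @export
rfi <- function(w) {
  stopifnot(inherits(w, "flow_waveform"))
  if (length(w$time_s) < 4) stop("rfi needs at least 4 samples over the period")
  fwd <- trapz_period(w$time_s, pmax(w$flow, 0), w$period_s)
  rev <- abs(trapz_period(w$time_s, pmin(w$flow, 0), w$period_s))
  if (fwd + rev == 0) return(0)
  100 * rev / (rev + fwd)
}

#' RFI through a tear, with the tear-direction convention
#'
#' Tear waveforms are signed with positive = TL-to-FL flow. Forward flow is
#' defined as TL-to-FL for the entry tear but FL-to-TL for re-entry tears, so
#' a re-entry tear's waveform is negated before computing [rfi()].
#'
#' @param w A [flow_waveform()], positive = TL-to-FL.
#' @param tear_kind `"entry"` or `"re-entry"`.
#' @return RFI in percent.
#' @export
tear_rfi <- function(w, tear_kind = c("entry", "re-entry")) {
  tear_kind <- match.arg(tear_kind)
  if (tear_kind == "re-entry")
    w <- flow_waveform(w$time_s, -w$flow, period_s = w$period_s)
  rfi(w)
}

#' True/false lumen flow distribution
#'
#' Percentages of cycle-mean net through-plane flow carried by each lumen:
#' `100 * mean(Q_TL) / (mean(Q_TL) + mean(Q_FL))` and its complement. The
#' result is flagged when either lumen's net flow is non-positive (the
#' percentages then fall outside `[0, 100]` and should be read with care).
#'
#' @param tl,fl [flow_waveform()]s for the two lumina on the same time base.
#' @return A list of class `flow_distribution`: `tl_pct`, `fl_pct`,
#'   `tl_mean`, `fl_mean` (L/min), `flagged`.
#' @export
flow_distribution <- function(tl, fl) {
  stopifnot(inherits(tl, "flow_waveform"), inherits(fl, "flow_waveform"))
  if (!isTRUE(all.equal(tl$time_s, fl$time_s)) ||
      !isTRUE(all.equal(tl$period_s, fl$period_s)))
    stop("TL and FL waveforms must share the same time base")
  qt <- cycle_mean(tl); qf <- cycle_mean(fl)
  if (qt + qf == 0) stop("total net flow is zero; flow distribution undefined")
  structure(list(tl_pct = 100 * qt / (qt + qf),
                 fl_pct = 100 * qf / (qt + qf),
                 tl_mean = qt, fl_mean = qf,
                 flagged = (qt <= 0 || qf <= 0)),
            class = "flow_distribution")
}

#' @export
print.flow_distribution <- function(x, ...) {
  cat(sprintf("Flow distribution: TL %.1f%% / FL %.1f%%%s\n",
              x$tl_pct, x$fl_pct,
              if (x$flagged) " [flagged: non-positive net flow in a lumen]" else ""))
  invisible(x)
}

#' Peak velocity on a plane
#'
#' Maximum velocity magnitude over the lumen-plane intersection, per cardiac
#' phase, and its maximum over the cycle (the peak systolic velocity when the
#' peak frame is systolic).
#'
#' @inheritParams plane_flow_rate
#' @return A list: `per_frame_cm_s` (length `nt`), `cycle_max_cm_s`.
#' @export
peak_velocity <- function(field, plane) {
  stopifnot(inherits(field, "velocity_field"), inherits(plane, "analysis_plane"))
  sp <- plane_sample_points(field, plane)
  if (nrow(sp$pts) == 0)
    stop("plane '", plane$label, "' has empty intersection with lumen '",
         plane$lumen, "'")
  idx <- world_to_index(field, sp$pts)
  ind <- lumen_indicator(field, plane$lumen)
  nt <- dim(field$v)[4]
  pf <- numeric(nt)
  for (k in seq_len(nt)) {
    vx <- interp3_masked(field$v[, , , k, 1], ind, idx)
    vy <- interp3_masked(field$v[, , , k, 2], ind, idx)
    vz <- interp3_masked(field$v[, , , k, 3], ind, idx)
    pf[k] <- max(sqrt(vx^2 + vy^2 + vz^2))
  }
  list(per_frame_cm_s = pf, cycle_max_cm_s = max(pf))
}

#' Area-weighted arch branch flow split
#'
#' Estimates per-branch cycle-mean flows from waveforms measured immediately
#' before and after a group of branches: the lost flow
#' `mean(Q_before) - mean(Q_after)` is distributed across the branches in
#' proportion to their cross-sectional areas. Conservation is exact:
#' the branch flows sum to the flow difference.
#'
#' @param q_before,q_after [flow_waveform()]s on the same time base.
#' @param branch_areas_mm2 Positive branch areas, mm^2.
#' @return Named numeric vector of cycle-mean branch flows (L/min), with
#'   attribute `flagged = TRUE` if the net branch flow is negative
#'   (nonphysical backflow into the branches; still computed).
#' @export
branch_flow_split <- function(q_before, q_after, branch_areas_mm2) {
  stopifnot(inherits(q_before, "flow_waveform"), inherits(q_after, "flow_waveform"),
            all(branch_areas_mm2 > 0))
  if (!isTRUE(all.equal(q_before$time_s, q_after$time_s)))
    stop("waveforms must share the same time base")
  dq <- cycle_mean(q_before) - cycle_mean(q_after)
  flagged <- dq < 0
  if (flagged)
    warning("net branch flow is negative (backflow into branches); computed anyway")
  out <- dq * branch_areas_mm2 / sum(branch_areas_mm2)
  names(out) <- paste0("branch", seq_along(branch_areas_mm2))
  attr(out, "flagged") <- flagged
  out
}

#' Extract an inlet velocity profile onto target mesh points
#'
#' Interpolates the in-plane velocity time series onto arbitrary target
#' points (e.g. the nodes of a CFD inlet mesh) and rescales each frame
#' uniformly so that the integrated flux over the target discretization
#' equals the plane flow rate on the source grid — a flux-conservative
#' mapping. Target points falling outside the masked lumen are zero-filled
#' and counted.
#'
#' @inheritParams plane_flow_rate
#' @param target_points_mm `n x 3` matrix of world points on the inlet plane.
#' @param point_area_mm2 Quadrature area per target point (scalar or length
#'   `n`); defaults to the plane pitch squared.
#' @return A list: `v_cm_s` (`n x nt x 3` array of rescaled velocities),
#'   `flux_L_min` (target-integrated flux per frame, equal to the source
#'   plane flow), `n_outside` (zero-filled target points).
#' @export
extract_inlet_profile <- function(field, plane, target_points_mm,
                                  point_area_mm2 = plane$pitch_mm^2) {
  stopifnot(is.matrix(target_points_mm), ncol(target_points_mm) == 3)
  q_src <- plane_flow_rate(field, plane)
  n <- nrow(target_points_mm)
  area <- rep_len(point_area_mm2, n)
  lab <- mask_at(field, target_points_mm)
  inside <- lab %in% lumen_labels(plane$lumen)
  idx <- world_to_index(field, target_points_mm)
  ind <- lumen_indicator(field, plane$lumen)
  nt <- dim(field$v)[4]
  v <- array(0, dim = c(n, nt, 3))
  cmmm2_to_Lmin <- 1e-2 * 1e-6 * 60000
  flux <- numeric(nt)
  for (k in seq_len(nt)) {
    vk <- sapply(1:3, function(c3)
      interp3_masked(field$v[, , , k, c3], ind, idx))
    vk[!inside, ] <- 0
    raw_flux <- sum((vk %*% plane$normal) * area) * cmmm2_to_Lmin
    s <- if (raw_flux != 0) q_src$flow[k] / raw_flux else 0
    v[, k, ] <- vk * s
    flux[k] <- raw_flux * s
  }
  list(v_cm_s = v, flux_L_min = flux, n_outside = sum(!inside))
}
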