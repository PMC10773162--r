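#' Lumen volume from a segmentation stack
#'
#' Slice-area summation: the volume of a labelled lumen is the sum over
#' axial slices of (labelled-pixel count x pixel area) x slice thickness.
#' Pixels belong to the lumen if their centre carries the label
#' (centre-sampling convention).
#'
#' @param vol A `label_volume` (from [make_segmentation_stack()] or
#'   [read_labels_nifti()]) or an integer array; in the latter case
#'   `pixel_mm` and `slice_thickness_mm` must be given.
#' @param label Integer label to measure (1 = TL, 2 = FL by convention).
#' @param pixel_mm,slice_thickness_mm Geometry when `vol` is a bare array.
#' @return Volume in mL. A label absent from the stack gives 0 with a
#'   warning.
#' @export
lumen_volume <- function(vol, label = 1L, pixel_mm = NULL,
                         slice_thickness_mm = NULL) {
  if (inherits(vol, "label_volume")) {
    pixel_mm <- vol$pixel_mm
    slice_thickness_mm <- vol$slice_thickness_mm
    vol <- vol$labels
  }
  stopifnot(!is.null(pixel_mm), !is.null(slice_thickness_mm),
            pixel_mm > 0, slice_thickness_mm > 0)
  n <- sum(vol == label)
  if (n == 0 && length(vol) > 0)
    warning("label ", label, " absent from the volume; returning 0")
  n * pixel_mm^2 * slice_thickness_mm / 1000   # mm^3 -> mL
}

#' Percent change between two volumes
#'
#' `100 * (v_new - v_ref) / v_ref`.
#'
#' @param v_ref Reference (earlier) volume; must be positive.
#' @param v_new New (later) volume.
#' @return Percent change.
#' @export
percent_change <- function(v_ref, v_new) {
  if (any(v_ref <= 0)) stop("reference volume must be positive")
  100 * (v_new - v_ref) / v_ref
}

#' Compose sequential percent changes multiplicatively
#'
#' Percent changes over consecutive intervals compose as a product of
#' ratios: `100 * (prod(1 + c_i/100) - 1)`. The composition is exact,
#' associative and order-independent, and satisfies
#' `compose_changes(c(percent_change(a, b), percent_change(b, c))) ==
#' percent_change(a, c)`.
#'
#' @param changes Numeric vector of percent changes, each `> -100`.
#' @return The composed percent change.
#' @examples
#' compose_changes(c(20.3, -6.2))  # 12.84
#' @export
compose_changes <- function(changes) {
  stopifnot(length(changes) >= 1)
  if (any(changes <= -100)) stop("each change must exceed -100 percent")
  100 * (prod(1 + changes / 100) - 1)
}

#' Maximum axial (Feret) diameter of a labelled region
#'
#' Per axial slice, the maximum caliper (Feret) diameter of the labelled
#' region, computed as the maximum pairwise distance between convex-hull
#' points of the labelled pixel squares (each pixel contributes its four
#' corners, so the caliper spans the full pixel extent); the global value is
#' the maximum over slices. A single-pixel region returns the pixel
#' diagonal.
#'
#' @inheritParams lumen_volume
#' @return A list: `per_slice_mm` (NA for slices without the label),
#'   `max_mm`.
#' @export
max_diameter <- function(vol, label = 1L, pixel_mm = NULL) {
  if (inherits(vol, "label_volume")) {
    pixel_mm <- vol$pixel_mm
    vol <- vol$labels
  }
  stopifnot(!is.null(pixel_mm), pixel_mm > 0)
  if (!any(vol == label)) stop("label ", label, " absent from the volume")
  nsl <- dim(vol)[3]
  h <- pixel_mm / 2
  per_slice <- vapply(seq_len(nsl), function(k) {
    idx <- which(vol[, , k] == label, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NA_real_)
    ctr <- idx * pixel_mm
    pts <- rbind(sweep(ctr, 2, c(-h, -h), "+"), sweep(ctr, 2, c(-h, h), "+"),
                 sweep(ctr, 2, c(h, -h), "+"), sweep(ctr, 2, c(h, h), "+"))
    hull <- if (nrow(pts) >= 3) pts[grDevices::chull(pts), , drop = FALSE]
            else pts
    max(stats::dist(hull))
  }, numeric(1))
  list(per_slice_mm = per_slice, max_mm = max(per_slice, na.rm = TRUE))
}

#' Morphometry summary of a segmentation stack
#'
#' @param vol A `label_volume`.
#' @return A data.frame of class `lumen_morphology`: TL/FL volumes (mL) and
#'   maximum axial diameters (mm; NA when a lumen is absent).
#' @export
lumen_morphology <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  has <- function(l) any(vol$labels == l)
  data.frame(
    tl_volume_mL = if (has(1L)) lumen_volume(vol, 1L) else 0,
    fl_volume_mL = if (has(2L)) lumen_volume(vol, 2L) else 0,
    tl_maxdiam_mm = if (has(1L)) max_diameter(vol, 1L)$max_mm else NA_real_,
    fl_maxdiam_mm = if (has(2L)) max_diameter(vol, 2L)$max_mm else NA_real_)
}
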