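#' Write / read a velocity field as NIfTI
#'
#' One 4-D NIfTI file (x, y, z, t) per velocity component plus a 3-D integer
#' mask volume, following the usual convention for 4D-flow derived data.
#' Voxel sizes are stored in the NIfTI pixdim (mm) and the frame interval in
#' the 4th pixdim slot (seconds); the cycle period is the frame interval
#' times the number of frames.
#'
#' @param field A [velocity_field()].
#' @param prefix Output path prefix; writes `<prefix>_vx.nii.gz`,
#'   `_vy`, `_vz` and `_mask.nii.gz`.
#' @return The prefix (write) or a [velocity_field()] (read), invisibly for
#'   write.
#' @export
write_field_nifti <- function(field, prefix) {
  stopifnot(inherits(field, "velocity_field"))
  dt <- field$period_s / length(field$time_s)
  comp <- c("vx", "vy", "vz")
  for (i in 1:3) {
    img <- RNifti::asNifti(field$v[, , , , i])
    RNifti::pixdim(img) <- c(field$voxel_mm, dt)
    RNifti::writeNifti(img, paste0(prefix, "_", comp[i], ".nii.gz"))
  }
  m <- RNifti::asNifti(field$mask + 0L)
  RNifti::pixdim(m) <- field$voxel_mm
  RNifti::writeNifti(m, paste0(prefix, "_mask.nii.gz"))
  invisible(prefix)
}

#' @rdname write_field_nifti
#' @param origin_mm World position of voxel (1,1,1) centre; not stored in
#'   the NIfTI header by this simple writer, so supply it on read if world
#'   coordinates matter.
#' @export
read_field_nifti <- function(prefix, origin_mm = c(0, 0, 0)) {
  comp <- c("vx", "vy", "vz")
  imgs <- lapply(comp, function(cc)
    RNifti::readNifti(paste0(prefix, "_", cc, ".nii.gz")))
  d <- dim(imgs[[1]])
  v <- array(0, dim = c(d, 3))
  for (i in 1:3) v[, , , , i] <- imgs[[i]]
  pd <- RNifti::pixdim(imgs[[1]])
  dt <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1 / d[4]
  mask <- RNifti::readNifti(paste0(prefix, "_mask.nii.gz"))
  velocity_field(v, array(as.integer(round(mask)), dim = d[1:3]),
                 voxel_mm = pd[1:3],
                 time_s = (seq_len(d[4]) - 1) * dt,
                 period_s = dt * d[4], origin_mm = origin_mm)
}

#' Write / read a label volume as NIfTI
#'
#' @param vol A `label_volume`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path` (write, invisibly) or a `label_volume` (read).
#' @export
write_labels_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  img <- RNifti::asNifti(vol$labels + 0L)
  RNifti::pixdim(img) <- c(vol$pixel_mm, vol$pixel_mm,
                           vol$slice_thickness_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_labels_nifti
#' @export
read_labels_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  structure(list(labels = array(as.integer(round(img)), dim = dim(img)),
                 pixel_mm = pd[1], slice_thickness_mm = pd[3]),
            class = "label_volume")
}
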