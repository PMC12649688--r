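#' CT-like volume container
#'
#' A `ct_volume` holds a 3D grid of Hounsfield Units together with its voxel
#' spacing and the room-frame position of the first voxel center. Axes are
#' ordered (x, y, z) with z the slice axis; the room frame has its origin at
#' the isocenter with X = left-right (LR), Y = superior-inferior (SI) and
#' Z = anterior-posterior (AP).
#'
#' @param values 3D numeric array of HU, dimensions `(nx, ny, nz)`.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, room-frame position (mm) of the center of
#'   voxel `(1, 1, 1)`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(values, spacing, origin = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (mm)")
  if (any(!is.finite(values)))
    stop("volume values must be finite")
  if (is.null(origin)) {
    # default: volume centered on the isocenter
    origin <- -(dim(values) - 1) / 2 * spacing
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm; HU range [%.0f, %.0f]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Room-frame coordinates of all voxel centers along one axis
#' @param vol a `ct_volume`
#' @param axis 1, 2 or 3
#' @return numeric vector of mm positions
#' @keywords internal
voxel_axis <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$origin[axis] + (seq_len(n) - 1) * vol$spacing[axis]
}

#' Insert mean-interpolated slices between adjacent CT slices
#'
#' Halves the slice spacing by inserting, midway between each adjacent pair of
#' slices, a new slice equal to their arithmetic mean. A volume with `n`
#' slices at spacing `s` becomes `2n - 1` slices at spacing `s / 2`; this is
#' the standard preparation step that takes 2 mm planning-CT slices to 1 mm
#' before DRR rendering.
#'
#' @param vol a `ct_volume` with at least 2 slices.
#' @return a `ct_volume` with `2 * nz - 1` slices and halved z spacing.
#' @export
interpolate_slices <- function(vol) {
  stopifnot(inherits(vol, "ct_volume"))
  d <- dim(vol$values)
  if (d[3] < 2L) stop("at least 2 slices are required for interpolation")
  nz <- 2L * d[3] - 1L
  out <- array(0, dim = c(d[1], d[2], nz))
  out[, , seq(1L, nz, by = 2L)] <- vol$values
  out[, , seq(2L, nz - 1L, by = 2L)] <-
    (vol$values[, , -d[3], drop = FALSE] + vol$values[, , -1L, drop = FALSE]) / 2
  ct_volume(out, c(vol$spacing[1:2], vol$spacing[3] / 2), vol$origin)
}

#' Dilate a fiducial marker into a high-HU sphere
#'
#' Sets every voxel whose center lies within `radius_mm` of `center` to a
#' fixed HU value, turning a point fiducial into a sphere that projects as a
#' clearly identifiable disc in a DRR (the marker-matching aid used when
#' pairing markers across stereo views).
#'
#' @param vol a `ct_volume`.
#' @param center mm triple; must lie inside the volume extent.
#' @param radius_mm sphere radius in mm (default 5, i.e. a 1 cm diameter ball).
#' @param hu HU value written into the sphere (default 3000).
#' @return the modified `ct_volume`.
#' @export
dilate_marker <- function(vol, center, radius_mm = 5, hu = 3000) {
  stopifnot(inherits(vol, "ct_volume"))
  center <- as.numeric(center)
  if (length(center) != 3L) stop("`center` must be a mm triple")
  lo <- vol$origin - vol$spacing / 2
  hi <- vol$origin + (dim(vol$values) - 1 + 0.5) * vol$spacing
  if (any(center < lo) || any(center > hi))
    stop("marker center lies outside the volume")
  xs <- voxel_axis(vol, 1) - center[1]
  ys <- voxel_axis(vol, 2) - center[2]
  zs <- voxel_axis(vol, 3) - center[3]
  # squared-distance field via outer sums, cheap relative to the volume itself
  d2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
  vol$values[d2 <= radius_mm^2] <- hu
  vol
}

#' Read / write volumes as NIfTI
#'
#' Thin NIfTI IO for `ct_volume` objects. The voxel spacing is stored in the
#' NIfTI pixdim; the room-frame origin is stored in the sform translation.
#'
#' @param vol a `ct_volume`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a `ct_volume`; `write_volume` returns `path`
#'   invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$values)
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  ct_volume(as.array(img), spacing = abs(diag(aff)[1:3]), origin = aff[1:3, 4])
}

#' Linear attenuation coefficient from HU
#'
#' Converts HU to a linear attenuation coefficient using
#' `mu = mu_water * (1 + HU / 1000)`, clamped at zero. Only relative
#' attenuation matters after DRR intensity rescaling.
#'
#' @param hu numeric HU values.
#' @param mu_water attenuation of water in 1/mm (default 0.02, kV range).
#' @return attenuation values in 1/mm, never negative.
#' @export
hu_to_mu <- function(hu, mu_water = 0.02) {
  pmax(mu_water * (1 + hu / 1000), 0)
}
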