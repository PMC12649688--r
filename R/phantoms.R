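#' Specification of a gelatin block phantom
#'
#' A cube or cylinder of gelatin (HU about 0) in air, optionally with
#' rectangular high-HU inserts such as aluminum blocks emulating bone. Used
#' to generate the static scenes on which noise characterization is
#' exercised.
#'
#' @param shape `"cube"` or `"cylinder"`.
#' @param outer_size outer dimension in mm (cube edge / cylinder diameter
#'   and height).
#' @param gelatin_hu HU of the gelatin body (default 0).
#' @param inserts list of inserts, each a list with `center` (mm triple),
#'   `extent` (mm triple, full widths) and `hu`.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("cube", "cylinder"), outer_size,
                         gelatin_hu = 0, inserts = list()) {
  shape <- match.arg(shape)
  if (outer_size <= 0) stop("outer_size must be positive")
  for (ins in inserts) {
    if (any(!is.finite(c(ins$center, ins$extent, ins$hu))))
      stop("insert fields must be finite")
    if (any(abs(ins$center) + ins$extent / 2 > outer_size / 2))
      stop("insert extends outside the phantom")
  }
  structure(list(shape = shape, outer_size = outer_size,
                 gelatin_hu = gelatin_hu, inserts = inserts),
            class = "phantom_spec")
}

#' Voxelize a gelatin block phantom
#'
#' Builds a `ct_volume` centered on the isocenter: air (-1000 HU) outside
#' the phantom, `gelatin_hu` inside, and each insert's HU inside its
#' axis-aligned box. Insert centers are phantom-local mm offsets from the
#' phantom center.
#'
#' @param spec a `phantom_spec`.
#' @param voxel_spacing mm triple (default 1 mm isotropic).
#' @param margin_mm air margin around the phantom (default 10 mm).
#' @return a `ct_volume`.
#' @export
make_block_phantom <- function(spec, voxel_spacing = c(1, 1, 1),
                               margin_mm = 10) {
  stopifnot(inherits(spec, "phantom_spec"))
  voxel_spacing <- as.numeric(voxel_spacing)
  if (any(voxel_spacing <= 0)) stop("voxel spacing must be positive")
  half <- spec$outer_size / 2
  n <- ceiling((spec$outer_size + 2 * margin_mm) / voxel_spacing)
  vol <- ct_volume(array(-1000, dim = n), voxel_spacing)
  xs <- voxel_axis(vol, 1); ys <- voxel_axis(vol, 2); zs <- voxel_axis(vol, 3)
  X <- array(xs, dim = n)
  Y <- aperm(array(ys, dim = n[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(zs, dim = n[c(3, 1, 2)]), c(2, 3, 1))
  inside <- if (spec$shape == "cube") {
    abs(X) <= half & abs(Y) <= half & abs(Z) <= half
  } else {
    # cylinder axis along z (SI view: axis vertical in room terms is y, but
    # the choice is immaterial for a synthetic phantom)
    X^2 + Y^2 <= half^2 & abs(Z) <= half
  }
  vol$values[inside] <- spec$gelatin_hu
  for (ins in spec$inserts) {
    sel <- abs(X - ins$center[1]) <= ins$extent[1] / 2 &
           abs(Y - ins$center[2]) <= ins$extent[2] / 2 &
           abs(Z - ins$center[3]) <= ins$extent[3] / 2
    vol$values[sel] <- ins$hu
  }
  vol
}

#' Synthetic thorax phantom with an ellipsoidal tumor and fiducial markers
#'
#' A low-HU lung background containing a soft-tissue ellipsoidal tumor and
#' point fiducial markers (one voxel each). The returned binary mask volume
#' is exactly the set of voxels whose centers fall inside the ellipsoid.
#' Markers placed within one voxel of each other trigger a warning (they
#' would be indistinguishable on projections) but not an error.
#'
#' @param tumor_center mm triple in room coordinates.
#' @param tumor_radii mm triple of ellipsoid semi-axes (> 0).
#' @param marker_centers list of mm triples (may be empty).
#' @param voxel_spacing mm triple (default 1 mm).
#' @param extent_mm full extent of the volume in mm (default 100).
#' @param lung_hu,tumor_hu,marker_hu tissue HU defaults -800 / 40 / 3000.
#' @return list with `volume` (`ct_volume`), `mask` (`ct_volume`, 0/1) and
#'   `markers` (list of mm triples snapped to voxel centers).
#' @export
make_thorax_phantom <- function(tumor_center, tumor_radii,
                                marker_centers = list(),
                                voxel_spacing = c(1, 1, 1),
                                extent_mm = 100,
                                lung_hu = -800, tumor_hu = 40,
                                marker_hu = 3000) {
  voxel_spacing <- as.numeric(voxel_spacing)
  if (any(voxel_spacing <= 0)) stop("voxel spacing must be positive")
  if (any(tumor_radii <= 0)) stop("tumor radii must be positive")
  n <- ceiling(extent_mm / voxel_spacing) * c(1, 1, 1)
  vol <- ct_volume(array(lung_hu, dim = n), voxel_spacing)
  half <- (n - 1) / 2 * voxel_spacing
  if (any(abs(tumor_center) + tumor_radii > half))
    stop("tumor extends outside the volume")
  xs <- voxel_axis(vol, 1); ys <- voxel_axis(vol, 2); zs <- voxel_axis(vol, 3)
  ex <- ((xs - tumor_center[1]) / tumor_radii[1])^2
  ey <- ((ys - tumor_center[2]) / tumor_radii[2])^2
  ez <- ((zs - tumor_center[3]) / tumor_radii[3])^2
  inside <- outer(outer(ex, ey, `+`), ez, `+`) <= 1
  vol$values[inside] <- tumor_hu
  mask <- array(0L, dim = n)
  mask[inside] <- 1L
  snapped <- list()
  used <- character()
  for (mc in marker_centers) {
    mc <- as.numeric(mc)
    if (any(abs(mc) > half)) stop("marker outside the volume")
    idx <- round((mc - vol$origin) / voxel_spacing) + 1
    key <- paste(idx, collapse = ",")
    if (key %in% used)
      warning("two markers share a voxel; they will be indistinguishable")
    used <- c(used, key)
    vol$values[idx[1], idx[2], idx[3]] <- marker_hu
    snapped[[length(snapped) + 1L]] <- vol$origin + (idx - 1) * voxel_spacing
  }
  list(volume = vol,
       mask = ct_volume(mask, voxel_spacing, vol$origin),
       markers = snapped)
}
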