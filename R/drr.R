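#' Detector pixel positions in room coordinates
#'
#' @param geom a `projection_geometry`.
#' @return a `3 x (W*H)` matrix of detector-pixel-center positions (mm), in
#'   the column-major order of an `H x W` image matrix (rows = y fastest).
#' @keywords internal
detector_points <- function(geom) {
  W <- geom$image_size[1]; H <- geom$image_size[2]
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  xs <- rep(0:(W - 1), each = H)   # column index, x
  ys <- rep(0:(H - 1), times = W)  # row index, y
  su <- (xs - cx) * geom$pixel_pitch
  sv <- (ys - cy) * geom$pixel_pitch
  t(cbind(geom$detector_center[1] + su * geom$u[1] + sv * geom$v[1],
          geom$detector_center[2] + su * geom$u[2] + sv * geom$v[2],
          geom$detector_center[3] + su * geom$u[3] + sv * geom$v[3]))
}

#' Render a digitally reconstructed radiograph
#'
#' Casts one ray per detector pixel from the source through the volume,
#' integrates the linear attenuation `mu = mu_water * (1 + HU/1000)` (clamped
#' at zero) with a fixed sampling step and trilinear interpolation, and maps
#' transmission `exp(-integral)` linearly to intensity so that an
#' unattenuated ray renders at 255. Air is bright, dense material dark.
#' Rays that miss the volume render at full brightness.
#'
#' @param vol a `ct_volume` in HU.
#' @param geom a `projection_geometry`.
#' @param mu_water water attenuation, 1/mm (default 0.02).
#' @param step ray sampling step in mm; default half the smallest voxel
#'   spacing.
#' @return an `H x W` numeric matrix with values in `[0, 255]` (float; round
#'   for an 8-bit frame).
#' @export
render_drr <- function(vol, geom, mu_water = 0.02, step = NULL) {
  stopifnot(inherits(vol, "ct_volume"), inherits(geom, "projection_geometry"))
  if (is.null(step)) step <- min(vol$spacing) / 2
  if (step <= 0) stop("`step` must be positive")
  mu <- hu_to_mu(vol$values, mu_water)
  integrals <- .drr_integrate(as.numeric(mu), dim(vol$values),
                              vol$spacing, vol$origin, geom$source,
                              detector_points(geom), step)
  matrix(255 * exp(-integrals),
         nrow = geom$image_size[2], ncol = geom$image_size[1])
}

#' Project a binary tumor mask volume with a voxel-count threshold
#'
#' A label pixel is set when its ray passes through at least `min_voxels`
#' distinct mask voxels, counted by exact voxel traversal along the ray.
#' Thin rims of a projected structure (few voxels deep along the ray) are
#' thereby excluded, which tightens label boundaries to the clearly visible
#' tumor core.
#'
#' @param mask_vol a `ct_volume` whose values are 0/1 (or logical).
#' @param geom a `projection_geometry`.
#' @param min_voxels minimum distinct mask voxels on the ray (default 7).
#' @return binary `H x W` integer matrix.
#' @export
project_label <- function(mask_vol, geom, min_voxels = 7L) {
  stopifnot(inherits(mask_vol, "ct_volume"))
  counts <- .ray_voxel_counts(as.integer(mask_vol$values != 0),
                              dim(mask_vol$values), mask_vol$spacing,
                              mask_vol$origin, geom$source,
                              detector_points(geom))
  matrix(as.integer(counts >= min_voxels),
         nrow = geom$image_size[2], ncol = geom$image_size[1])
}

#' 10 x 10 elliptical structuring element
#'
#' Inscribed-ellipse membership on a 10 x 10 grid (the even-sized elliptical
#' kernel convention of mainstream image libraries).
#' @return a 10 x 10 0/1 matrix.
#' @keywords internal
ellipse_kernel_10 <- function() {
  i <- matrix(0:9, 10, 10)        # rows
  j <- t(i)                       # cols
  k <- ((i - 4.5) / 5)^2 + ((j - 4.5) / 5)^2 <= 1
  storage.mode(k) <- "integer"
  k
}

#' Clean a binary label by elliptical opening and closing
#'
#' Morphological opening followed by closing with a 10 x 10 elliptical
#' structuring element, removing small isolated white regions and filling
#' minor black voids in projected tumor labels.
#'
#' @param label binary `H x W` matrix.
#' @param kernel structuring element; default the 10 x 10 ellipse.
#' @return binary integer matrix of the same size.
#' @export
clean_label <- function(label, kernel = ellipse_kernel_10()) {
  if (!all(label %in% c(0, 1))) stop("`label` must be binary")
  x <- EBImage::Image(t(label))  # EBImage is (x, y)-ordered
  opened <- EBImage::closing(EBImage::opening(x, kernel), kernel)
  out <- t(EBImage::imageData(opened))
  storage.mode(out) <- "integer"
  out
}

#' Standard background (SB) circular mask
#'
#' Binary mask equal to 1 inside the largest centered inscribed circle of the
#' frame and 0 outside, used to standardize the background of fluoroscopic
#' frames, DRRs and labels (radius `floor(min(W, H) / 2)` px around the image
#' geometric center).
#'
#' @param size `(width, height)` in px.
#' @return binary `H x W` integer matrix.
#' @export
standard_background_mask <- function(size) {
  W <- as.integer(size[1]); H <- as.integer(size[2])
  if (W <= 0L || H <= 0L) stop("mask size must be positive")
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  r <- floor(min(W, H) / 2)
  x <- matrix(0:(W - 1), H, W, byrow = TRUE)
  y <- matrix(0:(H - 1), H, W)
  m <- (x - cx)^2 + (y - cy)^2 <= r^2
  storage.mode(m) <- "integer"
  m
}

#' Apply an SB mask to a frame
#'
#' Zeroes all pixels outside the mask; elementwise `frame * mask`.
#' @param frame numeric `H x W` matrix.
#' @param mask binary matrix of the same size.
#' @return masked frame.
#' @export
apply_sb <- function(frame, mask) {
  if (!all(dim(frame) == dim(mask))) stop("frame/mask shape mismatch")
  frame * mask
}
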