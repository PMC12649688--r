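#' Render a stereo fluoroscopy sequence of a moving phantom
#'
#' For each frame at time `t = k / fs` (k = 0, 1, ...), the whole volume is
#' rigidly displaced by the respiratory motion model (implemented as an
#' origin shift, so voxel data are never resampled), both stereo views are
#' rendered as DRRs, tumor labels are threshold-projected from the displaced
#' mask, and optional stochastic degradation is applied with a per-frame
#' seed substream. Ground truth comes for free from the construction: the
#' projected tumor-centroid paths in both views, the 3D centroid path, and
#' the projected marker paths.
#'
#' @param volume a `ct_volume` (HU).
#' @param mask binary tumor-mask `ct_volume` on the same grid.
#' @param markers list of mm triples (may be empty).
#' @param motion a `motion_model`.
#' @param geometry_pair list of two `projection_geometry`.
#' @param degradation optional `degradation_params`; NULL renders clean
#'   frames identical to direct DRR rendering of the displaced volume.
#' @param n_frames number of frames.
#' @param fs frame rate, Hz (default 30).
#' @param curves `content_curves` for the degradation.
#' @param min_voxels label projection threshold (default 7).
#' @param render_labels also project per-frame tumor labels (default TRUE).
#' @return list with `frames_a`, `frames_b` (`H x W x N` arrays),
#'   `labels_a`, `labels_b` (binary arrays or NULL), `gt2d_a`, `gt2d_b`,
#'   `marker2d_a`, `marker2d_b` (`trajectory2d`), `gt3d` (`trajectory3d`)
#'   and `centroid0` (static tumor centroid, mm).
#' @export
render_sequence <- function(volume, mask, markers, motion, geometry_pair,
                            degradation = NULL, n_frames, fs = 30,
                            curves = default_content_curves(),
                            min_voxels = 7L, render_labels = TRUE) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "ct_volume"),
            inherits(motion, "motion_model"))
  if (fs <= 0) stop("fs must be positive")
  if (length(geometry_pair) != 2L)
    stop("geometry_pair must hold exactly two views")
  ga <- geometry_pair[[1]]; gb <- geometry_pair[[2]]
  # static tumor centroid = mean of mask voxel centers
  idx <- which(mask$values != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty tumor mask")
  c0 <- mask$origin + (colMeans(idx) - 1) * mask$spacing
  H_a <- ga$image_size[2]; W_a <- ga$image_size[1]
  H_b <- gb$image_size[2]; W_b <- gb$image_size[1]
  frames_a <- array(0, dim = c(H_a, W_a, n_frames))
  frames_b <- array(0, dim = c(H_b, W_b, n_frames))
  labels_a <- if (render_labels) array(0L, dim = c(H_a, W_a, n_frames)) else NULL
  labels_b <- if (render_labels) array(0L, dim = c(H_b, W_b, n_frames)) else NULL
  gt2a <- gt2b <- m2a <- m2b <- matrix(NA_real_, n_frames, 2)
  gt3 <- matrix(NA_real_, n_frames, 3)
  ts <- (seq_len(n_frames) - 1) / fs
  for (k in seq_len(n_frames)) {
    disp <- respiratory_displacement(motion, ts[k])
    vol_k <- volume; vol_k$origin <- volume$origin + disp
    mask_k <- mask; mask_k$origin <- mask$origin + disp
    fa <- render_drr(vol_k, ga)
    fb <- render_drr(vol_k, gb)
    if (!is.null(degradation)) {
      pk <- degradation
      pk$seed <- frame_seed(degradation$seed, k)
      fa <- degrade(fa, pk, curves)
      pk$seed <- frame_seed(degradation$seed, k + n_frames)
      fb <- degrade(fb, pk, curves)
    }
    frames_a[, , k] <- fa
    frames_b[, , k] <- fb
    if (render_labels) {
      labels_a[, , k] <- project_label(mask_k, ga, min_voxels)
      labels_b[, , k] <- project_label(mask_k, gb, min_voxels)
    }
    ck <- c0 + disp
    gt3[k, ] <- ck
    gt2a[k, ] <- project_point(ga, ck)
    gt2b[k, ] <- project_point(gb, ck)
    if (length(markers) > 0) {
      mk <- as.numeric(markers[[1]]) + disp
      m2a[k, ] <- project_point(ga, mk)
      m2b[k, ] <- project_point(gb, mk)
    }
  }
  list(frames_a = frames_a, frames_b = frames_b,
       labels_a = labels_a, labels_b = labels_b,
       gt2d_a = trajectory2d(gt2a[, 1], gt2a[, 2], fs = fs),
       gt2d_b = trajectory2d(gt2b[, 1], gt2b[, 2], fs = fs),
       marker2d_a = if (length(markers) > 0)
         trajectory2d(m2a[, 1], m2a[, 2], fs = fs) else NULL,
       marker2d_b = if (length(markers) > 0)
         trajectory2d(m2b[, 1], m2b[, 2], fs = fs) else NULL,
       gt3d = trajectory3d(gt3[, 1], gt3[, 2], gt3[, 3], fs = fs),
       centroid0 = c0)
}
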