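#' Tracking pipeline configuration
#'
#' Orders and enables the per-frame stages of the tracking workflow:
#' grayscale conversion, style transfer (identity unless a plugin is
#' supplied — the "without style transfer" arm of a workflow comparison),
#' segmentation (always on) and trajectory low-pass filtering. Neural style
#' transfer and segmentation models are plugin points with the contract
#' `function(frame) -> frame` / `function(frame, k) -> binary mask`; the
#' package ships an identity style stage and a classical threshold
#' segmenter.
#'
#' @param grayscale enable color-to-gray conversion (default TRUE; ignored
#'   for already-gray stacks).
#' @param style_transfer NULL (identity / disabled) or a plugin
#'   `function(frame) -> frame`.
#' @param segmenter a plugin `function(frame, k) -> binary mask`; default
#'   the shipped [toy_segmenter()] over the SB-mask circle.
#' @param lpf enable trajectory low-pass filtering (default TRUE).
#' @param filter a `filter_spec`.
#' @param seed integer seed recorded with the run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(grayscale = TRUE, style_transfer = NULL,
                            segmenter = NULL, lpf = TRUE,
                            filter = filter_spec(), seed = 1L) {
  if (!is.null(style_transfer) && !is.function(style_transfer))
    stop("style_transfer plugin must be a function or NULL")
  if (!is.null(segmenter) && !is.function(segmenter))
    stop("segmenter plugin must be a function or NULL")
  structure(list(grayscale = grayscale, style_transfer = style_transfer,
                 segmenter = segmenter, lpf = lpf, filter = filter,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Luminance color-to-gray conversion
#' @keywords internal
luminance <- function(frame_rgb, weights = c(0.299, 0.587, 0.114)) {
  frame_rgb[, , 1] * weights[1] + frame_rgb[, , 2] * weights[2] +
    frame_rgb[, , 3] * weights[3]
}

#' Grayscale conversion stage
#'
#' Converts a 3-channel 8-bit frame to grayscale. The default converter is
#' the standard luminance weighting (0.299, 0.587, 0.114); any conforming
#' converter (`function(H x W x 3) -> H x W`) can be dropped in, e.g. a
#' correlation-based contrast-preserving method.
#'
#' @param frame `H x W x 3` array with values in `[0, 255]`, or an already
#'   gray `H x W` matrix (returned unchanged).
#' @param converter optional drop-in converter function.
#' @return `H x W` matrix in `[0, 255]`.
#' @export
grayscale_stage <- function(frame, converter = NULL) {
  if (is.matrix(frame)) return(frame)
  if (length(dim(frame)) != 3L || dim(frame)[3] != 3L)
    stop("expected an H x W x 3 color frame")
  if (is.null(converter)) luminance(frame) else converter(frame)
}

#' Classical threshold segmenter
#'
#' Stand-in for a learned segmentation model: within a rectangular ROI the
#' frame is inverted (the tumor is darker than aerated lung), thresholded by
#' Otsu's method, reduced to its largest connected component and
#' hole-filled. Returns an all-zero mask (empty-mask signal) when no
#' foreground survives.
#'
#' @param frame `H x W` matrix in `[0, 255]`.
#' @param roi `c(x0, y0, x1, y1)` 0-based inclusive pixel rectangle; default
#'   the bounding box of the SB-mask circle.
#' @return binary `H x W` integer matrix.
#' @export
toy_segmenter <- function(frame, roi = NULL) {
  H <- nrow(frame); W <- ncol(frame)
  if (is.null(roi)) {
    r <- floor(min(W, H) / 2)
    cx <- (W - 1) / 2; cy <- (H - 1) / 2
    roi <- c(ceiling(cx - r), ceiling(cy - r), floor(cx + r), floor(cy + r))
    roi <- pmax(roi, 0)
    roi[c(3, 4)] <- pmin(roi[c(3, 4)], c(W - 1, H - 1))
  }
  if (roi[1] < 0 || roi[2] < 0 || roi[3] > W - 1 || roi[4] > H - 1 ||
      roi[1] > roi[3] || roi[2] > roi[4])
    stop("roi outside the frame")
  rows <- (roi[2]:roi[4]) + 1
  cols <- (roi[1]:roi[3]) + 1
  sub <- frame[rows, cols, drop = FALSE]
  inv <- (255 - sub) / 255
  if (max(inv) - min(inv) < 1e-9) return(matrix(0L, H, W))
  th <- EBImage::otsu(EBImage::Image(t(inv)), range = c(0, 1))
  bin <- inv > th
  if (!any(bin)) return(matrix(0L, H, W))
  lab <- EBImage::bwlabel(EBImage::Image(t(bin)))
  sizes <- table(EBImage::imageData(lab)[EBImage::imageData(lab) > 0])
  biggest <- as.integer(names(sizes)[which.max(sizes)])
  comp <- EBImage::fillHull(lab == biggest)
  mask <- matrix(0L, H, W)
  mask[rows, cols] <- t(EBImage::imageData(comp)) * 1L
  mask
}

#' Run the full stereo tracking workflow
#'
#' Per view: stage chain (grayscale, optional style transfer, segmentation)
#' produces a mask sequence; centroid extraction yields the 2D trajectory,
#' optionally aligned to a reference and low-pass filtered; the two views
#' are then triangulated frame-wise into the 3D tumor-center trajectory.
#' When 2D/3D references are supplied the corresponding grade reports and
#' 3D error statistics are computed.
#'
#' @param stack_a,stack_b synchronized frame stacks of the two views (gray
#'   `H x W x N` or color `H x W x 3 x N`).
#' @param geom_a,geom_b the views' `projection_geometry`.
#' @param config a `pipeline_config`.
#' @param ref_a,ref_b optional reference `trajectory2d` per view (e.g.
#'   fiducial-marker tracks) for alignment and grading.
#' @param ref_3d optional reference `trajectory3d` for 3D error statistics.
#' @param fs frame rate (default 30).
#' @param out_dir optional directory; when given, masks (PNG) and
#'   trajectories (CSV) are persisted.
#' @return list with `traj3d`, `grades` (per-view `grade_report` or NULL),
#'   `stats` (3D error stats or NULL), `masks_a`, `masks_b`, `traj_a`,
#'   `traj_b`, `timing_s`.
#' @export
run_tracking <- function(stack_a, stack_b, geom_a, geom_b,
                         config = pipeline_config(), ref_a = NULL,
                         ref_b = NULL, ref_3d = NULL, fs = 30,
                         out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  to_gray_stack <- function(stack) {
    if (length(dim(stack)) == 4L) {
      n <- dim(stack)[4]
      out <- array(0, dim = c(dim(stack)[1:2], n))
      for (k in seq_len(n))
        out[, , k] <- if (config$grayscale) grayscale_stage(stack[, , , k])
                      else stop("color stack requires the grayscale stage")
      out
    } else as_stack(stack)
  }
  sa <- to_gray_stack(stack_a)
  sb <- to_gray_stack(stack_b)
  if (dim(sa)[3] != dim(sb)[3]) stop("stereo stacks differ in frame count")
  segment <- config$segmenter
  if (is.null(segment)) segment <- function(frame, k) toy_segmenter(frame)
  run_view <- function(stack) {
    n <- dim(stack)[3]
    masks <- array(0L, dim = dim(stack))
    for (k in seq_len(n)) {
      frame <- stack[, , k]
      if (!is.null(config$style_transfer))
        frame <- config$style_transfer(frame)
      masks[, , k] <- segment(frame, k)
    }
    masks
  }
  masks_a <- run_view(sa)
  masks_b <- run_view(sb)
  traj_a <- extract_trajectory(masks_a, fs = fs)
  traj_b <- extract_trajectory(masks_b, fs = fs)
  if (!is.null(ref_a)) traj_a <- align_to_reference(traj_a, ref_a)
  if (!is.null(ref_b)) traj_b <- align_to_reference(traj_b, ref_b)
  if (config$lpf) {
    spec <- config$filter
    spec$fs <- fs
    traj_a <- lowpass(traj_a, spec)
    traj_b <- lowpass(traj_b, spec)
  }
  traj3d <- trajectory_3d(traj_a, traj_b, geom_a, geom_b)
  grades <- list(
    a = if (!is.null(ref_a)) rmse_grade(traj_a, ref_a) else NULL,
    b = if (!is.null(ref_b)) rmse_grade(traj_b, ref_b) else NULL)
  stats <- if (!is.null(ref_3d)) error_stats_3d(traj3d, ref_3d) else NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_stack_png(masks_a * 255L, file.path(out_dir, "masks_a"), "mask")
    write_stack_png(masks_b * 255L, file.path(out_dir, "masks_b"), "mask")
    write_trajectory(traj_a, file.path(out_dir, "traj2d_a.csv"))
    write_trajectory(traj_b, file.path(out_dir, "traj2d_b.csv"))
    write_trajectory(traj3d, file.path(out_dir, "traj3d.csv"))
  }
  list(traj3d = traj3d, grades = grades, stats = stats,
       masks_a = masks_a, masks_b = masks_b,
       traj_a = traj_a, traj_b = traj_b,
       timing_s = proc.time()[["elapsed"]] - t0)
}

#' Compare two workflow configurations on a dataset
#'
#' Runs both configurations on every sequence of a dataset and reports
#' paired per-sequence final errors `E` (worst of the two views), the 3D
#' median Euclidean errors and their differences, as a data.frame plus a
#' short text summary — the structure of a style-transfer on/off trade-off
#' analysis.
#'
#' @param dataset list of sequences, each a list with `stack_a`, `stack_b`,
#'   `geom_a`, `geom_b`, `ref_a`, `ref_b`, `ref_3d` and optional `name`.
#' @param config_a,config_b two `pipeline_config`s.
#' @param fs frame rate (default 30).
#' @return list with `table` (per-sequence data.frame), `median_diff_mm` and
#'   `summary` (character).
#' @export
compare_workflows <- function(dataset, config_a, config_b, fs = 30) {
  if (length(dataset) == 0L) stop("empty dataset")
  rows <- lapply(seq_along(dataset), function(i) {
    sq <- dataset[[i]]
    run <- function(cfg) run_tracking(sq$stack_a, sq$stack_b, sq$geom_a,
                                      sq$geom_b, cfg, sq$ref_a, sq$ref_b,
                                      sq$ref_3d, fs = fs)
    ra <- run(config_a); rb <- run(config_b)
    E_of <- function(r) max(r$grades$a$E, r$grades$b$E)
    med_of <- function(r) if (is.null(r$stats)) NA_real_ else r$stats$median_mm
    data.frame(sequence = if (!is.null(sq$name)) sq$name else paste0("seq", i),
               E_a = E_of(ra), E_b = E_of(rb),
               median_a_mm = med_of(ra), median_b_mm = med_of(rb),
               dE = E_of(rb) - E_of(ra),
               dmedian_mm = med_of(rb) - med_of(ra))
  })
  tab <- do.call(rbind, rows)
  med_diff <- stats::median(tab$dmedian_mm)
  list(table = tab,
       median_diff_mm = med_diff,
       summary = sprintf(
         "%d sequences; median per-sequence 3D-median-error difference (B - A): %.3f mm; mean dE: %.3f px",
         nrow(tab), med_diff, mean(tab$dE)))
}
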