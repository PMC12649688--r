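#' 2D and 3D trajectory containers
#'
#' A `trajectory2d` is a data.frame with columns `frame` (0-based), `t_s`
#' (`frame / fs` seconds), `x_px`, `y_px` and a logical `flag` marking
#' frames whose position was carried forward (e.g. empty segmentation
#' masks); a `trajectory3d` has `X_mm` (LR), `Y_mm` (SI), `Z_mm` (AP)
#' instead. The sampling rate is kept in the `fs` attribute.
#'
#' @param x,y,z coordinate vectors (px for 2D, mm for 3D).
#' @param fs sampling rate in Hz (> 0).
#' @param flag logical per-frame quality flags.
#' @return a `trajectory2d` / `trajectory3d` data.frame.
#' @export
trajectory2d <- function(x, y, fs = 30, flag = logical(length(x))) {
  if (fs <= 0) stop("fs must be positive")
  if (length(x) != length(y) || length(x) < 1L)
    stop("x and y must be equal-length, non-empty")
  frame <- seq_along(x) - 1L
  structure(data.frame(frame = frame, t_s = frame / fs,
                       x_px = as.numeric(x), y_px = as.numeric(y),
                       flag = flag),
            fs = fs, class = c("trajectory2d", "data.frame"))
}

#' @rdname trajectory2d
#' @export
trajectory3d <- function(x, y, z, fs = 30, flag = logical(length(x))) {
  if (fs <= 0) stop("fs must be positive")
  if (length(unique(c(length(x), length(y), length(z)))) != 1L)
    stop("coordinate vectors must have equal length")
  frame <- seq_along(x) - 1L
  structure(data.frame(frame = frame, t_s = frame / fs,
                       X_mm = as.numeric(x), Y_mm = as.numeric(y),
                       Z_mm = as.numeric(z), flag = flag),
            fs = fs, class = c("trajectory3d", "data.frame"))
}

traj_fs <- function(traj) attr(traj, "fs")

coord_cols <- function(traj) {
  if (inherits(traj, "trajectory2d")) c("x_px", "y_px")
  else if (inherits(traj, "trajectory3d")) c("X_mm", "Y_mm", "Z_mm")
  else stop("not a trajectory")
}

#' Centroid of a binary segmentation mask
#'
#' Arithmetic mean of the member pixels' 0-based column (x) and row (y)
#' indices — the tumor center position used throughout trajectory
#' extraction.
#'
#' @param mask binary `H x W` matrix.
#' @return `(x, y)` in px, or `NULL` for an empty mask (caller policy
#'   decides what to do with empty frames).
#' @export
centroid <- function(mask) {
  w <- which(mask != 0, arr.ind = TRUE)
  if (nrow(w) == 0L) return(NULL)
  c(x = mean(w[, 2] - 1), y = mean(w[, 1] - 1))
}

#' Extract a centroid trajectory from a mask sequence
#'
#' One centroid per frame at `t = frame / fs`. Frames with an empty mask
#' carry the previous centroid forward and are flagged; an empty first frame
#' is an error since there is nothing to carry.
#'
#' @param mask_sequence `H x W x N` binary array or list of masks.
#' @param fs frame rate, Hz (default 30).
#' @return a `trajectory2d`.
#' @export
extract_trajectory <- function(mask_sequence, fs = 30) {
  stack <- as_stack(mask_sequence)
  n <- dim(stack)[3]
  xs <- ys <- numeric(n)
  flags <- logical(n)
  for (k in seq_len(n)) {
    ctr <- centroid(stack[, , k])
    if (is.null(ctr)) {
      if (k == 1L) stop("first frame mask is empty")
      xs[k] <- xs[k - 1]; ys[k] <- ys[k - 1]; flags[k] <- TRUE
    } else {
      xs[k] <- ctr["x"]; ys[k] <- ctr["y"]
    }
  }
  trajectory2d(xs, ys, fs = fs, flag = flags)
}

#' Low-pass filter specification
#'
#' Parameters of the trajectory smoothing filter: a digital Butterworth
#' low-pass of order `order`, cutoff `fc`, designed by bilinear transform at
#' normalized cutoff `fc / (fs / 2)`, applied forward-backward (zero phase)
#' by default. The defaults (8 Hz cutoff at 30 Hz sampling, order 4) keep
#' respiratory and cardiac components (< 2 Hz) untouched while removing
#' frame-level segmentation jitter.
#'
#' @param fc cutoff frequency, Hz (0 < fc < fs/2).
#' @param fs sampling frequency, Hz.
#' @param order filter order (>= 1).
#' @param zero_phase apply forward-backward (default TRUE).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(fc = 8, fs = 30, order = 4L, zero_phase = TRUE) {
  if (order < 1) stop("order must be >= 1")
  if (fc <= 0 || fc >= fs / 2)
    stop("need 0 < fc < fs/2 (Nyquist)")
  structure(list(fc = fc, fs = fs, order = as.integer(order),
                 zero_phase = zero_phase),
            class = "filter_spec")
}

butter_coefs <- function(spec) {
  ba <- signal::butter(spec$order, spec$fc / (spec$fs / 2), type = "low")
  list(b = ba$b, a = ba$a)
}

#' Steady-state initial filter state (direct form II transposed)
#' @keywords internal
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  # companion matrix of a, transposed
  comp <- rbind(-a[-1], cbind(diag(n - 2), 0))
  IminusA <- diag(n - 1) - t(comp)
  B <- b[-1] - a[-1] * b[1]
  solve(IminusA, B)
}

#' IIR filtering with explicit initial state (direct form II transposed)
#' @keywords internal
df2t_filter <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  z <- if (is.null(zi)) rep(0, n - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    for (j in seq_len(n - 2))
      z[j] <- b[j + 1] * x[i] + z[j + 1] - a[j + 1] * y[i]
    z[n - 1] <- b[n] * x[i] - a[n] * y[i]
  }
  y
}

#' Zero-phase filtering of one signal
#'
#' Forward-backward application with odd-reflection edge padding of three
#' filter lengths and steady-state initial conditions, so constants pass
#' unchanged (exact DC gain 1) and the output has no phase lag.
#'
#' @param x numeric signal.
#' @param b,a digital filter coefficients.
#' @return filtered signal, same length.
#' @keywords internal
zero_phase_filter <- function(x, b, a) {
  n <- max(length(a), length(b))
  pad <- 3L * (n - 1L)
  if (length(x) <= pad)
    stop("signal too short for zero-phase filtering (need > ", pad, " samples)")
  # odd reflection about the end points
  pre <- 2 * x[1] - x[seq(pad + 1, 2)]
  post <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - pad)]
  ext <- c(pre, x, post)
  zi <- lfilter_zi(b, a)
  y <- df2t_filter(b, a, ext, zi * ext[1])
  y <- rev(df2t_filter(b, a, rev(y), zi * y[length(y)]))
  y[pad + seq_along(x)]
}

#' Low-pass filter a trajectory
#'
#' Applies the Butterworth design of `spec` to each coordinate of a 2D or 3D
#' trajectory. With `zero_phase` the filter runs forward-backward so the
#' smoothed trajectory stays aligned in time with the original (no phase
#' distortion); the effective magnitude response is then the squared design
#' response. Timestamps and flags are unchanged.
#'
#' @param traj a `trajectory2d` or `trajectory3d`.
#' @param spec a `filter_spec`; its `fs` must match the trajectory's.
#' @return a trajectory of the same type.
#' @export
lowpass <- function(traj, spec = filter_spec(fs = traj_fs(traj))) {
  cols <- coord_cols(traj)
  if (spec$fc >= spec$fs / 2) stop("cutoff must be below Nyquist")
  if (nrow(traj) <= 3L * spec$order)
    stop("trajectory too short for the requested filter order")
  ba <- butter_coefs(spec)
  for (cl in cols) {
    traj[[cl]] <- if (spec$zero_phase)
      zero_phase_filter(traj[[cl]], ba$b, ba$a)
    else
      df2t_filter(ba$b, ba$a, traj[[cl]], lfilter_zi(ba$b, ba$a) * traj[[cl]][1])
  }
  traj
}

#' Designed squared-magnitude response of a filter spec
#'
#' Magnitude response of the digital Butterworth design evaluated at given
#' frequencies, raised to the power 2 when `zero_phase` (forward-backward
#' doubles the attenuation). Used as the analytic reference for what
#' [lowpass()] does to narrowband signals.
#'
#' @param spec a `filter_spec`.
#' @param freq_hz frequencies at which to evaluate.
#' @return magnitude gains.
#' @export
filter_gain <- function(spec, freq_hz) {
  ba <- butter_coefs(spec)
  w <- 2 * pi * freq_hz / spec$fs
  ew <- exp(-1i * outer(w, seq_along(ba$b) - 1))
  num <- as.vector(ew %*% ba$b)
  den <- as.vector(ew %*% c(ba$a, rep(0, length(ba$b) - length(ba$a))))
  g <- Mod(num / den)
  if (spec$zero_phase) g^2 else g
}

#' One-sided amplitude spectrum of a trajectory
#'
#' Mean-subtracted FFT amplitude spectrum per coordinate on `[0, fs/2]`.
#' Amplitudes are normalized as `2 |X_k| / N` (and `|X_k| / N` at DC and
#' Nyquist) so a pure sinusoid of amplitude a shows a peak of height a.
#'
#' @param traj a `trajectory2d` or `trajectory3d` (length >= 8).
#' @param fs sampling rate; defaults to the trajectory's.
#' @return data.frame with `freq_hz` and one amplitude column per
#'   coordinate.
#' @export
amplitude_spectrum <- function(traj, fs = traj_fs(traj)) {
  cols <- coord_cols(traj)
  n <- nrow(traj)
  if (n < 8L) stop("need at least 8 samples")
  nk <- floor(n / 2) + 1L
  out <- data.frame(freq_hz = (seq_len(nk) - 1) * fs / n)
  for (cl in cols) {
    x <- traj[[cl]] - mean(traj[[cl]])
    X <- stats::fft(x)[seq_len(nk)]
    amp <- 2 * Mod(X) / n
    amp[1] <- Mod(X[1]) / n
    if (n %% 2 == 0) amp[nk] <- Mod(X[nk]) / n
    out[[paste0("amp_", cl)]] <- amp
  }
  out
}

#' Align a trajectory to a reference's mean position
#'
#' Shifts the trajectory so its mean position coincides with the reference's
#' mean position (per coordinate), removing the constant spatial offset
#' between e.g. a tumor centroid and a nearby fiducial marker so only the
#' dynamic motion is compared.
#'
#' @param traj,ref trajectories of the same type and length.
#' @return the aligned trajectory.
#' @export
align_to_reference <- function(traj, ref) {
  cols <- coord_cols(traj)
  if (!identical(cols, coord_cols(ref))) stop("trajectory types differ")
  if (nrow(traj) != nrow(ref)) stop("trajectory lengths differ")
  for (cl in cols)
    traj[[cl]] <- traj[[cl]] - mean(traj[[cl]]) + mean(ref[[cl]])
  traj
}

#' RMSE grading of a 2D trajectory against a reference
#'
#' Per-axis root mean square error, the final error `E = max(RMSE_x,
#' RMSE_y)` and the standard grade: `E < 3` px Excellent, `3 <= E < 8` High,
#' `8 <= E < 13` Moderate, `E >= 13` Low.
#'
#' @param traj_aligned aligned `trajectory2d`.
#' @param ref reference `trajectory2d` of equal length.
#' @return object of class `grade_report` with `rmse_x`, `rmse_y`, `E`,
#'   `grade`.
#' @export
rmse_grade <- function(traj_aligned, ref) {
  if (nrow(traj_aligned) != nrow(ref)) stop("trajectory lengths differ")
  rmse_x <- sqrt(mean((traj_aligned$x_px - ref$x_px)^2))
  rmse_y <- sqrt(mean((traj_aligned$y_px - ref$y_px)^2))
  E <- max(rmse_x, rmse_y)
  grade <- if (E < 3) "Excellent" else if (E < 8) "High"
           else if (E < 13) "Moderate" else "Low"
  structure(list(rmse_x = rmse_x, rmse_y = rmse_y, E = E, grade = grade),
            class = "grade_report")
}

#' @export
print.grade_report <- function(x, ...) {
  cat(sprintf("<grade_report> RMSE x %.3f px, y %.3f px; E = %.3f px -> %s\n",
              x$rmse_x, x$rmse_y, x$E, x$grade))
  invisible(x)
}

#' Stereo 3D trajectory from two 2D trajectories
#'
#' Frame-wise triangulation of paired 2D image positions using the two
#' views' projection geometries. Per-frame triangulation residuals above
#' `residual_flag_mm` set the frame's quality flag rather than failing.
#'
#' @param traj_a,traj_b equal-length `trajectory2d` of the two views.
#' @param geom_a,geom_b the views' `projection_geometry`.
#' @param residual_flag_mm residual threshold for flagging (default 2).
#' @return a `trajectory3d` with a `residual_mm` column.
#' @export
trajectory_3d <- function(traj_a, traj_b, geom_a, geom_b,
                          residual_flag_mm = 2) {
  if (nrow(traj_a) != nrow(traj_b)) stop("trajectory lengths differ")
  n <- nrow(traj_a)
  pts <- matrix(0, n, 3)
  res <- numeric(n)
  for (k in seq_len(n)) {
    tri <- triangulate(geom_a, c(traj_a$x_px[k], traj_a$y_px[k]),
                       geom_b, c(traj_b$x_px[k], traj_b$y_px[k]))
    pts[k, ] <- tri$point
    res[k] <- tri$residual_mm
  }
  out <- trajectory3d(pts[, 1], pts[, 2], pts[, 3], fs = traj_fs(traj_a),
                      flag = traj_a$flag | traj_b$flag |
                        res > residual_flag_mm)
  out$residual_mm <- res
  out
}

#' 3D tracking error statistics
#'
#' Per-axis (LR/SI/AP) mean and SD of the absolute per-frame differences,
#' the per-frame 3D Euclidean distances, and the median and interquartile
#' range of the Euclidean series.
#'
#' @param traj,ref equal-length `trajectory3d`.
#' @return list with `axis` (data.frame axis/mean/sd), `euclidean_mm`
#'   (per-frame), `median_mm`, `iqr_mm`.
#' @export
error_stats_3d <- function(traj, ref) {
  if (nrow(traj) != nrow(ref)) stop("trajectory lengths differ")
  cols <- c("X_mm", "Y_mm", "Z_mm")
  dmat <- as.matrix(traj[cols]) - as.matrix(ref[cols])
  axis <- data.frame(axis = c("LR", "SI", "AP"),
                     mean = colMeans(abs(dmat)),
                     sd = apply(abs(dmat), 2, stats::sd))
  euc <- unname(sqrt(rowSums(dmat^2)))
  list(axis = axis, euclidean_mm = euc,
       median_mm = stats::median(euc),
       iqr_mm = stats::IQR(euc))
}

#' Track a small template through a frame stack
#'
#' Simple normalized-cross-correlation tracker used as the fiducial-marker
#' reference tracker: in each frame the template is searched in a window
#' around the previous position, the best match refined to subpixel
#' precision by quadratic fits along each axis, and frames whose peak
#' correlation falls below `min_corr` are flagged (position carried from the
#' search maximum regardless).
#'
#' @param stack `H x W x N` frame stack.
#' @param template numeric patch, odd dimensions recommended, smaller than
#'   the frame.
#' @param start `(x, y)` px, template-center position in frame 1.
#' @param search_radius search window half-width in px (default 10).
#' @param min_corr correlation threshold for the quality flag (default 0.5).
#' @param fs frame rate (default 30).
#' @return a `trajectory2d`.
#' @export
marker_track_template <- function(stack, template, start, search_radius = 10L,
                                  min_corr = 0.5, fs = 30) {
  stack <- as_stack(stack)
  th <- nrow(template); tw <- ncol(template)
  H <- dim(stack)[1]; W <- dim(stack)[2]; n <- dim(stack)[3]
  if (th > H || tw > W) stop("template larger than frame")
  if (start[1] < 0 || start[1] > W - 1 || start[2] < 0 || start[2] > H - 1)
    stop("start position outside the frame")
  hy <- (th - 1) %/% 2; hx <- (tw - 1) %/% 2
  tz <- template - mean(template)
  tnorm <- sqrt(sum(tz^2))
  ncc_at <- function(frame, cx, cy) {
    # template centered at 0-based (cx, cy); returns NA when off-frame
    r0 <- cy - hy + 1; c0 <- cx - hx + 1
    if (r0 < 1 || c0 < 1 || r0 + th - 1 > H || c0 + tw - 1 > W) return(NA_real_)
    patch <- frame[r0:(r0 + th - 1), c0:(c0 + tw - 1)]
    pz <- patch - mean(patch)
    pn <- sqrt(sum(pz^2))
    if (pn < 1e-12 || tnorm < 1e-12) return(0)
    sum(pz * tz) / (pn * tnorm)
  }
  xs <- ys <- numeric(n)
  flags <- logical(n)
  prev <- round(as.numeric(start))
  for (k in seq_len(n)) {
    frame <- stack[, , k]
    cand_x <- (prev[1] - search_radius):(prev[1] + search_radius)
    cand_y <- (prev[2] - search_radius):(prev[2] + search_radius)
    cc <- matrix(NA_real_, length(cand_y), length(cand_x))
    for (i in seq_along(cand_y))
      for (j in seq_along(cand_x))
        cc[i, j] <- ncc_at(frame, cand_x[j], cand_y[i])
    if (all(is.na(cc))) stop("search window left the frame")
    best <- which(cc == max(cc, na.rm = TRUE), arr.ind = TRUE)[1, ]
    bx <- cand_x[best[2]]; by <- cand_y[best[1]]
    flags[k] <- max(cc, na.rm = TRUE) < min_corr
    # subpixel: 3-point parabola per axis
    refine <- function(cm, c0, cp) {
      if (is.na(cm) || is.na(cp)) return(0)
      den <- cm - 2 * c0 + cp
      if (abs(den) < 1e-12) return(0)
      d <- 0.5 * (cm - cp) / den
      max(min(d, 0.5), -0.5)
    }
    i0 <- best[1]; j0 <- best[2]
    dx <- refine(if (j0 > 1) cc[i0, j0 - 1] else NA, cc[i0, j0],
                 if (j0 < ncol(cc)) cc[i0, j0 + 1] else NA)
    dy <- refine(if (i0 > 1) cc[i0 - 1, j0] else NA, cc[i0, j0],
                 if (i0 < nrow(cc)) cc[i0 + 1, j0] else NA)
    xs[k] <- bx + dx; ys[k] <- by + dy
    prev <- c(bx, by)
  }
  trajectory2d(xs, ys, fs = fs, flag = flags)
}

#' Read / write trajectories as CSV
#'
#' 2D trajectories use columns `frame,t_s,x_px,y_px,flag`; 3D trajectories
#' `frame,t_s,X_mm,Y_mm,Z_mm,flag`.
#'
#' @param traj a trajectory.
#' @param path CSV path.
#' @param fs sampling rate used when reading (recovered from `t_s` when
#'   NULL).
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, fs = NULL) {
  df <- utils::read.csv(path)
  if (is.null(fs))
    fs <- if (nrow(df) > 1) 1 / (df$t_s[2] - df$t_s[1]) else 30
  flag <- if ("flag" %in% names(df)) as.logical(df$flag) else logical(nrow(df))
  if ("x_px" %in% names(df))
    trajectory2d(df$x_px, df$y_px, fs = fs, flag = flag)
  else
    trajectory3d(df$X_mm, df$Y_mm, df$Z_mm, fs = fs, flag = flag)
}
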