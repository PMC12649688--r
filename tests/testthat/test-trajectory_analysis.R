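test_that("mask centroids are exact index means", {
  m <- matrix(0L, 32, 32)
  m[21, 11] <- 1L  # row 21 = y 20, col 11 = x 10
  expect_equal(centroid(m), c(x = 10, y = 20))
  m2 <- matrix(0L, 32, 32)
  m2[11:20, 6:15] <- 1L
  expect_equal(centroid(m2), c(x = 9.5, y = 14.5))
  set.seed(12)
  m3 <- matrix(rbinom(64 * 64, 1, 0.3), 64, 64)
  w <- which(m3 == 1, arr.ind = TRUE)
  expect_equal(centroid(m3), c(x = mean(w[, 2]) - 1, y = mean(w[, 1]) - 1))
  expect_null(centroid(matrix(0L, 4, 4)))
})

test_that("trajectory extraction carries empty frames forward with a flag", {
  mk <- function(cx) {
    m <- matrix(0L, 32, 32); m[15:17, (cx + 1):(cx + 3)] <- 1L; m
  }
  stack <- as_stack(list(mk(5), mk(7), matrix(0L, 32, 32), mk(11)))
  tr <- extract_trajectory(stack, fs = 30)
  expect_equal(nrow(tr), 4L)
  expect_equal(tr$t_s, (0:3) / 30)
  expect_equal(tr$x_px[3], tr$x_px[2])
  expect_equal(tr$flag, c(FALSE, FALSE, TRUE, FALSE))
  static <- as_stack(list(mk(5), mk(5), mk(5)))
  trs <- extract_trajectory(static)
  expect_equal(length(unique(trs$x_px)), 1L)
  expect_error(extract_trajectory(as_stack(list(matrix(0L, 4, 4)))),
               "first frame")
})

test_that("zero-phase Butterworth filtering honors its frequency contract", {
  fs <- 30
  spec <- filter_spec(fc = 8, fs = fs, order = 4)
  t <- (0:(20 * fs - 1)) / fs
  # DC gain exactly 1: constant trajectory unchanged
  const <- trajectory2d(rep(3.7, length(t)), rep(-1.2, length(t)), fs = fs)
  lc <- lowpass(const, spec)
  expect_equal(lc$x_px, const$x_px, tolerance = 1e-9)
  # passband: 1 Hz sine keeps >= 0.99 amplitude (RMS ratio), zero lag
  s1 <- sin(2 * pi * 1 * t)
  tr1 <- trajectory2d(s1, s1, fs = fs)
  lf1 <- lowpass(tr1, spec)
  core <- seq(fs + 1, length(t) - fs)  # discard 1 s edges
  rms_ratio <- sqrt(mean(lf1$x_px[core]^2) / mean(s1[core]^2))
  expect_gte(rms_ratio, 0.99)
  cc <- ccf(lf1$x_px, s1, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # stopband: 14 Hz attenuation matches the designed squared response
  # (RMS ratio after discarding 3 s of forward-backward edge transients,
  # which decay slower than the single-pass transient)
  s14 <- sin(2 * pi * 14 * t)
  lf14 <- lowpass(trajectory2d(s14, s14, fs = fs), spec)
  core3 <- seq(3 * fs + 1, length(t) - 3 * fs)
  gain_meas <- sqrt(mean(lf14$x_px[core3]^2) / mean(s14[core3]^2))
  gain_design <- filter_gain(spec, 14)
  expect_lt(abs(gain_meas - gain_design) / gain_design, 0.05)
  # single-pass design response is likewise realized
  spec1 <- filter_spec(zero_phase = FALSE)
  lf14s <- lowpass(trajectory2d(s14, s14, fs = fs), spec1)
  gain1 <- sqrt(mean(lf14s$x_px[core]^2) / mean(s14[core]^2))
  expect_lt(abs(gain1 - filter_gain(spec1, 14)) / filter_gain(spec1, 14),
            0.05)
  # zero-phase guarantee on a band-limited mixture
  mix <- sin(2 * pi * 0.33 * t) + 0.3 * sin(2 * pi * 2 * t + 1)
  lmix <- lowpass(trajectory2d(mix, mix, fs = fs), spec)
  ccm <- ccf(lmix$x_px, mix, lag.max = 10, plot = FALSE)
  expect_equal(ccm$lag[which.max(ccm$acf)], 0)
  expect_error(filter_spec(fc = 15, fs = 30), "Nyquist")
  expect_error(lowpass(trajectory2d(1:5, 1:5), spec), "too short")
})

test_that("filtering commutes with mean alignment (both linear)", {
  set.seed(3)
  t <- (0:299) / 30
  x <- 5 * sin(2 * pi * 0.33 * t) + rnorm(300, 0, 0.5) + 40
  y <- 3 * cos(2 * pi * 0.33 * t) + rnorm(300, 0, 0.5) - 10
  traj <- trajectory2d(x, y)
  ref <- trajectory2d(x + 4, y - 6)
  a <- lowpass(align_to_reference(traj, ref))
  b <- align_to_reference(lowpass(traj), ref)
  # both operations are linear and the filter has unit DC gain, so the two
  # orders differ only by the constant mean(x) - mean(lowpass(x)) (filtering
  # perturbs the sample mean slightly); the difference must be constant and
  # small
  dx <- a$x_px - b$x_px
  dy <- a$y_px - b$y_px
  expect_lt(max(dx) - min(dx), 1e-9)
  expect_lt(max(dy) - min(dy), 1e-9)
  expect_lt(abs(mean(dx)), 0.01)
  expect_lt(abs(mean(dy)), 0.01)
})

test_that("amplitude spectrum finds the fundamental and conserves energy", {
  fs <- 30
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  y <- 4 * sin(2 * pi * (20 / 60) * t)
  tr <- trajectory2d(y, 0 * t, fs = fs)
  sp <- amplitude_spectrum(tr)
  peak <- sp$freq_hz[which.max(sp$amp_x_px)]
  expect_equal(round(peak, 2), 0.33)
  expect_equal(max(sp$amp_x_px), 4, tolerance = 1e-9)
  # constant trajectory: all zero after mean removal
  spc <- amplitude_spectrum(trajectory2d(rep(2, 64), rep(3, 64)))
  expect_true(all(abs(spc$amp_x_px) < 1e-12))
  # Parseval: one-sided amplitude energy equals signal variance
  set.seed(6)
  z <- rnorm(200)
  spz <- amplitude_spectrum(trajectory2d(z, z, fs = fs))
  n <- 200
  amp <- spz$amp_x_px
  power <- amp[1]^2 + sum(amp[2:(length(amp) - 1)]^2 / 2) +
    amp[length(amp)]^2
  expect_equal(power, mean((z - mean(z))^2), tolerance = 1e-9)
})

test_that("mean alignment cancels constant offsets exactly", {
  set.seed(14)
  ref <- trajectory2d(rnorm(50, 10), rnorm(50, -4))
  traj <- ref
  traj$x_px <- ref$x_px + 5
  traj$y_px <- ref$y_px + 7
  al <- align_to_reference(traj, ref)
  expect_equal(al$x_px, ref$x_px, tolerance = 1e-12)
  expect_equal(al$y_px, ref$y_px, tolerance = 1e-12)
  # means agree by construction for arbitrary inputs
  t2 <- trajectory2d(rnorm(50, 3, 4), rnorm(50, 8, 2))
  al2 <- align_to_reference(t2, ref)
  expect_equal(mean(al2$x_px), mean(ref$x_px))
  expect_equal(mean(al2$y_px), mean(ref$y_px))
  # direct-formula oracle
  exp_x <- t2$x_px - mean(t2$x_px) + mean(ref$x_px)
  expect_equal(al2$x_px, exp_x)
  expect_error(align_to_reference(trajectory2d(1:3, 1:3), ref), "lengths")
})

test_that("RMSE grading implements the max rule and grade boundaries", {
  ref <- trajectory2d(rep(0, 300), rep(0, 300))
  same <- rmse_grade(ref, ref)
  expect_equal(same$E, 0)
  expect_equal(same$grade, "Excellent")
  # sine over whole periods: RMSE = a / sqrt(2)
  t <- (0:299) / 30
  a <- 4
  traj <- trajectory2d(a * sin(2 * pi * 1 * t), rep(0, 300))
  g <- rmse_grade(traj, ref)
  expect_equal(g$rmse_x, a / sqrt(2), tolerance = 1e-9)
  expect_equal(g$rmse_y, 0)
  expect_equal(g$E, g$rmse_x)
  # boundary cases: E = 3 is High, not Excellent
  mk_const_err <- function(e) {
    tr <- trajectory2d(rep(e, 10), rep(0, 10))
    rmse_grade(tr, trajectory2d(rep(0, 10), rep(0, 10)))
  }
  expect_equal(mk_const_err(2.99)$grade, "Excellent")
  expect_equal(mk_const_err(3)$grade, "High")
  expect_equal(mk_const_err(7.99)$grade, "High")
  expect_equal(mk_const_err(8)$grade, "Moderate")
  expect_equal(mk_const_err(13)$grade, "Low")
  # permutation invariance and strict growth in single-frame deviations
  set.seed(21)
  tr <- trajectory2d(rnorm(40), rnorm(40))
  rf <- trajectory2d(rnorm(40), rnorm(40))
  p <- sample(40)
  trp <- trajectory2d(tr$x_px[p], tr$y_px[p])
  rfp <- trajectory2d(rf$x_px[p], rf$y_px[p])
  expect_equal(rmse_grade(trp, rfp)$E, rmse_grade(tr, rf)$E)
  tr2 <- tr; tr2$x_px[7] <- tr2$x_px[7] + 10
  expect_gt(rmse_grade(tr2, rf)$rmse_x, rmse_grade(tr, rf)$rmse_x)
})

test_that("stereo 3D trajectories recover known paths and error statistics", {
  pair <- stereo_geometry(image_size = c(128L, 128L))
  t <- (0:59) / 30
  path <- cbind(2 * sin(2 * pi * t / 2), 8 * sin(2 * pi * t / 2),
                4 * cos(2 * pi * t / 2))
  pa <- t(apply(path, 1, function(p) project_point(pair[[1]], p)))
  pb <- t(apply(path, 1, function(p) project_point(pair[[2]], p)))
  tra <- trajectory2d(pa[, 1], pa[, 2])
  trb <- trajectory2d(pb[, 1], pb[, 2])
  t3 <- trajectory_3d(tra, trb, pair[[1]], pair[[2]])
  expect_lt(max(abs(as.matrix(t3[c("X_mm", "Y_mm", "Z_mm")]) - path)), 1e-6)
  expect_true(all(!t3$flag))
  # static pair -> constant 3D trajectory
  st <- trajectory_3d(trajectory2d(rep(10, 5), rep(20, 5)),
                      trajectory2d(rep(30, 5), rep(20, 5)),
                      pair[[1]], pair[[2]])
  expect_equal(length(unique(st$X_mm)), 1L)
  expect_error(trajectory_3d(tra, trajectory2d(1:5, 1:5),
                             pair[[1]], pair[[2]]), "lengths")
  # 3D error statistics: constant 1 mm AP offset
  ref <- trajectory3d(path[, 1], path[, 2], path[, 3])
  off <- trajectory3d(path[, 1], path[, 2], path[, 3] + 1)
  stats <- error_stats_3d(off, ref)
  expect_equal(stats$axis$mean, c(0, 0, 1))
  expect_equal(stats$median_mm, 1)
  expect_equal(stats$iqr_mm, 0)
  # brute-force agreement on random pairs
  set.seed(17)
  r1 <- trajectory3d(rnorm(20), rnorm(20), rnorm(20))
  r2 <- trajectory3d(rnorm(20), rnorm(20), rnorm(20))
  s <- error_stats_3d(r1, r2)
  euc <- sapply(1:20, function(i) sqrt((r1$X_mm[i] - r2$X_mm[i])^2 +
                                         (r1$Y_mm[i] - r2$Y_mm[i])^2 +
                                         (r1$Z_mm[i] - r2$Z_mm[i])^2))
  expect_equal(s$euclidean_mm, euc)
  expect_equal(s$axis$mean[1], mean(abs(r1$X_mm - r2$X_mm)))
})

test_that("template tracker recovers integer and subpixel shifts", {
  H <- 48; W <- 48
  dot <- function(cx, cy) {
    x <- matrix(0:(W - 1), H, W, byrow = TRUE)
    y <- matrix(0:(H - 1), H, W)
    220 * exp(-((x - cx)^2 + (y - cy)^2) / (2 * 2.5^2)) + 10
  }
  shifts <- cbind(c(0, 1, 3, 2, -1), c(0, -2, 1, 4, 2))
  stack <- as_stack(lapply(seq_len(nrow(shifts)), function(k)
    dot(20 + shifts[k, 1], 24 + shifts[k, 2])))
  template <- dot(20, 24)[(24 - 6):(24 + 8), (20 - 6):(20 + 8)]
  tr <- marker_track_template(stack, template, start = c(20, 24),
                              search_radius = 6)
  expect_equal(tr$x_px, 20 + shifts[, 1], tolerance = 0.05)
  expect_equal(tr$y_px, 24 + shifts[, 2], tolerance = 0.05)
  # subpixel half-px shifts recovered within 0.2 px
  stack2 <- as_stack(list(dot(20, 24), dot(20.5, 24), dot(20, 24.5)))
  tr2 <- marker_track_template(stack2, template, start = c(20, 24),
                               search_radius = 4)
  expect_lt(abs(tr2$x_px[2] - 20.5), 0.2)
  expect_lt(abs(tr2$y_px[3] - 24.5), 0.2)
  expect_error(marker_track_template(stack, matrix(0, 60, 60), c(20, 24)),
               "larger")
})

test_that("trajectory CSV round trip preserves coordinates and flags", {
  tr <- trajectory2d(rnorm(10), rnorm(10), fs = 30,
                     flag = rep(c(TRUE, FALSE), 5))
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(back$x_px, tr$x_px)
  expect_equal(back$flag, tr$flag)
  expect_equal(attr(back, "fs"), 30)
  t3 <- trajectory3d(rnorm(5), rnorm(5), rnorm(5))
  f3 <- tempfile(fileext = ".csv")
  write_trajectory(t3, f3)
  b3 <- read_trajectory(f3)
  expect_s3_class(b3, "trajectory3d")
  expect_equal(b3$Z_mm, t3$Z_mm)
})
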