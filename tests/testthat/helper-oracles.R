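# Independent brute-force oracles used across the test files. These stay
# deliberately naive (loops, enumeration) so they do not share code paths
# with the implementations they check.

# Distinct mask voxels entered by the ray source -> detector point, by
# exhaustive enumeration: every voxel is intersected with the ray as an
# axis-aligned box and counted when the chord length is positive. Exact for
# every ray that does not touch a voxel exactly on a face or corner
# (measure-zero under the randomized geometries used in tests).
oracle_ray_voxel_count <- function(mask_vol, source, det_pt) {
  sp <- mask_vol$spacing
  org <- mask_vol$origin
  n <- dim(mask_vol$values)
  on <- which(mask_vol$values != 0, arr.ind = TRUE)
  if (nrow(on) == 0L) return(0L)
  dir <- det_pt - source
  dir <- dir / sqrt(sum(dir^2))
  count <- 0L
  for (r in seq_len(nrow(on))) {
    lo <- org + (on[r, ] - 1.5) * sp
    hi <- lo + sp
    t0 <- -Inf; t1 <- Inf
    miss <- FALSE
    for (a in 1:3) {
      if (abs(dir[a]) < 1e-14) {
        if (source[a] < lo[a] || source[a] > hi[a]) { miss <- TRUE; break }
      } else {
        ta <- (lo[a] - source[a]) / dir[a]
        tb <- (hi[a] - source[a]) / dir[a]
        t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
      }
    }
    if (!miss && t1 > t0 && t1 > 0) count <- count + 1L
  }
  count
}

# Brute-force binary erosion / dilation with an arbitrary 0/1 kernel whose
# anchor is its geometric center (matching even-kernel centering).
oracle_erode <- function(img, kern) {
  H <- nrow(img); W <- ncol(img)
  kh <- nrow(kern); kw <- ncol(kern)
  ay <- (kh + 1) %/% 2; ax <- (kw + 1) %/% 2  # anchor (1-based)
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ok <- TRUE
    for (di in seq_len(kh)) {
      for (dj in seq_len(kw)) {
        if (kern[di, dj] == 0) next
        ii <- i + di - ay; jj <- j + dj - ax
        v <- if (ii < 1 || ii > H || jj < 1 || jj > W) 0 else img[ii, jj]
        if (v == 0) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    out[i, j] <- as.integer(ok)
  }
  out
}

oracle_dilate <- function(img, kern) {
  H <- nrow(img); W <- ncol(img)
  kh <- nrow(kern); kw <- ncol(kern)
  ay <- (kh + 1) %/% 2; ax <- (kw + 1) %/% 2
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (img[i, j] == 0) next
    for (di in seq_len(kh)) for (dj in seq_len(kw)) {
      if (kern[di, dj] == 0) next
      ii <- i - (di - ay); jj <- j - (dj - ax)
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) out[ii, jj] <- 1L
    }
  }
  out
}

# Random non-degenerate stereo geometry pair for round-trip properties.
random_stereo_pair <- function(image_size = c(64L, 64L)) {
  one <- function() {
    th <- runif(1, 0, 2 * pi)
    ph <- runif(1, -0.4, 0.4)
    axis <- c(cos(ph) * sin(th), sin(ph), cos(ph) * cos(th))
    up <- c(0, 1, 0)
    u <- c(axis[3], 0, -axis[1])
    u <- u / sqrt(sum(u^2))
    v <- c(u[2] * axis[3] - u[3] * axis[2],
           u[3] * axis[1] - u[1] * axis[3],
           u[1] * axis[2] - u[2] * axis[1])
    v <- v / sqrt(sum(v^2))
    sad <- runif(1, 1500, 2500)
    sid <- sad + runif(1, 800, 1500)
    projection_geometry(source = -sad * axis,
                        detector_center = (sid - sad) * axis,
                        u = u, v = v,
                        pixel_pitch = runif(1, 0.3, 0.6),
                        image_size = image_size)
  }
  repeat {
    ga <- one(); gb <- one()
    ang <- acos(min(1, abs(sum(
      (ga$source / sqrt(sum(ga$source^2))) *
        (gb$source / sqrt(sum(gb$source^2)))))))
    if (ang > 20 * pi / 180) return(list(ga, gb))
  }
}

# Small thorax phantom + stereo geometry shared by sequence-level tests.
small_thorax_fixture <- function(image_size = c(64L, 64L),
                                 pixel_pitch = 1.2,
                                 tumor_radii = c(8, 10, 8)) {
  ph <- make_thorax_phantom(tumor_center = c(0, 0, 0),
                            tumor_radii = tumor_radii,
                            marker_centers = list(c(15, 10, -5)),
                            voxel_spacing = c(2, 2, 2),
                            extent_mm = 80)
  geoms <- stereo_geometry(image_size = image_size,
                           pixel_pitch = pixel_pitch)
  list(phantom = ph, geoms = geoms)
}
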