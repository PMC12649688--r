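#' Degradation-model parameters
#'
#' All scalars that determine one stochastic degradation draw: the upper
#' limits `Pmax` / `Mmax` of the noise-probability and noise-amplitude maps,
#' the base levels `Bp` / `Ba` at the beam center, the central flatness
#' radius `sigma_d`, the beam-center offset `Xc` from the image geometric
#' center, the diffusion blur width, the global noise mean `mu` and the RNG
#' seed. Defaults `Pmax = 0.92`, `Mmax = 16` are the experimentally observed
#' ceilings; `mu = 0` unless a device characterization supplies one.
#'
#' @param Pmax upper probability limit (default 0.92).
#' @param Mmax upper amplitude limit in intensity levels (default 16).
#' @param Bp base noise probability at the beam center (default 0.36).
#' @param Ba base noise amplitude (default 1.9).
#' @param sigma_d central flatness radius in px (default 108).
#' @param Xc beam-center offset `(x, y)` in px (default `c(0, 0)`).
#' @param diffusion_sigma Gaussian diffusion width in px (default 2.0).
#' @param noise_mean global noise mean `mu` in intensity levels (default 0).
#' @param seed integer RNG seed (default 1).
#' @return object of class `degradation_params`.
#' @export
degradation_params <- function(Pmax = 0.92, Mmax = 16, Bp = 0.36, Ba = 1.9,
                               sigma_d = 108, Xc = c(0, 0),
                               diffusion_sigma = 2.0, noise_mean = 0,
                               seed = 1L) {
  if (!(Bp >= 0 && Bp <= Pmax && Pmax <= 1))
    stop("need 0 <= Bp <= Pmax <= 1")
  if (!(Ba >= 0 && Ba <= Mmax))
    stop("need 0 <= Ba <= Mmax")
  if (sigma_d <= 0) stop("sigma_d must be positive")
  if (diffusion_sigma < 0) stop("diffusion_sigma must be >= 0")
  structure(list(Pmax = Pmax, Mmax = Mmax, Bp = Bp, Ba = Ba,
                 sigma_d = sigma_d, Xc = as.numeric(Xc),
                 diffusion_sigma = diffusion_sigma,
                 noise_mean = noise_mean, seed = as.integer(seed)),
            class = "degradation_params")
}

#' Radial distance map from the beam center
#'
#' Distance of every pixel from the actual beam center
#' `d_img + Xc`, where `d_img = ((W-1)/2, (H-1)/2)` is the image geometric
#' center and `Xc` the beam-center offset.
#'
#' @param image_size `(width, height)` px.
#' @param Xc beam-center offset `(x, y)` px.
#' @return `H x W` matrix of distances in px.
#' @export
radial_distance_map <- function(image_size, Xc = c(0, 0)) {
  W <- as.integer(image_size[1]); H <- as.integer(image_size[2])
  if (W <= 0L || H <= 0L) stop("image size must be positive")
  cx <- (W - 1) / 2 + Xc[1]
  cy <- (H - 1) / 2 + Xc[2]
  x <- matrix(0:(W - 1), H, W, byrow = TRUE)
  y <- matrix(0:(H - 1), H, W)
  sqrt((x - cx)^2 + (y - cy)^2)
}

#' Spatial dependency factor
#'
#' `B + F_d(d, sigma_d)` with the core radial modification function
#' `F_d(d, sigma_d) = 1 - exp(-d^2 / (2 sigma_d^2))`: noise is at its base
#' level at the beam center and rises towards the periphery, with
#' `sigma_d` controlling how far the central flat region extends.
#'
#' @param d radial distances (px), any shape.
#' @param sigma_d central flatness radius (px, > 0).
#' @param B base noise level (probability `Bp` or amplitude `Ba`).
#' @return values of the same shape as `d`, in `[B, B + 1)`.
#' @export
spatial_factor <- function(d, sigma_d, B) {
  if (sigma_d <= 0) stop("sigma_d must be positive")
  B + (1 - exp(-d^2 / (2 * sigma_d^2)))
}

#' Affine rescaling of a raw noise-characteristic map
#'
#' Linearly maps the raw map so its minimum lands on the base level `B` and
#' its maximum on `Max`. A constant raw map (no content or spatial variation)
#' maps entirely to `B`.
#'
#' @param raw numeric matrix.
#' @param B target minimum.
#' @param Max target maximum (`Max >= B`).
#' @return rescaled matrix with `min = B`, `max = Max`.
#' @export
scale_map <- function(raw, B, Max) {
  if (Max < B) stop("need Max >= B")
  lo <- min(raw); hi <- max(raw)
  if (hi - lo < .Machine$double.eps * max(1, abs(hi)))
    return(array(B, dim = dim(raw)))
  B + (raw - lo) / (hi - lo) * (Max - B)
}

#' Noise probability and amplitude maps for a clean image
#'
#' Composes the content dependency (polynomial in the clean intensity V) and
#' the spatial dependency (radial about the beam center) and rescales each
#' product map into its target range: probabilities in `[Bp, Pmax]`,
#' amplitudes in `[Ba, Mmax]`.
#'
#' @param clean numeric `H x W` matrix with values in `[0, 255]`.
#' @param params a `degradation_params`.
#' @param curves a `content_curves` (default the shipped defaults).
#' @return list with `np_map` and `na_map` (`H x W` matrices).
#' @export
build_noise_maps <- function(clean, params, curves = default_content_curves()) {
  stopifnot(inherits(params, "degradation_params"))
  d <- radial_distance_map(c(ncol(clean), nrow(clean)), params$Xc)
  fvp <- matrix(content_factor(as.numeric(clean), curves, "prob"),
                nrow(clean), ncol(clean))
  fva <- matrix(content_factor(as.numeric(clean), curves, "amp"),
                nrow(clean), ncol(clean))
  np <- scale_map(fvp * spatial_factor(d, params$sigma_d, params$Bp),
                  params$Bp, params$Pmax)
  na <- scale_map(fva * spatial_factor(d, params$sigma_d, params$Ba),
                  params$Ba, params$Mmax)
  list(np_map = np, na_map = na)
}

#' Draw randomized degradation parameters
#'
#' Resampling strategy used when building a degraded dataset so that the
#' simulated frames span a family of devices and acquisition settings: each
#' beam-offset component `Xc ~ Normal(0, 30 px)` (independent per component,
#' SD 30), `sigma_d ~ Uniform(103, 113)`, `Bp ~ Uniform(0.35, 0.37)`,
#' `Ba ~ Uniform(1.8, 2.0)`; `Pmax`, `Mmax`, the diffusion width and `mu`
#' stay at their defaults.
#'
#' @param seed integer seed; the same seed reproduces the same draw.
#' @return a `degradation_params`.
#' @export
sample_degradation_params <- function(seed) {
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  Xc <- stats::rnorm(2, 0, 30)
  sigma_d <- stats::runif(1, 103, 113)
  Bp <- stats::runif(1, 0.35, 0.37)
  Ba <- stats::runif(1, 1.8, 2.0)
  degradation_params(Bp = Bp, Ba = Ba, sigma_d = sigma_d, Xc = Xc, seed = seed)
}

#' Separable Gaussian blur with reflective boundaries
#'
#' @param img numeric matrix.
#' @param sigma Gaussian SD in px; 0 returns the input.
#' @param truncate kernel half-width in SDs (default 4).
#' @return blurred matrix.
#' @keywords internal
gaussian_blur <- function(img, sigma, truncate = 4) {
  if (sigma == 0) return(img)
  r <- max(1L, ceiling(truncate * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  reflect_pad_filter <- function(m) {
    n <- nrow(m)
    idx <- c(rev(seq_len(min(r, n))), seq_len(n), n + 1 - rev(seq_len(min(r, n))))
    if (r > n) stop("blur kernel larger than image")
    padded <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * padded[(j - 1) + seq_len(n), , drop = FALSE]
    out
  }
  t(reflect_pad_filter(t(reflect_pad_filter(img))))
}

#' Stochastic noise generation and diffusion
#'
#' Degrades a clean 8-bit-range frame with content- and spatially-dependent
#' noise: (1) draw a uniform matrix R and form the event mask
#' `M = R < Np`; (2) at masked pixels draw primary noise
#' `Normal(mu, sd = Na(p))`; (3) diffuse the sparse noise with a Gaussian
#' filter of width `diffusion_sigma` (reflective boundary, kernel truncated
#' at 4 SD) and add it to the clean frame; (4) draw fresh secondary noise at
#' the same masked pixels and add it; (5) clip to `[0, 255]` and quantize to
#' 8-bit. All randomness is determined by `params$seed`; draw order is the
#' R matrix, then primary values in column-major masked order, then
#' secondary values.
#'
#' With `diffusion = FALSE` the whole diffusion stage (blur and secondary
#' noise) is skipped, leaving pure sparse Bernoulli-Gaussian noise whose
#' per-pixel statistics have closed forms — the mode used for statistical
#' validation. `clip`/`quantize` can likewise be disabled for exact
#' statistical tests.
#'
#' @param clean numeric `H x W` matrix in `[0, 255]`.
#' @param params a `degradation_params`.
#' @param curves a `content_curves`.
#' @param maps optional precomputed result of [build_noise_maps()] (reused
#'   across frames of a static scene).
#' @param diffusion apply the blur + secondary-noise stage (default TRUE).
#' @param clip clip the result to `[0, 255]` (default TRUE).
#' @param quantize round to 8-bit integers (default TRUE).
#' @return degraded `H x W` matrix.
#' @export
degrade <- function(clean, params, curves = default_content_curves(),
                    maps = NULL, diffusion = TRUE, clip = TRUE,
                    quantize = TRUE) {
  stopifnot(inherits(params, "degradation_params"))
  if (is.null(maps)) maps <- build_noise_maps(clean, params, curves)
  np <- maps$np_map; na <- maps$na_map
  if (!all(dim(np) == dim(clean))) stop("noise maps do not match the frame")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)
  R <- matrix(stats::runif(length(clean)), nrow(clean), ncol(clean))
  M <- R < np
  nmask <- sum(M)
  sparse <- matrix(0, nrow(clean), ncol(clean))
  if (nmask > 0)
    sparse[M] <- stats::rnorm(nmask, params$noise_mean, na[M])
  if (diffusion) {
    out <- clean + gaussian_blur(sparse, params$diffusion_sigma)
    if (nmask > 0)
      out[M] <- out[M] + stats::rnorm(nmask, params$noise_mean, na[M])
  } else {
    out <- clean + sparse
  }
  if (clip) out <- pmin(pmax(out, 0), 255)
  if (quantize) out <- round(out)
  out
}

#' Build a paired clean/degraded training dataset
#'
#' For every clean image in `clean_dir`, draws `variants_per_image` fresh
#' parameter sets (beam offset, flatness radius, base levels resampled per
#' variant) and writes the degraded PNGs plus a manifest CSV pairing each
#' degraded file with its clean source and recording the parameters used.
#' Unreadable inputs are skipped with a warning.
#'
#' @param clean_dir directory of clean 8-bit PNG/TIFF images.
#' @param variants_per_image degraded copies per clean image.
#' @param master_seed integer; variant seeds are derived from it by counter,
#'   so the whole dataset is reproducible.
#' @param out_dir output directory.
#' @param curves a `content_curves`.
#' @return the manifest as a data.frame (also written to
#'   `out_dir/manifest.csv`).
#' @export
build_paired_dataset <- function(clean_dir, variants_per_image, master_seed,
                                 out_dir, curves = default_content_curves()) {
  files <- sort(list.files(clean_dir, pattern = "\\.(png|tif|tiff)$",
                           full.names = TRUE, ignore.case = TRUE))
  if (length(files) == 0L) stop("no clean images in ", clean_dir)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- list()
  counter <- 0L
  for (f in files) {
    clean <- tryCatch(read_frame(f), error = function(e) {
      warning("skipping unreadable input: ", f, call. = FALSE)
      NULL
    })
    if (is.null(clean)) next
    for (vv in seq_len(variants_per_image)) {
      counter <- counter + 1L
      seed <- (as.integer(master_seed) + 7919L * counter) %% .Machine$integer.max
      params <- sample_degradation_params(seed)
      deg <- degrade(clean, params, curves)
      out_name <- sprintf("%s_deg%02d.png",
                          tools::file_path_sans_ext(basename(f)), vv)
      out_path <- file.path(out_dir, out_name)
      png::writePNG(deg / 255, out_path)
      rows[[length(rows) + 1L]] <- data.frame(
        clean_path = f, degraded_path = out_path, seed = seed,
        Bp = params$Bp, Ba = params$Ba, sigma_d = params$sigma_d,
        Xc_x = params$Xc[1], Xc_y = params$Xc[2])
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
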