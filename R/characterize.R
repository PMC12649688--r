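#' Per-pixel noise probability map
#'
#' Fraction of frames in which the absolute deviation from the temporal
#' average exceeds the threshold `tau`. The default `tau = 2` intensity
#' levels is appropriate when the average is computed from a large stack
#' (high SNR reference); noisier references need a larger threshold.
#'
#' @param stack `H x W x N` frame stack of a static scene.
#' @param avg temporal average frame (default computed from the stack).
#' @param tau intensity threshold (>= 0, default 2).
#' @return `H x W` matrix of probabilities in `[0, 1]`.
#' @export
noise_probability_map <- function(stack, avg = average_frames(stack), tau = 2) {
  stack <- as_stack(stack)
  if (tau < 0) stop("tau must be >= 0")
  if (!all(dim(avg) == dim(stack)[1:2])) stop("avg/stack shape mismatch")
  rowMeans(abs(stack - as.vector(avg)) > tau, dims = 2)
}

#' Per-pixel noise amplitude map
#'
#' Mean absolute deviation from the temporal average across frames.
#'
#' @inheritParams noise_probability_map
#' @return `H x W` matrix of amplitudes (intensity levels, >= 0).
#' @export
noise_amplitude_map <- function(stack, avg = average_frames(stack)) {
  stack <- as_stack(stack)
  if (!all(dim(avg) == dim(stack)[1:2])) stop("avg/stack shape mismatch")
  rowMeans(abs(stack - as.vector(avg)), dims = 2)
}

#' Intensity-binned noise curves
#'
#' Bins in-mask pixels by their rounded average-image intensity (256 bins,
#' 0..255) and returns per-bin means of the noise probability and amplitude
#' maps, plus the bin counts. Background pixels (outside the SB mask) are
#' excluded. Empty bins are NA.
#'
#' @param avg average (clean-content proxy) frame.
#' @param pn_map,an_map noise probability and amplitude maps.
#' @param sb_mask binary mask of valid (foreground) pixels.
#' @return data.frame with `intensity`, `pn`, `an`, `count`.
#' @export
intensity_curves <- function(avg, pn_map, an_map, sb_mask) {
  stopifnot(all(dim(avg) == dim(pn_map)), all(dim(avg) == dim(an_map)),
            all(dim(avg) == dim(sb_mask)))
  keep <- sb_mask != 0
  bins <- pmin(pmax(round(avg[keep]), 0), 255)
  f <- factor(bins, levels = 0:255)
  data.frame(
    intensity = 0:255,
    pn = as.numeric(tapply(pn_map[keep], f, mean)),
    an = as.numeric(tapply(an_map[keep], f, mean)),
    count = as.integer(table(f)))
}

#' Estimate the X-ray beam center from the average image
#'
#' Intensity-weighted centroid of the in-mask pixels at or above the 90th
#' brightness percentile — the bright core of the beam. On a flat image the
#' centroid is undefined; the image geometric center is returned with a
#' `flat` flag.
#'
#' @param avg average frame.
#' @param sb_mask binary foreground mask.
#' @return list with `center` = `(x, y)` px and logical `flat`.
#' @export
estimate_beam_center <- function(avg, sb_mask) {
  keep <- sb_mask != 0
  if (!any(keep)) stop("empty mask")
  vals <- avg[keep]
  ctr <- c((ncol(avg) - 1) / 2, (nrow(avg) - 1) / 2)
  if (max(vals) - min(vals) < .Machine$double.eps * max(1, abs(max(vals))))
    return(list(center = ctr, flat = TRUE))
  q <- stats::quantile(vals, 0.90, names = FALSE)
  sel <- keep & avg >= q
  x <- matrix(0:(ncol(avg) - 1), nrow(avg), ncol(avg), byrow = TRUE)
  y <- matrix(0:(nrow(avg) - 1), nrow(avg), ncol(avg))
  w <- avg[sel]
  list(center = c(sum(x[sel] * w), sum(y[sel] * w)) / sum(w), flat = FALSE)
}

#' Calibrate spatial noise parameters from observed maps
#'
#' Bins an observed noise map radially about the estimated beam center and
#' fits the radial model `B + (Max - B) * F_d(d, sigma_d)` with
#' `F_d = 1 - exp(-d^2 / (2 sigma_d^2))` by grid search over
#' `(sigma_d, B)`; for each grid point `Max` has a closed-form least-squares
#' solution because the model is linear in it. Both the probability and
#' amplitude maps are fitted. A spatially constant map cannot constrain
#' `sigma_d`; it is then reported at the top of the grid with an
#' `insensitive` flag (the flat-field case of newer collimated devices).
#'
#' @param pn_map,an_map observed noise probability / amplitude maps.
#' @param beam_center `(x, y)` px about which to bin radially.
#' @param sigma_grid candidate `sigma_d` values (px).
#' @param base_grid candidate base levels; probabilities are fitted over
#'   `base_grid$p`, amplitudes over `base_grid$a` (each a numeric vector).
#' @param n_rbins number of radial bins (default 48).
#' @return list with `sigma_d_hat`, `Bp_hat`, `Ba_hat`, `Pmax_hat`,
#'   `Mmax_hat`, `sse`, `insensitive`.
#' @export
calibrate_spatial <- function(pn_map, an_map, beam_center,
                              sigma_grid = seq(60, 160, by = 2),
                              base_grid = list(p = seq(0.30, 0.45, by = 0.005),
                                               a = seq(1.5, 3.0, by = 0.05)),
                              n_rbins = 48L) {
  if (length(sigma_grid) == 0L || length(base_grid$p) == 0L ||
      length(base_grid$a) == 0L)
    stop("empty parameter grid")
  radial_profile <- function(m) {
    x <- matrix(0:(ncol(m) - 1), nrow(m), ncol(m), byrow = TRUE)
    y <- matrix(0:(nrow(m) - 1), nrow(m), ncol(m))
    d <- sqrt((x - beam_center[1])^2 + (y - beam_center[2])^2)
    br <- seq(0, max(d) + 1e-9, length.out = n_rbins + 1)
    f <- cut(as.numeric(d), br, include.lowest = TRUE)
    list(d = as.numeric(tapply(as.numeric(d), f, mean)),
         v = as.numeric(tapply(as.numeric(m), f, mean)))
  }
  fit_one <- function(prof, bases) {
    keep <- !is.na(prof$v)
    d <- prof$d[keep]; v <- prof$v[keep]
    if (max(v) - min(v) < 1e-9) {
      return(list(sigma = max(sigma_grid), B = mean(v), Max = mean(v),
                  sse = 0, insensitive = TRUE))
    }
    best <- list(sse = Inf)
    for (s in sigma_grid) {
      Fd <- 1 - exp(-d^2 / (2 * s^2))
      for (B in bases) {
        # model = B + (Max - B) Fd, linear in Max given (B, sigma)
        resid_target <- v - B
        denom <- sum(Fd^2)
        Max <- if (denom > 0) B + sum(Fd * resid_target) / denom else B
        if (Max < B) Max <- B
        sse <- sum((B + (Max - B) * Fd - v)^2)
        if (sse < best$sse)
          best <- list(sigma = s, B = B, Max = Max, sse = sse,
                       insensitive = FALSE)
      }
    }
    best
  }
  fp <- fit_one(radial_profile(pn_map), base_grid$p)
  fa <- fit_one(radial_profile(an_map), base_grid$a)
  # one shared sigma: keep the probability fit's sigma unless it was flat
  sigma_hat <- if (fp$insensitive) fa$sigma else fp$sigma
  list(sigma_d_hat = sigma_hat, Bp_hat = fp$B, Ba_hat = fa$B,
       Pmax_hat = fp$Max, Mmax_hat = fa$Max, sse = fp$sse + fa$sse,
       insensitive = fp$insensitive && fa$insensitive)
}

#' Full empirical noise characterization of a static-scene stack
#'
#' Runs the four-step device calibration on a stack of frames of a static
#' phantom: (1) temporal average as the clean reference; (2) noise
#' probability and amplitude maps against it; (3) intensity-noise curves
#' inside the SB mask, smoothed and fitted with degree-`degree` polynomials;
#' (4) beam-center estimation and radial spatial-parameter search.
#'
#' @param stack `H x W x N` frame stack.
#' @param tau noise threshold (default 2).
#' @param degree content-curve polynomial degree (default 10).
#' @param sb_mask binary foreground mask (default the inscribed circle).
#' @param sigma_grid,base_grid passed to [calibrate_spatial()].
#' @return object of class `characterization` with fields `avg_image`,
#'   `pn_map`, `an_map`, `tau`, `curves`, `intensity_table`, `beam_center`,
#'   `flat_beam`, `sigma_d_hat`, `base_levels`, `max_levels`,
#'   `noise_mean_hat`, `spatially_insensitive`.
#' @export
characterize_frames <- function(stack, tau = 2, degree = 10L, sb_mask = NULL,
                                sigma_grid = seq(60, 160, by = 2),
                                base_grid = list(p = seq(0.30, 0.45, by = 0.005),
                                                 a = seq(1.5, 3.0, by = 0.05))) {
  stack <- as_stack(stack)
  avg <- average_frames(stack)
  if (is.null(sb_mask))
    sb_mask <- standard_background_mask(c(ncol(avg), nrow(avg)))
  pn <- noise_probability_map(stack, avg, tau)
  an <- noise_amplitude_map(stack, avg)
  tab <- intensity_curves(avg, pn, an, sb_mask)
  curves <- content_curves(
    fit_content_curve(tab$pn, degree = degree),
    fit_content_curve(tab$an, degree = degree),
    amp_factor = 1)  # empirical curves already on the amplitude scale
  bc <- estimate_beam_center(avg, sb_mask)
  cal <- calibrate_spatial(pn, an, bc$center, sigma_grid, base_grid)
  keep <- sb_mask != 0
  noise_mean_hat <- mean(sweep(stack, 1:2, avg)[rep(keep, dim(stack)[3])])
  structure(list(avg_image = avg, pn_map = pn, an_map = an, tau = tau,
                 curves = curves, intensity_table = tab,
                 beam_center = bc$center, flat_beam = bc$flat,
                 sigma_d_hat = cal$sigma_d_hat,
                 base_levels = c(Bp = cal$Bp_hat, Ba = cal$Ba_hat),
                 max_levels = c(Pmax = cal$Pmax_hat, Mmax = cal$Mmax_hat),
                 noise_mean_hat = noise_mean_hat,
                 spatially_insensitive = cal$insensitive),
            class = "characterization")
}

#' @export
print.characterization <- function(x, ...) {
  cat(sprintf("<characterization> %d x %d px, tau = %g\n",
              ncol(x$avg_image), nrow(x$avg_image), x$tau))
  cat(sprintf("  beam center (%.1f, %.1f) px%s; sigma_d_hat = %.1f px%s\n",
              x$beam_center[1], x$beam_center[2],
              if (x$flat_beam) " [flat image]" else "",
              x$sigma_d_hat,
              if (x$spatially_insensitive) " [spatially insensitive]" else ""))
  cat(sprintf("  base levels Bp = %.3f, Ba = %.2f; ceilings Pmax = %.3f, Mmax = %.2f\n",
              x$base_levels["Bp"], x$base_levels["Ba"],
              x$max_levels["Pmax"], x$max_levels["Mmax"]))
  cat(sprintf("  global noise mean %.4f\n", x$noise_mean_hat))
  invisible(x)
}

#' Persist a characterization result
#'
#' Scalars and fitted polynomial coefficients go to JSON; the average image
#' and the two noise maps are written as 32-bit float TIFFs next to it.
#'
#' @param ch a `characterization`.
#' @param path JSON output path; map TIFFs use the same stem.
#' @export
write_characterization <- function(ch, path) {
  stem <- tools::file_path_sans_ext(path)
  obj <- list(tau = ch$tau, beam_center = ch$beam_center,
              flat_beam = ch$flat_beam, sigma_d_hat = ch$sigma_d_hat,
              base_levels = as.list(ch$base_levels),
              max_levels = as.list(ch$max_levels),
              noise_mean_hat = ch$noise_mean_hat,
              spatially_insensitive = ch$spatially_insensitive,
              curves = list(prob_poly = unclass(ch$curves$prob_poly),
                            amp_poly = unclass(ch$curves$amp_poly),
                            amp_factor = ch$curves$amp_factor))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  tiff::writeTIFF(ch$avg_image / 255, paste0(stem, "_avg.tif"),
                  bits.per.sample = 32L)
  tiff::writeTIFF(ch$pn_map, paste0(stem, "_pn.tif"), bits.per.sample = 32L)
  tiff::writeTIFF(ch$an_map / 255, paste0(stem, "_an.tif"),
                  bits.per.sample = 32L)
  invisible(path)
}
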