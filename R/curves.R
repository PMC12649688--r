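#' Intensity-dependence polynomials (content curves)
#'
#' The degradation model's content dependency `f_vp(V)` / `f_va(V)` — how
#' noise probability and amplitude vary with the underlying clean pixel
#' intensity V — is represented by degree-10 polynomials fitted to smoothed
#' empirical intensity-noise curves. Coefficients are stored over the scaled
#' variable `u = (V - center) / scale` with `center = scale = 127.5`, so the
#' Vandermonde basis stays well-conditioned over V in 0..255; evaluation is
#' by Horner's scheme. The amplitude curve is additionally multiplied by
#' `amp_factor` (default 2) at evaluation time to match the empirical
#' amplitude scale.
#'
#' @param prob_poly,amp_poly objects returned by [fit_content_curve()].
#' @param amp_factor multiplier applied to the amplitude curve (default 2).
#' @return an object of class `content_curves`.
#' @export
content_curves <- function(prob_poly, amp_poly, amp_factor = 2) {
  stopifnot(inherits(prob_poly, "intensity_poly"),
            inherits(amp_poly, "intensity_poly"))
  structure(list(prob_poly = prob_poly, amp_poly = amp_poly,
                 amp_factor = amp_factor),
            class = "content_curves")
}

#' Construct an intensity polynomial from raw coefficients
#' @param coef coefficients, constant term first, over the scaled variable.
#' @param center,scale affine scaling of intensity: `u = (V - center)/scale`.
#' @return object of class `intensity_poly`.
#' @export
intensity_poly <- function(coef, center = 127.5, scale = 127.5) {
  structure(list(coef = as.numeric(coef), center = center, scale = scale),
            class = "intensity_poly")
}

#' Evaluate an intensity polynomial (Horner's scheme)
#' @param p an `intensity_poly`.
#' @param v intensity values.
#' @return polynomial values (unclipped).
#' @export
eval_intensity_poly <- function(p, v) {
  u <- (v - p$center) / p$scale
  acc <- rep(p$coef[length(p$coef)], length(u))
  for (k in seq(length(p$coef) - 1, 1)) acc <- acc * u + p$coef[k]
  acc
}

#' Content-dependency factor of the degradation model
#'
#' Evaluates the fitted intensity polynomial at clean-image intensities,
#' clipped at zero; for `kind = "amp"` the result is multiplied by the
#' curves' amplitude factor.
#'
#' @param v intensity values in `[0, 255]`.
#' @param curves a `content_curves` object.
#' @param kind `"prob"` or `"amp"`.
#' @return non-negative factor values.
#' @export
content_factor <- function(v, curves, kind = c("prob", "amp")) {
  kind <- match.arg(kind)
  if (any(v < 0 | v > 255)) stop("intensity out of [0, 255]")
  if (kind == "prob") {
    pmax(0, eval_intensity_poly(curves$prob_poly, v))
  } else {
    curves$amp_factor * pmax(0, eval_intensity_poly(curves$amp_poly, v))
  }
}

#' Centered moving average with partial windows at the edges
#' @keywords internal
moving_average <- function(x, window) {
  h <- window %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - h):min(n, i + h)]
    mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Fit a content curve to binned intensity-noise data
#'
#' Smooths the per-intensity-bin curve with a centered moving average and
#' fits a least-squares polynomial of the requested degree on the scaled
#' intensity variable. Empty (NA) bins are excluded from the fit.
#'
#' @param bin_values numeric vector of per-bin values indexed by intensity
#'   `0..length-1`; empty bins as NA.
#' @param degree polynomial degree (default 10).
#' @param smoothing_window moving-average window in bins (default 9).
#' @return an `intensity_poly`.
#' @export
fit_content_curve <- function(bin_values, degree = 10L, smoothing_window = 9L) {
  v <- seq_along(bin_values) - 1
  sm <- moving_average(bin_values, smoothing_window)
  keep <- !is.na(bin_values) & !is.na(sm)
  if (sum(keep) < degree + 1)
    stop("need at least degree + 1 populated bins (have ", sum(keep), ")")
  center <- 127.5; scale <- 127.5
  u <- (v[keep] - center) / scale
  X <- outer(u, 0:degree, `^`)
  coef <- stats::lm.fit(X, sm[keep])$coefficients
  coef[is.na(coef)] <- 0
  intensity_poly(unname(coef), center, scale)
}

#' Default shipped content curves
#'
#' Device-specific fitted polynomial coefficients are calibration outputs and
#' are not universal; the shipped defaults reproduce the canonical four-phase
#' intensity dependence observed on a kV image-intensifier system: rapid
#' ascent over intensities 0-85, a plateau over 85-190 (probability about
#' 0.81, amplitude about 6.5), a sharp decline over 190-225 (bright-region
#' noise clipped by the 255 ceiling), and a recovery over 225-255 (about
#' 0.56 / 2.75). Piecewise-linear knots through those phases are smoothed and
#' polynomial-fitted exactly as a real calibration would be.
#'
#' @param degree polynomial degree (default 10).
#' @return a `content_curves` object.
#' @export
default_content_curves <- function(degree = 10L) {
  v <- 0:255
  knots_v <- c(0, 85, 190, 225, 240, 255)
  prob_k <- c(0.10, 0.81, 0.81, 0.40, 0.56, 0.56)
  amp_k <- c(1.00, 6.50, 6.50, 1.80, 2.75, 2.75)
  prob_raw <- stats::approx(knots_v, prob_k, xout = v)$y
  amp_raw <- stats::approx(knots_v, amp_k, xout = v)$y
  content_curves(fit_content_curve(prob_raw, degree = degree),
                 fit_content_curve(amp_raw, degree = degree),
                 amp_factor = 2)
}

#' Read / write content curves as JSON
#' @param curves a `content_curves`.
#' @param path JSON path.
#' @export
write_content_curves <- function(curves, path) {
  obj <- list(prob_poly = unclass(curves$prob_poly),
              amp_poly = unclass(curves$amp_poly),
              amp_factor = curves$amp_factor)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_content_curves
#' @export
read_content_curves <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  content_curves(intensity_poly(o$prob_poly$coef, o$prob_poly$center,
                                o$prob_poly$scale),
                 intensity_poly(o$amp_poly$coef, o$amp_poly$center,
                                o$amp_poly$scale),
                 o$amp_factor)
}
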