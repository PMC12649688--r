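#' Harmonic respiratory motion model
#'
#' Periodic rigid displacement consisting of a fundamental sinusoid at the
#' breathing rate plus integer harmonics with configurable relative
#' amplitudes, optionally with an additive cardiac sinusoid. Respiratory
#' traces observed on fluoroscopy have exactly this structure: a fundamental
#' around 0.33 Hz (20 breaths/min) with harmonics decaying in amplitude.
#' Displacement is zero at `t = 0` when `phase = 0`, and (with the cardiac
#' term off) periodic with period `60 / rate_bpm` seconds.
#'
#' @param rate_bpm breathing rate, breaths/min (> 0; default 20).
#' @param amplitude_mm per-axis (LR, SI, AP) amplitude triple in mm.
#' @param harmonics list of `c(order, relative_amplitude)` pairs; orders are
#'   integers >= 2 and relative amplitudes lie in `[0, 1]`. Defaults: 2nd
#'   harmonic at 0.3, 3rd at 0.1.
#' @param cardiac_rate_bpm optional cardiac rate (beats/min).
#' @param cardiac_amplitude_mm per-axis cardiac amplitude (mm).
#' @param phase fundamental phase offset in radians.
#' @return object of class `motion_model`.
#' @export
motion_model <- function(rate_bpm = 20,
                         amplitude_mm = c(2, 8, 4),
                         harmonics = list(c(2, 0.3), c(3, 0.1)),
                         cardiac_rate_bpm = NULL,
                         cardiac_amplitude_mm = NULL,
                         phase = 0) {
  if (rate_bpm <= 0) stop("rate_bpm must be positive")
  for (h in harmonics) {
    if (h[1] < 2 || h[1] != round(h[1]))
      stop("harmonic orders must be integers >= 2")
    if (h[2] < 0 || h[2] > 1)
      stop("relative harmonic amplitudes must lie in [0, 1]")
  }
  if (!is.null(cardiac_rate_bpm) && cardiac_rate_bpm <= 0)
    stop("cardiac_rate_bpm must be positive")
  structure(list(rate_bpm = rate_bpm,
                 amplitude_mm = as.numeric(amplitude_mm),
                 harmonics = harmonics,
                 cardiac_rate_bpm = cardiac_rate_bpm,
                 cardiac_amplitude_mm = cardiac_amplitude_mm,
                 phase = phase),
            class = "motion_model")
}

#' Displacement of the motion model at given times
#'
#' Sum of the fundamental sinusoid at `rate_bpm / 60` Hz and its harmonics,
#' scaled per axis, plus the optional cardiac sinusoid. The waveform is
#' normalized so the per-axis amplitude stays interpretable: the harmonic
#' sum is divided by `1 + sum(relative amplitudes)`.
#'
#' @param model a `motion_model`.
#' @param t time(s) in seconds (>= 0); vectorized.
#' @return an `length(t) x 3` matrix of mm displacements (a plain triple for
#'   scalar `t`).
#' @export
respiratory_displacement <- function(model, t) {
  stopifnot(inherits(model, "motion_model"))
  if (any(t < 0)) stop("t must be >= 0")
  f0 <- model$rate_bpm / 60
  w <- sin(2 * pi * f0 * t + model$phase) - sin(model$phase)
  norm <- 1
  for (h in model$harmonics) {
    w <- w + h[2] * (sin(2 * pi * h[1] * f0 * t + h[1] * model$phase) -
                       sin(h[1] * model$phase))
    norm <- norm + h[2]
  }
  w <- w / norm
  disp <- outer(w, model$amplitude_mm)
  if (!is.null(model$cardiac_rate_bpm) &&
      !is.null(model$cardiac_amplitude_mm)) {
    fc <- model$cardiac_rate_bpm / 60
    wc <- sin(2 * pi * fc * t)
    disp <- disp + outer(wc, as.numeric(model$cardiac_amplitude_mm))
  }
  if (length(t) == 1L) as.numeric(disp) else disp
}
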