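#' Inject Bernoulli-Gaussian noise with known parameters
#'
#' Test fixture for the noise-characterization statistics: each frame is
#' `clean + Bernoulli(q_map) * Normal(mu, a_map)` per pixel, clipped to
#' `[0, 255]` unless `clip = FALSE` (exact closed-form statistical tests
#' need unclipped float values). Per-frame RNG substreams are derived from
#' `seed` by counter, so frame `k` is reproducible in isolation via
#' `frames = k`.
#'
#' @param clean numeric `H x W` matrix.
#' @param q_map per-pixel event probability (scalar or matrix in `[0, 1]`).
#' @param a_map per-pixel Gaussian SD (scalar or matrix, >= 0).
#' @param mu noise mean (intensity levels).
#' @param n_frames number of frames to generate.
#' @param seed integer seed.
#' @param clip clip to `[0, 255]` (default TRUE).
#' @param frames optional integer vector of frame indices to generate
#'   (default `1:n_frames`).
#' @return `H x W x length(frames)` array.
#' @export
inject_known_noise <- function(clean, q_map, a_map, mu = 0, n_frames, seed,
                               clip = TRUE, frames = seq_len(n_frames)) {
  if (length(q_map) == 1L) q_map <- matrix(q_map, nrow(clean), ncol(clean))
  if (length(a_map) == 1L) a_map <- matrix(a_map, nrow(clean), ncol(clean))
  if (!all(dim(q_map) == dim(clean)) || !all(dim(a_map) == dim(clean)))
    stop("q_map/a_map shape mismatch with clean frame")
  if (any(q_map < 0 | q_map > 1)) stop("q_map must lie in [0, 1]")
  if (any(a_map < 0)) stop("a_map must be >= 0")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  npx <- length(clean)
  out <- array(0, dim = c(dim(clean), length(frames)))
  for (i in seq_along(frames)) {
    set.seed(frame_seed(seed, frames[i]))
    events <- stats::runif(npx) < q_map
    noise <- matrix(0, nrow(clean), ncol(clean))
    ne <- sum(events)
    if (ne > 0) noise[events] <- stats::rnorm(ne, mu, a_map[events])
    f <- clean + noise
    if (clip) f <- pmin(pmax(f, 0), 255)
    out[, , i] <- f
  }
  out
}

#' Derive a per-frame RNG substream seed by counter
#' @keywords internal
frame_seed <- function(seed, k) {
  (as.integer(seed) + 9973L * as.integer(k)) %% .Machine$integer.max
}
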