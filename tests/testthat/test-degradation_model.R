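test_that("radial distance map implements the beam-center offset", {
  d <- radial_distance_map(c(64, 64), c(0, 0))
  expect_equal(d[32, 32], sqrt(0.5^2 + 0.5^2))
  # pixel at the geometric center + Xc has distance 0
  d2 <- radial_distance_map(c(65, 65), c(3, -2))
  expect_equal(d2[33 - 2, 33 + 3], 0)
  # Xc = 0: 180-degree rotational symmetry
  expect_equal(d, d[64:1, 64:1])
  # random pixels match the definition with the shifted beam center
  set.seed(11)
  Xc <- c(5.5, -7.25)
  dmap <- radial_distance_map(c(48, 40), Xc)
  for (rep in 1:20) {
    x <- sample(0:47, 1); y <- sample(0:39, 1)
    beam <- c((48 - 1) / 2 + Xc[1], (40 - 1) / 2 + Xc[2])
    expect_equal(dmap[y + 1, x + 1], sqrt(sum((c(x, y) - beam)^2)))
  }
})

test_that("spatial factor evaluates the radial modification function", {
  expect_equal(spatial_factor(0, 108, 0.36), 0.36)
  expect_equal(spatial_factor(1e6, 108, 0.36), 1.36, tolerance = 1e-12)
  expect_equal(spatial_factor(108, 108, 0.5), 0.5 + 1 - exp(-0.5))
  expect_error(spatial_factor(10, 0, 0.3), "positive")
})

test_that("scale_map sends raw extremes to the target range and preserves order", {
  set.seed(4)
  raw <- matrix(runif(100, 2, 9), 10, 10)
  out <- scale_map(raw, 0.36, 0.92)
  expect_equal(min(out), 0.36)
  expect_equal(max(out), 0.92)
  o <- order(raw)
  expect_true(all(diff(out[o]) >= 0))
  # constant raw map -> all base
  expect_true(all(scale_map(matrix(5, 4, 4), 1.9, 16) == 1.9))
  # idempotence: rescaling an already-scaled map with the same bounds
  expect_equal(scale_map(out, 0.36, 0.92), out, tolerance = 1e-12)
  expect_error(scale_map(raw, 2, 1), "Max >= B")
})

test_that("noise maps hit their documented bounds on a full-range input", {
  clean <- matrix(rep(seq(0, 255, length.out = 256), each = 256), 256, 256)
  params <- degradation_params(Bp = 0.36, Ba = 1.9, sigma_d = 108,
                               Xc = c(0, 0))
  maps <- build_noise_maps(clean, params)
  expect_equal(max(maps$np_map), 0.92)
  expect_equal(max(maps$na_map), 16)
  expect_equal(min(maps$np_map), 0.36)
  expect_equal(min(maps$na_map), 1.9)
  # elementwise reference composition of the factor operations
  curves <- default_content_curves()
  d <- radial_distance_map(c(256, 256), c(0, 0))
  raw_p <- matrix(content_factor(as.numeric(clean), curves, "prob"),
                  256, 256) * spatial_factor(d, 108, 0.36)
  ref_np <- 0.36 + (raw_p - min(raw_p)) / (max(raw_p) - min(raw_p)) *
    (0.92 - 0.36)
  expect_equal(maps$np_map, ref_np, tolerance = 1e-12)
  # monotone radial trend for a constant-intensity input with Xc = 0
  flat <- matrix(128, 64, 64)
  mf <- build_noise_maps(flat, degradation_params(Xc = c(0, 0)))
  dm <- radial_distance_map(c(64, 64), c(0, 0))
  o <- order(dm)
  expect_true(all(diff(mf$np_map[o]) >= -1e-12))
})

test_that("content factor doubles amplitude and matches a Horner oracle", {
  curves <- default_content_curves()
  v <- runif(50, 0, 255)
  horner <- function(coef, u) {
    acc <- 0
    for (k in rev(seq_along(coef))) acc <- acc * u + coef[k]
    acc
  }
  up <- (v - 127.5) / 127.5
  expect_equal(content_factor(v, curves, "prob"),
               pmax(0, horner(curves$prob_poly$coef, up)))
  expect_equal(content_factor(v, curves, "amp"),
               2 * pmax(0, horner(curves$amp_poly$coef, up)))
  zero <- content_curves(intensity_poly(rep(0, 11)),
                         intensity_poly(rep(0, 11)))
  expect_true(all(content_factor(v, zero, "amp") == 0))
  expect_error(content_factor(300, curves, "prob"), "\\[0, 255\\]")
})

test_that("randomized parameter draws stay in their documented ranges", {
  n <- 2000
  draws <- lapply(seq_len(n), function(k) sample_degradation_params(k))
  sig <- vapply(draws, `[[`, numeric(1), "sigma_d")
  bp <- vapply(draws, `[[`, numeric(1), "Bp")
  ba <- vapply(draws, `[[`, numeric(1), "Ba")
  xcx <- vapply(draws, function(d) d$Xc[1], numeric(1))
  xcy <- vapply(draws, function(d) d$Xc[2], numeric(1))
  expect_true(all(sig >= 103 & sig <= 113))
  expect_true(all(bp >= 0.35 & bp <= 0.37))
  expect_true(all(ba >= 1.8 & ba <= 2.0))
  # CLT: component means of Xc near 0 within 3 SE (SD = 30)
  expect_lt(abs(mean(xcx)), 3 * 30 / sqrt(n))
  expect_lt(abs(mean(xcy)), 3 * 30 / sqrt(n))
  expect_identical(sample_degradation_params(77), sample_degradation_params(77))
})

test_that("degradation respects its mask, bounds and determinism contracts", {
  set.seed(8)
  clean <- matrix(runif(32 * 32, 30, 220), 32, 32)
  params <- degradation_params(seed = 21)
  # zero probability everywhere -> output identical to input
  zero_curves <- content_curves(intensity_poly(rep(0, 11)),
                                intensity_poly(c(1, rep(0, 10))))
  p0 <- degradation_params(Bp = 0, Pmax = 0.92, seed = 3)
  m0 <- list(np_map = matrix(0, 32, 32), na_map = matrix(2, 32, 32))
  expect_equal(degrade(clean, p0, maps = m0), round(clean))
  # output range and 8-bit quantization
  out <- degrade(clean, params)
  expect_true(all(out >= 0 & out <= 255))
  expect_true(all(out == round(out)))
  # determinism under the seed
  expect_identical(degrade(clean, params), degrade(clean, params))
  expect_false(identical(degrade(clean, params),
                         degrade(clean, degradation_params(seed = 22))))
  # with diffusion off, pixels outside the event mask are untouched
  maps <- build_noise_maps(clean, params)
  outd <- degrade(clean, params, maps = maps, diffusion = FALSE,
                  clip = FALSE, quantize = FALSE)
  set.seed(params$seed)
  R <- matrix(runif(length(clean)), 32, 32)
  M <- R < maps$np_map
  expect_equal(outd[!M], clean[!M])
  expect_true(any(outd[M] != clean[M]))
})

test_that("independent seeds give independent event masks", {
  # constant event probability so the pooled pixel pairs are exchangeable
  # (a shared spatially varying Np would itself induce marginal association)
  clean <- matrix(128, 100, 100)
  params1 <- degradation_params(seed = 101)
  params2 <- degradation_params(seed = 202)
  maps <- list(np_map = matrix(0.4, 100, 100), na_map = matrix(2, 100, 100))
  mask_of <- function(p) {
    set.seed(p$seed)
    matrix(runif(length(clean)), 100, 100) < maps$np_map
  }
  m1 <- mask_of(params1); m2 <- mask_of(params2)
  tab <- table(m1, m2)
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("sparse noise statistics match the Bernoulli-Gaussian closed forms", {
  # flat input, diffusion off, mu = 0: P(|x| > tau) = Np * 2(1 - Phi(tau/Na))
  clean <- matrix(128, 24, 24)
  params <- degradation_params(Bp = 0.4, Pmax = 0.4, Ba = 5, Mmax = 5,
                               seed = 1)  # constant maps
  maps <- list(np_map = matrix(0.4, 24, 24), na_map = matrix(5, 24, 24))
  N <- 1500
  devs <- matrix(0, length(clean), N)
  for (k in seq_len(N)) {
    pk <- params; pk$seed <- k
    devs[, k] <- as.numeric(degrade(clean, pk, maps = maps,
                                    diffusion = FALSE, clip = FALSE,
                                    quantize = FALSE)) - 128
  }
  p_hat <- rowMeans(abs(devs) > 2)
  a_hat <- rowMeans(abs(devs))
  p_true <- 0.4 * 2 * (1 - pnorm(2 / 5))
  a_true <- 0.4 * 5 * sqrt(2 / pi)
  se_p <- sqrt(p_true * (1 - p_true) / N)
  se_a <- sqrt((0.4 * 25 - a_true^2) / N)
  expect_lt(abs(mean(p_hat) - p_true), 3 * se_p / sqrt(length(clean)))
  expect_lt(abs(mean(a_hat) - a_true), 3 * se_a / sqrt(length(clean)))
})

test_that("paired dataset generation writes a complete, in-range manifest", {
  tmp_in <- tempfile(); tmp_out <- tempfile()
  dir.create(tmp_in)
  set.seed(9)
  for (k in 1:3)
    png::writePNG(matrix(runif(32 * 32), 32, 32),
                  file.path(tmp_in, sprintf("clean_%d.png", k)))
  man <- build_paired_dataset(tmp_in, variants_per_image = 4,
                              master_seed = 5, out_dir = tmp_out)
  expect_equal(nrow(man), 12L)
  expect_true(all(file.exists(man$degraded_path)))
  expect_true(all(man$sigma_d >= 103 & man$sigma_d <= 113))
  expect_true(all(man$Bp >= 0.35 & man$Bp <= 0.37))
  expect_true(all(man$Ba >= 1.8 & man$Ba <= 2.0))
  # reproducibility: same master seed -> byte-identical outputs
  tmp_out2 <- tempfile()
  man2 <- build_paired_dataset(tmp_in, 4, 5, tmp_out2)
  f1 <- png::readPNG(man$degraded_path[5])
  f2 <- png::readPNG(man2$degraded_path[5])
  expect_identical(f1, f2)
})
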