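# fluorotrack

Marker-less lung-tumor tracking on kV fluoroscopy needs two hard-to-get
ingredients: realistic noisy training images (clinical frames cannot be
annotated at scale, clean DRRs look nothing like them), and a trustworthy
trajectory-evaluation chain (centroids, smoothing, grading, stereo 3D
errors). `fluorotrack` provides the non-neural core of such a workflow for
medical-physics and image-analysis researchers:

* **Empirical noise characterization** of an imaging chain from repeated
  frames of a static phantom: per-pixel noise probability
  `P_N(x,y) = (1/N) Σ 1[|I_k − I_avg| > τ]` (default τ = 2) and amplitude
  `A_N(x,y) = (1/N) Σ |I_k − I_avg|`, intensity–noise curves, degree-10
  polynomial content fits, beam-center estimation, and a radial
  grid-search calibration of the spatial parameters.
* **A stochastic degradation model** for DRRs. Per-pixel event probability
  and noise scale are

  `Np(V,d) = scale(Pmax, Bp, f_vp(V)·f_sp(d))`,
  `Na(V,d) = scale(Mmax, Ba, f_va(V)·f_sa(d))`,

  with `f_s(d) = B + 1 − exp(−d²/(2σ_d²))` the radial factor about the
  (offset) beam center and `f_v` the fitted content polynomials. A draw
  places sparse Gaussian noise at Bernoulli(`Np`)-masked pixels, diffuses
  it with a σ = 2 px Gaussian, adds fresh secondary noise at the same
  pixels, and clips to 8-bit — all reproducible from one seed, with
  per-image parameter resampling (`Xc ~ N(0, 30 px)`, `σ_d ~ U(103,113)`,
  `Bp ~ U(0.35,0.37)`, `Ba ~ U(1.8,2.0)`) for dataset diversity.
* **Projection geometry**: cone-beam DRR rendering (Beer–Lambert with
  `μ = μ_water(1 + HU/1000)`), 7-voxel threshold projection of tumor label
  volumes by exact voxel traversal, 10×10 elliptical morphological label
  cleanup, 5 mm / 3000 HU fiducial-marker dilation, circular standard-
  background masks, and point projection / stereo triangulation.
* **Trajectory analysis**: mask-centroid extraction (Eq.
  `x_t = (1/|Ω_t|) Σ i`), zero-phase 4th-order Butterworth smoothing
  (fc = 8 Hz, fs = 30 Hz), FFT amplitude spectra, mean-position alignment,
  per-axis RMSE with final error `E = max(RMSE_x, RMSE_y)` graded
  Excellent (< 3 px) / High (3–8) / Moderate (8–13) / Low (≥ 13), and 3D
  error statistics (per-axis mean ± SD, median and IQR of Euclidean
  errors).
* **Synthetic phantoms**: gelatin blocks with aluminum inserts,
  an ellipsoidal-tumor thorax with fiducials, harmonic respiratory motion
  (20 breaths/min fundamental ≈ 0.33 Hz plus harmonics), seeded noise
  injection, and full stereo sequence rendering with exact ground truth.

See `vignettes/fluorotrack-methods.Rmd` for the model details, parameter
meanings, numerical choices and limitations.

## Worked example

Render a degraded stereo sequence of a breathing thorax phantom, track the
tumor from its projected labels, and score against the exact ground truth:

```r
library(fluorotrack)

ph    <- make_thorax_phantom(c(0, 0, 0), c(8, 10, 8), list(c(15, 10, -5)),
                             voxel_spacing = c(1, 1, 1), extent_mm = 60)
geoms <- stereo_geometry(image_size = c(96L, 96L), pixel_pitch = 0.8)
mo    <- motion_model(rate_bpm = 20, amplitude_mm = c(2, 8, 4))
sq    <- render_sequence(ph$volume, ph$mask, ph$markers, mo, geoms,
                         degradation = sample_degradation_params(1),
                         n_frames = 90, fs = 30)

tr_a <- align_to_reference(extract_trajectory(sq$labels_a, fs = 30), sq$gt2d_a)
tr_b <- align_to_reference(extract_trajectory(sq$labels_b, fs = 30), sq$gt2d_b)
rmse_grade(tr_a, sq$gt2d_a)
#> <grade_report> RMSE x 0.078 px, y 0.107 px; E = 0.107 px -> Excellent

spec <- filter_spec(fc = 8, fs = 30, order = 4)
t3 <- trajectory_3d(lowpass(tr_a, spec), lowpass(tr_b, spec),
                    geoms[[1]], geoms[[2]])
for (cl in c("X_mm", "Y_mm", "Z_mm"))
  t3[[cl]] <- t3[[cl]] - mean(t3[[cl]]) + mean(sq$gt3d[[cl]])
st <- error_stats_3d(t3, sq$gt3d)
st$axis
#>      axis       mean         sd
#> X_mm   LR 0.02831669 0.02150329
#> Y_mm   SI 0.02242742 0.02383657
#> Z_mm   AP 0.02910024 0.01829458
st$median_mm
#> [1] 0.05630556
```

The grade is Excellent (sub-pixel 2D RMSE), and the mean-aligned 3D track
reproduces the generating motion to a median Euclidean error of 0.056 mm —
the geometric limit of the 96 px / 1 mm-voxel configuration, showing the
projection, label and triangulation chain is unbiased. The trajectory
spectrum peaks at 0.33 Hz, the 20 breaths/min fundamental.

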