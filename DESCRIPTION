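Package: fluorotrack
Title: Fluoroscopic Noise Modeling and Marker-Less Tumor-Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the non-neural core of a marker-less lung-tumor tracking
    workflow for kV fluoroscopy-guided radiotherapy: empirical characterization
    of signal- and spatially-dependent fluoroscopic noise from static-phantom
    frame stacks; a stochastic, content- and beam-geometry-aware degradation
    simulator that turns clean digitally reconstructed radiographs (DRRs) into
    realistic fluoroscopy-like images; cone-beam DRR rendering, threshold label
    projection, fiducial-marker dilation and stereo point triangulation; and a
    trajectory pipeline with zero-phase Butterworth smoothing, FFT spectra,
    mean-position alignment, RMSE grading and 3D error statistics. Synthetic
    gelatin-block and thorax phantoms with harmonic respiratory motion make the
    whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    RNifti,
    signal,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
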