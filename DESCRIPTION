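Package: gevipipe
Title: Analysis and Simulation of GEVI-Imaged Cortical Oscillations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing spontaneous oscillations recorded with
    genetically encoded voltage indicators (GEVIs) in widefield
    epifluorescence movies of brain slices. The pipeline converts raw
    fluorescence count movies into per-pixel fractional fluorescence
    (%dF/F0) waveforms (dark-pixel masking, zero-phase Butterworth
    bandpass, exponential photobleaching baseline normalisation), builds
    a representative oscillation waveform by correlation-guided pixel
    averaging, and extracts oscillation features: 3-sigma bounds and
    duration, cycle counts, short-segment dominant-frequency tracks,
    power spectral density and peak timing. It scores anomalies against
    the recording's own baseline with a k = 1 nearest-neighbour sliding
    window detector on 4x4-pixel group waveforms, quantifies amplitude
    symmetry between inversely correlated pixel groups, maps per-pixel
    oscillation initiation times and tests their spatial clustering with
    the Hopkins statistic, and compares pixel substrates across
    oscillations. A synthetic-data module generates ground-truth
    membrane-voltage fields, passes them through bi-exponential GEVI
    kinetic transfer functions (ArcLight, Bongwoori-Pos6, Bongwoori-R3
    presets), and renders realistic movies with photobleaching, masked
    out-of-slice pixels and Gaussian/shot noise, so every stage is
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    signal,
    tiff,
    png,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
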