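Package: hgmap
Title: Source-Level High-Gamma EEG Mapping with Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Non-invasive mapping of high-gamma (70-100 Hz) cortical activity
    from multichannel EEG. Implements a linearly constrained minimum variance
    (LCMV) beamformer over complex Morlet wavelet coefficients, baseline
    Z-scoring of trial-averaged source amplitudes, a maximum-statistic
    permutation test based on baseline/signal segment swapping, spectral
    artifact-trial rejection and EMG/EOG envelope monitoring, and an
    EEG-fMRI cluster proximity statistic with surface resampling
    significance. Includes a synthetic-session generator (analytic dipole
    leadfields on a sphere-like cortical mesh, 1/f noise, narrowband
    high-gamma bursts, beta desynchronization, broadband artifacts and
    matched fMRI vertex maps) so the full pipeline is testable against
    known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
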