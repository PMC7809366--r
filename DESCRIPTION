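Package: massrhythm
Title: Ultradian Rhythm Detection in Single-Cell Dry Mass from Lens-Free Holography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis chain for detecting short-period (ultradian)
    rhythms in the dry mass of single adherent cells imaged by lens-free inline
    holographic microscopy. Provides a ground-truthed synthetic-data generator
    (dry-mass trajectories with pulse trains, 1/f noise and division events,
    plus optical cell phantoms rendered into intensity holograms by Fresnel
    propagation), total-variation regularized phase retrieval by nonlinear
    conjugate gradients, blob detection and track linking with gap closing,
    phase to optical-path-difference to dry-mass conversion, and cohort-level
    Fourier statistics: per-cell sine-windowed spectra on heterogeneous-length
    interphase traces, bin-averaged cohort spectra with power-law background
    rejection, fundamental-peak detection, and inverse-Fourier waveform
    reconstruction. The central entry point is rhythm_fit(), which returns a
    classed model object with the usual print, summary, coef, plot, predict
    and simulate methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, yaml, tiff
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
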