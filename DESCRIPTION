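Package: stroboMRE
Title: Real-Time Multifrequency MR Elastography Reconstruction and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for time-resolved multifrequency magnetic resonance
    elastography (MRE) with stroboscopically sampled vibrations. Provides a
    synthetic acquisition simulator (viscoelastic phantom with a slow
    physiological modulation of the complex shear modulus, finite-difference
    Helmholtz wavefields, fractional motion encoding into wrapped phase,
    complex Gaussian image noise), the reconstruction chain (complex-image
    Gaussian smoothing, least-squares gradient phase unwrapping,
    aliased-frequency Gaussian bandpass decomposition with analytic-signal
    demodulation), time-resolved multifrequency dual elasto-visco (MDEV)
    inversion into stiffness and loss-angle map series, and region-of-interest
    time-course analysis (phase-interval statistics, overshoot peak and delay
    detection, coefficient of variation, SNR and wavelet-based wave-SNR
    diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
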