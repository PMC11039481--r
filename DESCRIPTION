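Package: neonv1
Title: Illusory Drifting Grating Stimuli and V1 Spiking Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Renders achromatic neon-color-spreading (NCS) stimuli and their
    controls (diffusion-blocked, luminance-defined grating), simulates
    extracellular recording sessions with known ground truth, and analyses
    spike trains from mouse primary visual cortex: PSTH construction,
    Poisson-deviation response latency detection, direction and size tuning,
    F0/F1 Fourier decomposition, illusory-grating response indices, circular
    phase statistics, receptive-field Gaussian fitting and inducer overlap,
    trough-to-peak waveform classification, current-source-density analysis,
    running-speed extraction and pupillometry dilation indices.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
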