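Package: poiscan
Title: Random-Access Two-Photon Point-of-Interest Scan Planning and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Plans and simulates random-access two-photon imaging of single
    neurons with acousto-optic deflector (AOD) beam steering and a piezo
    Z-actuator. Reads or generates neuron morphologies (SWC), interpolates
    points of interest (POIs) along the dendritic arbor, converts image
    coordinates to AOD frequency-sweep instructions, plans a monotone piezo
    Z-trajectory under velocity and acceleration limits, and schedules
    synchronized start pulses for full-arbor, planar, segmented and raster
    scan modes. A digital twin executes schedules against simulated piezo
    dynamics, Gaussian excitation optics and fluorescent-indicator
    physiology, and the analysis layer turns raw line-scan samples into
    dF/F0 traces, transient kinetics, FFT bandwidth estimates,
    matched-filter event detections and evoked-response maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
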