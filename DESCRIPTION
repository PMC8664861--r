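Package: duovolt
Title: Simulation and Analysis of Dual-Channel Voltage and Calcium Imaging
Version: 0.1.0
Authors@R: person("Pipeline", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for simultaneous two-photon voltage (genetically encoded
    voltage indicator) and calcium imaging of cortical populations: a
    biophysically motivated synthetic-data generator (Boltzmann
    fluorescence-voltage transfer, two-exponential indicator kinetics,
    photobleaching, spike-number-dependent calcium transients, heartbeat and
    flash artifacts, focal-seizure dynamics with a propagating ictal
    wavefront), movie preprocessing (stimulus-artifact frame replacement,
    rigid registration, temporal Kalman stack filtering), trace statistics
    (detrending, dF/F, SNR, stimulus-triggered averages), indicator
    calibration fits, dual-channel spiking/subthreshold event
    discrimination, and seizure-propagation statistics (onset delays,
    recruitment order, windowed LFP-optical correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
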