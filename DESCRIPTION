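Package: cbgtloop
Title: Closed-Loop Deep Brain Stimulation in a Cortex-Basal Ganglia-Thalamus
    Network Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A simulation testbed for closed-loop deep brain stimulation (DBS)
    of the internal globus pallidus (GPi). A conductance-based network model of
    the cortex-basal ganglia-thalamus circuit with a scalar parkinsonism
    variable serves as the plant; beta-band (13-30 Hz) power of the simulated
    GPi local field potential, estimated with a sliding-window multitaper
    spectrum, is the feedback biomarker; and proportional, proportional-
    integral, and adaptive supervisory controllers (a fixed-gain feedback
    controller combined with an on-line trained radial basis function network)
    modulate the DBS pulse repetition frequency to drive beta power to a
    target level. Includes firing-rate and spike-synchrony characterization,
    stimulation-frequency sweeps, and robustness scenarios with time-varying
    disease state and time-varying reference.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
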