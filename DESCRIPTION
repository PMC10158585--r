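Package: swingcycle
Title: Event-Related Electrocortical Analysis of Cyclic Motor Tasks from
    Mobile Dual-Layer EEG
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing event-related electrocortical dynamics
    recorded during continuous, cyclic motor behaviour (for example table
    tennis) with mobile dual-layer EEG.  The package covers the full chain
    from motion-sensor hit-event detection, through artifact suppression by
    sliding-window canonical correlation against dedicated noise and muscle
    reference channels, independent-component decomposition and k-means
    clustering of component source locations, aperiodic/periodic power
    spectrum parameterisation, Morlet time-frequency decomposition with
    linear time warping to a canonical swing cycle, event-related spectral
    perturbation, intertrial phase coherence, event-related potentials and
    inter-cluster coherence, to bootstrap and cluster-based permutation
    statistics.  A fully parameterised synthetic-study generator emulates
    the recording structure (scalp/noise/muscle layers, inertial sensors,
    machine- and human-fed ball conditions) so that every stage of the
    pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    cluster,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
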