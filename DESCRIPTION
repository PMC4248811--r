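Package: ribbonflux
Title: Clathrin and Synaptic Vesicle Dynamics at Ribbon Synapses from
    FCS, FRAP and TIRF Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of presynaptic clathrin and synaptic
    vesicle dynamics from live-cell fluorescence microscopy. Implements
    auto- and cross-correlation of intensity traces with 3D diffusion
    model fitting (fluorescence correlation spectroscopy, FCS, and its
    dual-colour cross-correlation variant, FCCS, including bound-fraction
    estimation with spectral crosstalk correction), normalisation and
    single-exponential fitting of fluorescence recovery after
    photobleaching (FRAP) traces, segmentation and classification of
    stimulus-evoked accumulation and loss events in total internal
    reflection fluorescence (TIRF) movies, event-to-ribbon distance
    geometry, and single/double-exponential decay kinetics with condition
    comparisons. A Brownian-dynamics photon-trace simulator, a FRAP curve
    generator and a TIRF movie generator provide synthetic data with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
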