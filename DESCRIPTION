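Package: cineStrain
Title: Global Myocardial Strain from Cine Cardiac Images by Border Length
    and Feature Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies global and segmental myocardial Lagrangian strain
    from cine cardiac image sequences. Implements endocardial border
    delineation (EBD) strain from sparse manual border points densified by
    monotone cubic Hermite interpolation, a feature-tracking (FT) engine
    combining normalised cross-correlation template matching with
    border-normal edge refinement and spatial smoothing, Bland-Altman and
    coefficient-of-variability agreement statistics, a synthetic deforming
    cardiac phantom generator with analytic ground truth, and an analytic
    model of the out-of-plane circumferential-strain bias caused by
    systolic longitudinal displacement through a fixed imaging plane.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tiff,
    jsonlite,
    yaml,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
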