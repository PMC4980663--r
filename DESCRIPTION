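Package: kcOCT
Title: Corneal Layer Thickness Profiles and Keratoconus Screening Indices
    from UHR-OCT B-Scans
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building refraction-corrected vertical thickness
    profiles of the corneal epithelium, Bowman's layer and stroma from
    ultra-high-resolution optical coherence tomography (UHR-OCT) B-scans,
    and for screening sub-clinical keratoconus from them. Provides
    gradient-cost shortest-path segmentation of the four corneal
    interfaces, Snell ray-tracing refraction correction, zonal averaging
    and Bowman's-layer-edge co-registration of central, superior and
    inferior scans into one vertical meridian profile, the twelve
    ectasia/variation/pattern-deviation diagnostic indices, Wilks-lambda
    stepwise linear discriminant analysis and empirical ROC evaluation.
    A synthetic-cornea module generates ground-truth layered geometry,
    rendered B-scans and whole cohorts with realistic group structure so
    every stage of the pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    png,
    MASS
Suggests:
    testthat (>= 3.0.0),
    pROC,
    multcomp,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
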