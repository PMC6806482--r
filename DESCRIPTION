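Package: protonqa
Title: Proton Pencil-Beam-Scanning Dose Engines and Gamma-Index Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale toolkit for validating proton pencil-beam-scanning
    (PBS) dose calculations against planar detector measurements. Provides
    synthetic voxel phantoms with discrete bone/air heterogeneities, an
    analytical pencil-beam (APB) dose engine built on the infinite-slab
    approximation, a condensed-history Class II proton Monte Carlo engine
    with per-voxel statistical-uncertainty tracking, a virtual
    ionization-chamber-array detector with OPG-style ASCII input/output,
    2D/3D global gamma-index analysis with a depth-of-best-agreement
    search, and a validation pipeline that assembles the full
    measured-versus-computed comparison into tabular reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
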