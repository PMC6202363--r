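Package: mpconcord
Title: Structure-Function Concordance Mapping on a Microperimetry Grid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the topographical agreement between
    functional loss measured by microperimetry and structural lesion extent
    delineated on indocyanine green angiography (ICGA) and spectral-domain
    optical coherence tomography (SD-OCT), developed for polypoidal
    choroidal vasculopathy. Implements an age- and eccentricity-referenced
    normative model with Total and Pattern Deviation probability maps on a
    56-location stimulus grid, projection of lesion boundary polygons onto
    the grid through per-location coverage regions, intersection-over-union
    concordance and relative-complement statistics, structure-function
    association regressions, and a synthetic cohort generator that emulates
    the statistical structure of such data for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
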