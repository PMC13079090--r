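Package: borealForcing
Title: Component and Net Climate Radiative Forcing of Boreal Forest Fires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the 70-year, per-unit-burned-area net climate radiative
    forcing of boreal forest fires from five components: direct greenhouse-gas
    and precursor emissions from combustion, aerosol emissions (direct and
    indirect), post-fire surface-albedo change via monthly radiative kernels,
    vegetation recovery (net ecosystem exchange of CO2), and greenhouse-gas
    emissions from fire-induced permafrost thaw. Includes a synthetic-landscape
    generator with known ground truth, space-for-time chronosequence modelling
    of post-fire albedo and NEE recovery, a first-order permafrost
    active-layer-thickening emission model, warming/cooling classification and
    comparative landscape analyses, and Monte-Carlo, bootstrap and scenario
    uncertainty machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
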