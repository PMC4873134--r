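Package: lurevp
Title: Vapour Pressure and Attractiveness of Raspberry Ketone Fruit-Fly Lures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links the physicochemical volatility of raspberry-ketone-analog
    fruit-fly lures to their behavioural attractiveness. Implements Antoine
    vapour-pressure evaluation, inversion and nonlinear least-squares fitting
    from isothermal boiling data, Clausius-Clapeyron derivation of the
    enthalpy of vaporisation, boiling-onset extraction from differential
    scanning calorimetry heat-flow traces, threshold-based fly counting in
    cage-bioassay images with per-fly-area calibration and rank-concordance
    validation, constrained exponential fitting of lure response kinetics,
    and a structure-clustered analysis of covariance of maximum response on
    vapour pressure. Ships synthetic-data generators with known ground truth
    for every pipeline input, plus the published Antoine parameter sets for
    cuelure, melolure, raspberry ketone and six analogs as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    png,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff
Config/testthat/edition: 3
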