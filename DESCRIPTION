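Package: pinedisc
Title: Leaf-Level Carbon Isotope Discrimination and Water-Use Efficiency
    for Scots Pine
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates photosynthetic 13C discrimination and intrinsic
    water-use efficiency (iWUE) of conifer shoots from chamber gas-exchange
    measurements and from delta13C of leaf carbon pools. Implements
    exponential closure-curve flux fitting for non-airtight shoot chambers,
    the steady-state Farquhar discrimination model with mesophyll,
    photorespiratory and mitochondrial respiration terms, inversion of
    carbon-pool delta13C to iWUE with a pinitol correction for
    water-soluble carbohydrates, carry-over (previous-day weighting)
    analysis of leaf-pool delta13C series, and a synthetic-season generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
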