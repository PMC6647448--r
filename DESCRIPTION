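Package: osteocrack
Title: Crack Propagation Around Osteons in Cortical Bone Microstructure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates quasi-static crack propagation in two-dimensional
    cortical bone microstructural models (one osteon bounded by a cement line
    inside an interstitial matrix) with a plane-stress finite element core and
    cohesive crack tracking. Damage initiation in bulk phases follows the
    maximum principal strain (MAXPE) criterion; the cement line additionally
    uses the quadratic nominal strain interface criterion (QUADE), so cracks
    can either penetrate osteons or deflect along the cement line. Includes
    the full sensitivity-analysis machinery of the accompanying parameter
    study: resolution IV fractional factorial screening over 14 material
    parameters, Box-Behnken response surfaces over 7 parameters,
    percent-of-total-sum-of-squares ANOVA, crack trajectory scoring (1-5),
    and toughness/interface-strength region mapping, plus synthetic surrogate
    responses and crack-path fixtures so every statistical stage is testable
    without finite element runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
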