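Package: exoflux
Title: Condition-Specific Metabolic Models from Extracellular Metabolomic
    Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds condition-specific constraint-based metabolic models from
    quantitative extracellular metabolomic (exometabolomic) profiles. Measured
    uptake and secretion rates are screened for qualitative feasibility,
    applied as flux bounds with a configurable allowance, and completed by an
    exchange-cardinality minimization (one-norm relaxation) that predicts the
    minimal set of unmeasured metabolite exchanges required for a feasible
    steady state. Includes a flux-balance-analysis kernel (FBA, parsimonious
    FBA, flux variability analysis, hit-and-run flux sampling), blocked
    reaction pruning, metabolite-centric flux-split and ATP-yield phenotyping,
    phenotypic phase plane scans, oxygen-dependence (oxotype) classification,
    gene and reaction essentiality screens, and deterministic toy-network
    generators with analytically known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    quadprog,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
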