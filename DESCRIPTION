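Package: cosmpn
Title: Two-Step Most Probable Number Enumeration of Carbonyl Sulfide
    Degrading Microorganisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for enumerating chemoorganotrophic carbonyl sulfide (COS)
    degrading microorganisms from two-step serial-dilution assays. The first
    step scores chemoorganotrophic growth by turbidity; the second step scores
    biological COS degradation of each grown culture against the chemical
    hydrolysis background using a degradation-ratio threshold. The package
    provides tube-level positivity calling over repeated measurement days,
    maximum-likelihood most probable number (MPN) estimation with
    Cochran-style confidence intervals and conversion to cells per gram dry
    sample, first-order COS decay kinetics (rate constants, a pH-dependent
    chemical hydrolysis baseline, biomass-carbon calibration and the
    biomass-normalized specific rate constant SRCB), log-log power-law
    correlation of MPN densities with degradation rate constants, and a
    synthetic-data generator that emulates Poisson inoculation, growth
    trajectories and gas chromatography measurement noise so every pipeline
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
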