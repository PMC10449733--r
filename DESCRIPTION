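Package: theranopk
Title: Semi-Physiological Population Pharmacokinetics and Dosimetry for a
    Theranostic Somatostatin-Receptor Peptide Pair
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Six-compartment receptor-saturable (maximal binding capacity)
    population pharmacokinetic modelling for a matched diagnostic/therapeutic
    somatostatin-receptor radiopeptide pair. Provides deterministic forward
    simulation with lognormal inter-individual variability and covariate
    effects (tumor sink, tumor-volume power), virtual-patient cohort
    generation with proportional residual error, MAP (posthoc) Bayesian
    estimation of individual random effects from sparse imaging-derived
    concentrations, Laplace-approximate population estimation of
    therapeutic-to-diagnostic fold differences, translation of diagnostic
    individual estimates into therapeutic predictions, MIRD-style
    time-integrated activity and absorbed-dose calculation, and
    relative-prediction-error evaluation of individual versus population
    predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
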