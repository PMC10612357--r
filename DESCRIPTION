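Package: kinstab
Title: Stability and Kinetics Profiling of Kinase Missense Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of the biophysical and biochemical
    characterization of protein kinase missense variants. Converts raw
    spectroscopic signals (circular dichroism, intrinsic fluorescence) to
    standard observables, counts independent spectral components by singular
    value decomposition, fits guanidinium-chloride equilibrium unfolding
    curves to two-state (linear extrapolation) and three-state intermediate
    models with optional shared-m global fitting, extracts apparent melting
    temperatures from the first derivative of thermal scans, reduces
    fluorogenic kinase assay progress curves to Michaelis-Menten and
    Arrhenius parameters, and assembles a per-variant comparison ledger
    (stability deltas, catalytic-efficiency ratios) against the wild type.
    A seeded synthetic-data generator emulates every input so the whole
    pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    deSolve,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
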