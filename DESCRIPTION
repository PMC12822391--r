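Package: bprisk
Title: Binding, Thermal Shift, and Integrated Risk Analysis of Bisphenol Analogs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis chain for receptor-binding and risk screening
    of bisphenol analogs: Stern-Volmer fluorescence-quenching and binding-
    constant estimation from titration spectra, two-point van't Hoff binding
    thermodynamics with noncovalent force classification, cellular thermal
    shift assay (CETSA) melt-curve fitting with Tm50 and delta-Tm50, validation
    and ranking of docking, MM/GBSA and circular-dichroism secondary-structure
    tables, a differentially-expressed-gene intersection biomarker screen, and
    ToxPi-style weighted-slice risk integration and ranking. Includes seeded
    synthetic-data generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
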