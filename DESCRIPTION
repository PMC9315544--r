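Package: pbpktbr
Title: Mechanistic Steady-State PBPK Prediction of PET Tissue-to-Blood Ratios
    for EGFR TKI Tracers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form, steady-state physiologically based pharmacokinetic
    (PBPK) tissue-partitioning models for three generations of EGFR tyrosine
    kinase inhibitor PET tracers (erlotinib, afatinib, osimertinib) in
    non-small-cell lung cancer patients. Implements weak-base and strong-base
    unbound tissue-to-plasma partition (Kpu) models extended with EGFR target
    binding, lysosomal sequestration (pH trapping plus lysosomal-membrane
    binding) and NSCLC tumor-microenvironment hallmarks (immune deprivation,
    acidic extracellular water, vascularization vs. perfusion coefficients).
    Provides tissue-to-blood ratio (TBR) and tumor-to-lung contrast
    predictions, component decompositions, a component-ablation sensitivity
    suite, and validation statistics (prediction error, Pearson correlation,
    fold accuracy, Bland-Altman export) against PET-image-derived TBR data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
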