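Package: dvhbio
Title: Radiobiological Evaluation of Radiotherapy Plans from Dose-Volume Histograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for radiobiological evaluation of external-beam radiotherapy
    plans at the dose-volume-histogram (DVH) level. Provides DVH containers with
    cumulative/differential conversion and dose-volume metrics (D95, mean, max,
    min, volume-at-dose), linear-quadratic EQD2 fractionation correction,
    Poisson linear-quadratic tumor control probability (TCP),
    Lyman-Kutcher-Burman (LKB) and relative-seriality normal tissue complication
    probability (NTCP) with generalized equivalent uniform dose, a normal-tissue
    constraint checker for lung SBRT criteria, paired plan comparison with
    cohort-level nonparametric statistics, and a seeded synthetic generator of
    paired plan cohorts for end-to-end testing. Bundles published TCP and NTCP
    model parameter sets for NSCLC lung SBRT evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
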