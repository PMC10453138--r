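Package: ddPurity
Title: Purity Screening and Adulterant Quantification for Single-Ingredient
    Herbs by Droplet Digital PCR and DNA Metabarcoding
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative DNA authentication of nominally single-species
    botanical ingredients such as dried oregano. Implements droplet calling
    for one-dimensional droplet digital PCR (ddPCR) fluorescence amplitudes,
    Poisson absolute copy quantification with Wilson confidence intervals,
    the "DNA accounting" purity screen that compares measured target copies
    against the copy number expected from a sample's fluorometric DNA mass,
    ploidy- and target-copy-corrected copy-percentage estimation of
    non-declared species, decision-rule classification of metabarcoding
    read tables (kingdom filtering, read percentages, adulterant /
    contaminant / noise classes with ddPCR confirmation flags), and
    per-species concordance analysis between sequencing read percentages
    and ddPCR copy percentages. A seeded synthetic-data generator emulates
    Poisson droplet partitioning, replicate fluorometry noise, and biased,
    misattributed read tables so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    rlang,
    yaml,
    withr,
    ggplot2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
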