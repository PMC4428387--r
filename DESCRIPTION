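Package: pascore
Title: Pathway Activation Strength Scoring and Cross-Platform Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores signaling-pathway activation from case/control gene
    expression profiles. For each case sample and pathway the pathway
    activation strength (PAS) is the sum, over member genes, of the gene's
    activator/repressor role weight times a significance flag times the
    decimal log of its case-to-normal expression ratio. Includes quantile
    normalization of expression matrices, a cross-platform concordance
    analysis comparing gene-level log-ratio correlation with pathway-level
    PAS correlation between two platforms profiling the same samples, and a
    seeded two-platform simulator with pathway-structured perturbations,
    gene-specific platform bias, measurement noise and dropout.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    limma,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
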