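Package: pyrosig
Title: Pyroptosis Signature Scoring and Subtype-Intersection Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying pyroptosis-related transcriptional programs in
    breast cancer: a subtype-level differential-expression screen (one-way ANOVA with
    Benjamini-Hochberg correction and Tukey post hoc contrasts, effect-size
    thresholding, and a five-subtype intersection that defines a subtype-independent
    signature), the Pyroptosis Index and Inflammasome Activation Score, relative qPCR
    quantification by the 2^-ddCt method, confidence tiering of predicted miRNA-mRNA
    target pairs, post-cryoablation longitudinal kinetics (peak detection,
    return-to-baseline, paired significance), and summary metrics of protein-protein
    interaction graphs. Ships the study's printed tables as plain-text fixtures and a
    seeded synthetic-cohort generator so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
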