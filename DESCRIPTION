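Package: rcccpred
Title: Sequence-Based Prediction of Renal Clear Cell Carcinoma Driver Genes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds labeled benchmarks of mutated gene sequences from a
    reference FASTA plus a single-nucleotide mutation catalog, extracts a
    six-value feature vector per sequence via two layers of statistical
    moments (raw, central, and discrete orthogonal Hahn moments followed by
    summary moments), trains three-class classifiers (renal clear cell
    carcinoma driver vs. other tumor driver vs. non-driver/unknown), and
    evaluates them under self-consistency, stratified k-fold cross-validation,
    jackknife (leave-one-out), and independent-split protocols with
    one-vs-rest metrics and ROC curves. Includes a synthetic-data generator
    so the full pipeline is testable without external downloads, and a
    command-line interface wiring the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
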