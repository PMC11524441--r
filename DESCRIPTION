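Package: oasig
Title: Transcriptomic Signature Comparison for Joint Injury Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Comparison layer for post-traumatic osteoarthritis (PTOA)
    transcriptomics: cosine-similarity search of log2 fold-change profiles
    against a compendium with z-score standardisation and ranking,
    directional Fisher exact enrichment of curated osteoarthritis
    effect annotations (Protective vs Detrimental) and of predicted
    miRNA target sets among differentially expressed genes, cross-model
    concordance statistics (Spearman rank correlation and discordant-sign
    fraction), small-sample assay computations (qPCR relative expression,
    dual-luciferase normalisation, unpaired t-tests), and seeded
    synthetic-data generators that emulate the statistical structure of
    the study inputs so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
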