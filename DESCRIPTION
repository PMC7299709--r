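Package: progenitorness
Title: Progenitorness Scoring and Pan-Cancer Evaluation of an Ancient
    Essential Gene Signature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a per-sample "progenitorness" score -- a single-sample
    gene-set enrichment statistic of a curated set of evolutionarily ancient
    essential genes -- from bulk, single-cell or proteome expression matrices,
    and evaluates it the way a pan-cancer biomarker study would: tumour/normal
    diagnosis (Wilcoxon rank-sum, ROC/AUROC), prognosis (Cox proportional
    hazards, Kaplan-Meier with log-rank), tumour grading (pairwise rank-sum
    trends), treatment monitoring (paired signed-rank) and drug-sensitivity
    correlation screening (Spearman with Benjamini-Hochberg FDR). Includes
    seeded synthetic-cohort generators emulating each study design so the
    full pipeline runs end-to-end with no external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
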