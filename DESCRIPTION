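Package: cernascreen
Title: Competing Endogenous RNA Screening with Survival, Enrichment and
    Immune-Association Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens bulk tumor/normal expression data for long non-coding
    RNAs that act as microRNA sponges co-regulating a pair of target mRNAs
    (competing endogenous RNA triplets). Provides log2(CPM+1) normalization,
    a moderated-t differential-expression screen, Spearman
    ligand-correlation filtering, prediction-source intersection, triplet
    assembly and hub ranking, Kaplan-Meier/log-rank/Cox survival screening,
    preranked gene-set enrichment with permutation significance, geometric
    mean signature scoring, immune cell-fraction association tests, and
    relative qPCR quantification. A calibrated synthetic-data generator with
    planted ground truth supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    igraph,
    jsonlite
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
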