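Package: sexconcord
Title: Cross-Species Sex-Differential Expression Concordance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for asking whether sex differences in gene expression
    observed in a mouse tumour model are recapitulated in human data.
    Implements a self-contained differential-expression stage (TMM-style
    normalization, log-CPM, moderated t statistics, Benjamini-Hochberg FDR,
    fold-change selection), a cross-species sign-concordance statistic
    calibrated against a resampling null of random gene sets with a
    fitted-normal tail probability, hypergeometric gene-set
    over-representation on GMT collections, and single-hit Poisson
    limiting-dilution (ELDA-style) clonogenic frequency estimation with
    likelihood-ratio group comparison. A negative-binomial simulator with
    planted sex effects and a controlled cross-species concordance rate
    provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    fgsea,
    jsonlite,
    stats,
    utils
Suggests:
    edgeR,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
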