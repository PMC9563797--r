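Package: cridumeth
Title: Paired Differential Methylation and 5p Deletion Analysis for Cri du Chat Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Blood DNA-methylation analysis for paired patient/control cohorts
    with segmental chromosome deletions, modelled on Cri du chat (5p-) syndrome.
    Implements probe filtering and beta/M conversion for Illumina-style
    intensity tables, empirical-Bayes moderated paired t-statistics,
    deletion-breakpoint calling from loess-smoothed total-intensity log-ratios,
    a preranked weighted-KS gene-set enrichment engine applied at two levels
    (CpG-to-promoter, promoter-score-to-category) with leading-edge extraction
    and region-exclusion reruns, direction-split hypergeometric CpG-category
    over-representation, bivalent-promoter scoring, linear epigenetic clocks,
    reference-based cell deconvolution, PCA quality control, and a fully
    specified synthetic paired-cohort generator with planted deletions and
    gene-set effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    jsonlite,
    withr
Config/testthat/edition: 3
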