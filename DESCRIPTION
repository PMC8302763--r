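Package: tgctrisk
Title: Post-GWAS Risk-Locus Analysis for Testicular Germ Cell Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis stages that follow a multi-study
    case-control genome scan of testicular germ cell tumors (TGCT):
    genotype and sample quality control, per-study additive logistic
    association, fixed-effects inverse-variance meta-analysis with
    heterogeneity control, credible-risk-variant sets from linkage
    disequilibrium against a reference panel, approximate conditional
    and joint (COJO-style) analysis for independent signals, per-SNP
    heritability explained relative to familial relative risk, polygenic
    risk scores with percentile-bin odds ratios and lifetime-risk
    scaling, and a multi-evidence variant-to-gene adjudication score.
    A synthetic-cohort module generates LD-structured genotype panels,
    case-control studies under an additive logistic disease model, and
    per-gene functional-evidence tables with known ground truth, so the
    whole pipeline is testable without access to consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
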