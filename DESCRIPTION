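Package: pexquant
Title: Quantification and Modelling of Poison-Exon Inclusion in Sodium Channel Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify inclusion of a "poison" cassette exon (an
    alternatively spliced exon whose inclusion causes a frameshift, a
    premature termination codon, and nonsense-mediated decay of the
    transcript) from bulk RNA-seq coverage and from quantitative RT-PCR, and
    to interpret the measurements under an additive two-allele steady-state
    model of splicing and decay. Includes a coverage-ratio percent-usage
    statistic computed from per-base depth, delta-Ct and amplicon-ratio
    inclusion estimators with undetectable-Ct handling, allele-level
    inference (per-allele baselines, knock-in fold increase, steady-state
    parameter fitting, predicted total-mRNA reduction), developmental
    time-course and cohort statistics (Mann-Kendall trend, Spearman
    permutation tests, Mendelian goodness of fit, Kaplan-Meier and log-rank),
    and a fully seeded synthetic-data generator covering transcript pools,
    read coverage with optional 3'-bias, Ct tables, developmental
    trajectories, and survival cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    GenomicRanges,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    DESeq2,
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
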