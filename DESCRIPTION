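Package: icbstrat
Title: Immunogenomic Stratification of Immune Checkpoint Therapy Cohorts by 9p21.3 Status
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking somatic 9p21.3 copy-number loss (homozygous
    deletion of CDKN2A/MTAP) to cold tumor-immune phenotypes and resistance
    to immune checkpoint therapy (ICT). Provides gene-level copy-call
    genotyping and expression-based surrogates (hi_hi/lo_lo median splits),
    marker-gene immune abundance scores and single-sample gene-set
    enrichment (ssGSEA), TCR repertoire diversity, Wilcoxon/BH differential
    screens, exact contingency statistics for response rates, a composite
    TMB/9p21/PD-L1 response score, Kaplan-Meier/Cox survival stratification,
    and a synthetic-cohort generator with a ground-truth ledger for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
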