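Package: fsevade
Title: Frameshift-Driven Immune Evasion Analysis for Microsatellite-Unstable Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing recurrent JAK1 frameshift mutations in
    microsatellite-instable (MSI-H) tumors and their transcriptional
    consequences. Provides hotspot detection at homopolymer tracts,
    mutant-allele-fraction based zygosity and clonality classification,
    cohort association statistics (Fisher exact, Mann-Whitney, binomial
    standard errors, tumor mutational burden), expression normalization
    (FPKM to TPM, log2, row z-scores), a from-scratch preranked gene-set
    enrichment engine with gene-label permutation FWER control, a per-sample
    interferon-response signature score, and a seeded synthetic-cohort
    generator so the full pipeline is testable without access to controlled
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    optparse
Config/testthat/edition: 3
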