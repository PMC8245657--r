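Package: neoprofiler
Title: Neoantigen Profiling from Tumor/Normal Allele Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for tumor neoantigen profiling from paired
    tumor/normal sequencing evidence. Calls somatic variants from per-site
    allele counts with a Fisher's exact test and six depth/frequency filters,
    classifies mutations into six classes (nsSNV, sSNV, stop gain, stop loss,
    splicing, INDEL), enumerates all 8-11mer mutant peptides harbouring each
    substituted amino acid, filters them by HLA class I binding affinity
    (IC50 < 500 nM) and RNA read-count support to obtain a per-patient
    neoantigen load, and computes cohort statistics (FPKM, Pearson
    correlations, subtype comparisons) and T-cell assay summaries (ELISpot
    positivity, calcein-release cytotoxicity). Includes a seeded synthetic
    cohort generator with ground truth and a deterministic matrix-based
    binding model so the whole pipeline is testable without external data
    or predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
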