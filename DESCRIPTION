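Package: metaomix
Title: Integrated Multi-Omics Analysis of Microbiome Amplicon, Metagenomics,
    Metatranscriptomics and Metaproteomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular toolkit for the bespoke computational stages of
    integrated multi-omics microbiome studies. Builds metaproteomics protein
    search databases from amplicon-derived taxonomic profiles (top-n taxon
    selection, proteome collection, exact redundancy removal, host inclusion),
    assigns peptide-level taxonomy by lowest common ancestor against the
    constructed database after in-silico tryptic digestion, fits per-feature
    linear models for differential abundance with phenotype and covariates
    (total-sum scaling, log or centered log-ratio transforms,
    Benjamini-Hochberg correction), integrates omics layers at pathway level
    via fold-change-normalized log2 ratios assembled into split-node tables,
    and performs joint multi-block ordination of two or more omics layers.
    Deterministic synthetic-data generators with planted effects make every
    stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
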