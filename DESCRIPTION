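Package: nterminomics
Title: Analysis of Protein N-Terminome Enrichment Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for N-terminomics (degradomics) studies of protease
    activity using negative-selection enrichment with two-channel isotopic
    dimethyl quantification. Provides an in silico protease digestion engine
    with LysN and ArgC-like specificities and per-method identifiability
    analysis of ORF and neo-N-terminal peptides; readers for PSM tables
    (a documented TSV dialect and pepXML); classification of peptides as
    ORF, neo-N-terminal or internal; median-centred ratio normalization and
    peak-area aggregation; staged winnowing of candidate caspase-3 cleavage
    sites and of posttranslationally acetylated neo-N-termini; cleavage-site
    sequence-context statistics (differential amino-acid-usage logo matrices,
    nearest-basic-residue distance distributions, structural context
    summaries); and a fully seeded synthetic-data generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
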