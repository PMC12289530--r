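Package: sorfpipe
Title: Proteogenomic Discovery, Classification and Quantification of
    sORF-Encoded Microproteins
Version: 0.1.0
Authors@R:
    person("sorfpipe", "developers", email = "sorfpipe@example.org",
           role = c("aut", "cre"))
Description: A desk-scale proteogenomic pipeline for microprotein discovery
    from transcript sequences and peptide-level mass-spectrometry tables.
    Enumerates small open reading frames (sORFs) by three-frame translation,
    builds and merges searchable protein databases, separates novel
    microprotein peptides from canonical proteins with a two-stage
    substring-plus-alignment filter, assigns each sORF one of seven
    genomic-context categories, scores experimental fragment spectra against
    theoretical b/y-ion spectra, and performs rule-based protein
    quantification, differential expression with Benjamini-Hochberg
    adjustment, nascent-protein labeling and candidate selection. A seeded
    synthetic-data generator produces every input the pipeline consumes
    together with a ground-truth table for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
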