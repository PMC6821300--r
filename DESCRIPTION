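Package: retinet
Title: Introgression and Positive-Selection Screens for Multi-Species
    Transcriptome Ortholog Sets
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative-transcriptomics toolkit for detecting ancient
    hybridization and adaptive protein evolution across a clade.
    Builds conserved ortholog clusters from per-species CDS sets by
    reciprocal best hits, extracts outgroup-polarized biallelic sites,
    and computes Patterson's D statistic in two estimator forms
    (per-cluster ABBA/BABA site counts, and derived-allele frequencies
    in genomic windows) with leave-one-out jackknife standard errors
    and two-tailed z tests. Screens clusters for positive selection
    with pairwise Nei-Gojobori (NG86) Ka/Ks, enumerates branch-site
    test plans over a fixed species topology, and applies
    Benjamini-Hochberg FDR control. A seeded synthetic-data generator
    with known introgression proportion and per-locus omega produces
    every pipeline input, so the whole analysis is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
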