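Package: phylosieve
Title: Dissecting Phylogenomic Signal in Protein Supermatrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and stress-testing phylogenomic protein
    supermatrices. Provides constraint-based screening of single-gene
    alignments, concatenation with partition and coverage bookkeeping, a
    self-contained maximum-likelihood engine for reversible amino-acid
    models with discrete-gamma rate heterogeneity (LG, WAG, Poisson),
    fast-evolving-site-removal and random-gene-sampling support curves,
    taxon-deletion experiments for diagnosing long-branch attraction, and
    per-gene and per-site log-likelihood comparisons between competing
    topologies. Includes a simulator for gene-partitioned alignments with
    rate heterogeneity, long-branch geometries, chimeric (dual-history)
    genes, and per-gene taxon missingness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
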