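Package: minpanel
Title: Minimal SNP Marker Panels for Fingerprinting Clonal Germplasm
    Collections
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for curating KASP-style biallelic SNP genotypes of
    clonally propagated germplasm collections and for selecting minimal
    marker panels that discriminate all distinguishable accessions.
    Provides a SummarizedExperiment-based container for genotype call
    matrices; fail-rate statistics and sample-retention filtering; a
    greedy pairwise-discrimination panel selector with an exhaustive
    reference search; grouping of identical SNP profiles, replicate-aware
    merging, systematic null-allele detection, cross-platform concordance
    with strand harmonization, and heterozygosity screening; replicate-based
    genotyping error-rate estimation under contrasting assumptions about
    label fidelity; shared-call similarity clustering with marker-bootstrap
    support and newick export; and a synthetic-collection simulator with
    known truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
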