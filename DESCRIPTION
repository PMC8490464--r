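Package: AneuDosage
Title: Dosage-Effect Analysis of Aneuploid Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of gene-dosage effects in aneuploid
    RNA-seq data. Provides a negative-binomial count simulator for
    Drosophila-like aneuploid karyotypes (trisomy 2L, metafemale) with known
    cis dosage (3/2), trans inverse-dosage (2/3) and MSL2 trans-repression
    structure; CPM normalization, empirical-Bayes batch adjustment and
    replicate averaging; ratio-distribution analysis against theoretical
    dosage-effect expectations with Kolmogorov-Smirnov comparison;
    LOWESS-smoothed chromosome fold-change profiles; negative-binomial Wald
    differential expression with BH correction, sex-bias classification,
    overlap enrichment and PPI shortest-path filtering; and signed weighted
    coexpression network analysis with topological overlap, module detection
    and module eigengenes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), methods, SummarizedExperiment
Imports: stats, utils, graphics, S4Vectors, igraph, yaml
Suggests: testthat (>= 3.0.0), sva, DESeq2, jsonlite, optparse
biocViews: Software, Transcriptomics, DifferentialExpression, Network
Config/testthat/edition: 3
RoxygenNote: 7.3.3
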