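Package: degnet
Title: Differential Expression and Seeded Interaction-Network Analysis for Case-Control Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of case-control bulk transcriptomes of the
    kind produced for small iPSC-derived neuronal cohorts: median-of-ratios
    normalization, negative-binomial conditional exact tests with
    Benjamini-Hochberg false discovery control, locus-group accounting of
    differentially expressed genes, Euclidean-distance hierarchical clustering
    and two-component PCA, construction of the protein-interaction subnetwork
    seeded by differentially expressed genes with a random-seed null ensemble
    and Kolmogorov-Smirnov topology comparison, Fisher/Bonferroni gene-set
    over-representation, and relative qPCR quantification by the 2^(-ddCt)
    method. Includes synthetic-data generators with the statistical structure
    the analysis assumes, so the whole chain is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    ape
Config/testthat/edition: 3
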