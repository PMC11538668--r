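Package: zonatlas
Title: Liver Lobule Zonation Analysis for Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the portal-central (PN-CV) axis of the liver lobule
    from 10x Visium-style spot-level expression data and classifies per-gene
    zonation patterns under different nutritional states. Provides a Space
    Ranger bundle reader/writer, per-spot QC and graph-based clustering with
    erythroid-cluster flagging, diffusion-map pseudotime oriented by landmark
    genes, nonlinear model fitting (quadratic polynomial, Gaussian peak,
    inverted Gaussian trough) with a normalized-range zonation statistic and a
    five-way pattern classification (periportal, pericentral, midzonal,
    bipolar, non-zonated), pattern-transition tables across conditions,
    Wilcoxon rank-sum differential expression with Benjamini-Hochberg FDR,
    per-spot single-sample gene-set enrichment (ssGSEA) scores, and a
    lobule-structured synthetic data generator with ground truth for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    minpack.lm,
    methods,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
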