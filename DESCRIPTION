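Package: lncscope
Title: Tumor Versus Normal Profiling of Coding and Long Non-Coding RNA
    Expression
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Differential-expression screening, lncRNA-mRNA correlation
    networks, genomic-distance classification of lncRNA/neighbor gene
    pairs (overlap, adjoining, proximal, others), and interaction-energy
    filtered trans-target prediction for small tumor-versus-control bulk
    RNA-seq cohorts quantified as FPKM. Includes a seeded synthetic-cohort
    generator with planted differential effects, cis-coupled gene pairs,
    trans correlation blocks and interaction-score tables, so the whole
    pipeline is testable without any data download, plus an orchestrated
    end-to-end pipeline with a reproducible JSON run report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    graphics,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    optparse
biocViews: Transcriptomics, GeneExpression, DifferentialExpression,
    Network, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
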