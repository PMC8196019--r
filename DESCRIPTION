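Package: qmpbench
Title: Benchmarking Microbiome Count Transformations Against Quantitative
    Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation-first benchmark of thirteen microbiome count
    transformations. Generates ground-truth absolute-abundance communities
    from Gaussian-copula multivariate negative binomials under three
    ecological scenarios (taxon blooming, ecological succession, low-load
    dysbiosis), simulates metagenomic sequencing at log-normal library
    sizes, flow-cytometry-like microbial load measurement, and metadata
    with designed taxon and load associations. Implements relative (Rel,
    RMP, AST), compositional (CLR, CSS, UQ, TMM, RLE, GMPR, VST) and
    quantitative (QMP, ACS) transformations of read-count matrices, alpha
    diversity with per-method applicability rules, and association-recovery
    scoring (precision, sensitivity, false positive rate, discordance)
    against the simulated ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    DESeq2,
    vegan,
    biomformat,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
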