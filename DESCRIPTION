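Package: pedscan
Title: Pedigree-Based Selection Simulation and Evolve-and-Resequence Scan
Version: 0.1.0
Authors@R:
    person("pedscan", "developers", email = "pedscan@example.org", role = c("aut", "cre"))
Description: Forward simulation of artificial selection experiments down a
    pedigree under an infinitesimal model with linkage, using a junction
    (ancestry-block) representation of genomes, together with the analysis
    machinery of an evolve-and-resequence study: allele-frequency shift
    scans on the variance-stabilized scale (delta-z-squared), simulation
    derived genome-wide significance thresholds, hitchhiking-aware sweep
    peak calling, parallelism statistics between replicate lines, and
    Wright-Fisher likelihood inference of selection coefficients from
    allele-frequency time series.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    BiocGenerics,
    SummarizedExperiment,
    VariantAnnotation
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
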