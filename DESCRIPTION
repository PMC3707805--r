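Package: clinekit
Title: Spatial Analysis of Fine-Scale Genomic Clines from SNP Genotypes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and orienting geographic gradients (clines) in
    genome-wide SNP genotype data sampled from many closely spaced sites, at the
    micro-geographic scale of a single country. Implements the full analysis
    chain: genotype input (VCF, PLINK PED/MAP, TSV), per-subpopulation quality
    control (Tukey IBS outlier and relatedness screening, missingness, exact
    Hardy-Weinberg filtering, Kendall tau-b LD pruning), identity-by-state and
    squared-difference distance matrices, normalized identity-by-descent segment
    sharing, classical multidimensional scaling with additive-constant
    correction, Procrustes comparison against geography, Weir-Cockerham Fst,
    AMOVA, spatial autocorrelograms on the individual genetic covariance matrix,
    bearing correlograms that estimate the compass orientation of a cline,
    per-SNP logistic allele-frequency gradient scans with a local Moran's I
    genome scan, a spatially explicit two-wave range-expansion simulator for
    scenario comparison, and a synthetic clinal-data generator with planted
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    vegan,
    mclust,
    geosphere,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: PopulationGenetics, SNP, Genetics, Spatial
Config/testthat/edition: 3
RoxygenNote: 7.3.3
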