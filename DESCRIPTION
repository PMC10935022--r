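Package: snpforge
Title: Design and Validation Pipeline for SNP Genotyping Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the computational stages used to design and validate
    a fixed-content SNP genotyping array from multi-sample resequencing
    variants, exercised end-to-end on a simulated citrus-like cohort.
    Stages include post-calling variant quality control (map/base/genotype
    quality, depth-versus-median, exact binomial allele-balance test,
    biallelic and missingness filters), group-wise polymorphism assignment,
    genic-window and transversion/indel filtering, probe strand-tiling
    decisions from convertibility scores, probe performance classification,
    two-run call-consistency retention, seeded downselection to a target
    array size, genotype call metrics (heterozygosity, concordance, clonal
    identity), population analyses (PCA, neighbor-joining phylogeny with
    bootstrap support, Robinson-Foulds comparison, LD pruning), and a
    genotyping-error robustness simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    vcfR,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
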