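Package: haplogp
Title: Annotation-Aware Haplotype Kernels for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction of quantitative traits from phased genotypes
    using haplotype-block relatedness kernels. Assigns SNPs to genomic classes
    (intergenic, gene, exon, CDS, UTR) from a GFF3 annotation, builds
    haploblocks under a maximum-allele-count rule, encodes them as numerical
    dosage pseudo-markers or categorical genotype configurations, and
    constructs the corresponding relationship matrices including categorical
    first-order epistasis (Hadamard) kernels. Variance components are
    estimated by single-kernel spectral REML and direct genomic values are
    obtained by BLUP; predictive accuracy and bias are assessed by replicated
    k-fold cross-validation. A founder-mosaic simulator generates phased
    genotypes with distance-decaying linkage disequilibrium, nested gene
    annotation and phenotypes under additive, multi-allelic haplotype, or
    pairwise-epistatic architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
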