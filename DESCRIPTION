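Package: haploencoder
Title: Haplotype-Block Autoencoders for Genomic Prediction and Block Effect Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compresses SNP genotype data into one feature per linkage-disequilibrium
    defined haplotype block using a block-masked autoencoder, with a semi-supervised
    extension that estimates haplotype-block-variant effects on a quantitative trait.
    Includes LD-based haplotype block construction from flanking-marker r-squared,
    VanRaden method I genomic relationship matrices, GBLUP for inbred lines and
    GCA/SCA mixed models for hybrids with Kronecker-structured SCA covariance,
    REML variance components, GBLUP-to-marker-effect back-transformation,
    block-wise marker effect sums, Mantel tests between relationship matrices,
    repeated and leave-parents-out (T0) cross-validation, and a synthetic data
    generator with planted haplotype-block structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vegan,
    vcfR
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
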