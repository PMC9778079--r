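Package: xtrd
Title: Transmission Ratio Distortion on Sex Chromosomes from Genotyped Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects transmission ratio distortion (TRD) on the X chromosome
    from sire-dam-offspring genotyped trios. Classifies markers as
    pseudoautosomal or heterosomal from Mendelian-inconsistency patterns under
    the two inheritance models, extracts parent- and offspring-sex-specific
    allele transmissions, and estimates allelic TRD (and genotypic
    additive/dominance TRD for recessive patterns) in a Bayesian framework
    with Savage-Dickey Bayes factors and empirical-null calibration. Includes
    deterministic trio phasing, sliding-window biallelic haplotype scans with
    kernel-smoothing consolidation, a forward simulator of sex-chromosome trio
    genotypes with configurable distortion and pseudoautosomal recombination,
    and descriptive profiles of sire-TRD decay and linkage disequilibrium.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
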