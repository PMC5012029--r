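Package: morphherit
Title: Mendelian Model Testing and Heritability of Colour Morphs in Breeding Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the inheritance of discrete colour morphs and
    quantitative colour expression in two-generation breeding pedigrees of
    polymorphic animals. Implements candidate Mendelian architectures for a
    four-morph throat-colour polymorphism (one locus with four alleles; one
    locus with three co-dominant alleles; two autosomal di-allelic loci),
    computes expected offspring morph frequencies under alternative parental
    zygosity assumptions, and tests fit with likelihood-ratio G tests,
    including ZW sex-linkage exclusion logic. Quantitative colour expression
    (proportions of orange and yellow throat coverage, arcsine-square-root
    transformed) is analysed with a pedigree-based REML animal model,
    parent-offspring regressions and cross-correlations, and an ANCOVA test
    for sex-linked inheritance. A pedigree simulator with Mendelian genotype
    transmission and additive-genetic trait variation supports validation,
    and a microsatellite mismatch rule provides paternity exclusion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
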