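Package: fertsel
Title: Pedigree-Based Fertility Association and Selection-Signature Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying quantitative fertility variation in large
    inbred pedigrees and the population-genetic footprint of the alleles
    involved. Implements pedigree validation, recursive kinship and
    inbreeding coefficients, Mendelian gene-drop simulation, construction of
    a birth-rate phenotype from reproductive histories, relatedness-corrected
    (generalized least squares) association tests with polygenic variance
    components, Kaplan-Meier and log-rank comparison of time to a given
    birth, rule-based haplotype phasing by Mendelian transmission, pairwise
    linkage disequilibrium (D'), Weir-Cockerham Fst, extended haplotype
    homozygosity (EHH) and the integrated haplotype score (iHS), together
    with synthetic data generators that emulate a consanguineous founder
    population with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
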