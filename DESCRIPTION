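Package: polySI
Title: S-Haplotype Segregation and Self-(In)compatibility Analysis for
    Polyploid Prunus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models gamete formation at the S-locus of tetraploid cherry
    under tetrasomic or fixed disomic inheritance, including double
    reduction and hetero-diploid pollen.  Applies gametophytic
    self-incompatibility rules (competitive interaction between two
    functional pollen S-haplotypes, pollen-part mutant haplotypes) to
    derive expected progeny S-phenotype class distributions, computes
    allele marginals from dosage-blind genotyping counts, and tests
    observed progeny count tables against theoretical or fitted
    segregation ratios with Pearson chi-squared goodness-of-fit
    statistics.  Includes a multinomial progeny simulator for power and
    calibration studies, an exhaustive small-integer ratio search, and a
    TSV/YAML interface for count tables and study configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
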