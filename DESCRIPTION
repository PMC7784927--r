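Package: tetragp
Title: Genomic Prediction Optimization for Autotetraploid Breeding Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing genomic prediction in autotetraploid crops
    genotyped by targeted capture sequencing. Implements G-BLUP on continuous
    ratio genotypes (per-marker alternative-allele read fractions), read-count
    filtering, Poisson downsampling of sequencing depth, structured resampling
    designs for marker density, probe density and training-population size and
    composition, a Gibbs sampler with a closed-form BLUP oracle, Tukey HSD
    compact letter displays, and a synthetic breeding-population generator
    (tetrasomic meiosis, additive traits, capture-seq style read counts) so the
    whole factorial analysis runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    emmeans,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
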