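Package: crossherd
Title: Simulation and Genomic Analysis of Additive and Dominance Effects
    in Crossbred Beef-Cow Herds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying cow weight and cumulative weight weaned in
    multibreed beef herds. Simulates crossbred herds (breed allele-frequency
    divergence, pedigrees with breed composition, gene-dropped linked
    genotypes, longitudinal breeding/weaning event data), builds trait
    records with opportunity-group fixed effects, constructs additive and
    dominance genomic relationship matrices, fits random-regression mixed
    models by restricted maximum likelihood with average-information
    acceleration, back-solves per-variant additive and dominance effects
    with permutation-based significance, computes pedigree and genomic
    heterosis indicators (retained heterozygosity, genomic heterozygosity
    and inbreeding, runs of homozygosity, heterozygosity-rich regions),
    and intersects significant variants with QTL interval tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
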