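Package: recmapr
Title: Mapping Recessive Disease Loci in Founder Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localizing recessive Mendelian disease loci in inbred
    founder populations from SNP-array and targeted sequencing data: genotype
    quality control (minor-allele-frequency and call-rate filters), genotypic
    2x3 chi-square association scans with Bonferroni correction and an exact
    (probability-ordering) alternative, shared runs-of-homozygosity mapping
    across affected individuals, a rule-based pileup variant caller with
    recessive case-control concordance filtering and coding-sequence
    consequence annotation, two-locus linkage-disequilibrium r-squared via
    expectation-maximization, and allele-frequency estimation from carrier
    screens. A seeded founder-population simulator generates SNP genotypes
    segregating a recessive lethal haplotype together with matching read
    pileups, so the whole workflow can be exercised end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
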