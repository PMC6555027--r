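Package: majorref
Title: Major-Allele Reference Genome Construction, Liftover and Call-Set Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an ethnically normalized ("major allele") reference genome by
    replacing every minor allele in a linear assembly with the population major
    allele (alternate allele frequency > 0.5) taken from a population VCF, and
    provides the companion machinery such a reference needs: a coordinate map and
    UCSC chain file for liftover between the original and normalized assemblies,
    migration of genePred gene annotation with spurious-intron collapse, reading
    frame recomputation and translation-based sanity checks, variant
    normalization/decomposition, and call-set comparison with false-positive /
    false-negative accounting. Includes seeded synthetic-data generators so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    jsonlite,
    generics,
    ggplot2,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    IRanges,
    optparse,
    withr
Config/testthat/edition: 3
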