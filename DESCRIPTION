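Package: aluscan
Title: Alignment-Free Discovery and Genotyping of Polymorphic Alu Insertions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free discovery of polymorphic Alu retrotransposon
    insertions from raw short-read sequencing data. Detects insertions absent
    from a reference genome (REF-) by scanning reads for the Alu 5' signature
    sequence, and potentially polymorphic elements present in the reference
    (REF+) by signature, target-site-duplication, homology and outgroup
    criteria. Builds breakpoint-specific bipartite 32-mer pairs, genotypes
    known insertions directly from raw reads with a Poisson allele-count
    caller, applies cohort-level reliability filters (unexpected ploidy,
    Hardy-Weinberg deviation, monomorphic markers), and includes a
    planted-insertion simulator with paired-read generation and a false
    negative decomposition for sensitivity evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
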