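Package: uselectr
Title: Uracil-Selection Simulation and Authentication of Ancient Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for authenticating ancient microbial taxa in metagenomic
    sequencing libraries that were physically partitioned, during
    single-stranded library preparation, into a uracil-enriched and a
    uracil-depleted fraction. Provides a forward simulator of multi-taxon
    ancient DNA mixtures under a position-dependent cytosine-deamination
    model together with the exact analytic oracle for conditional damage
    frequencies in each fraction; position-specific substitution profiles
    with decay-model fitting and fold-amplification statistics; a minimal
    k-mer lowest-common-ancestor read classifier with per-node read-count
    summaries; paired-fraction relative-enrichment statistics that label
    taxa as ancient-like or recent-like; haploid genotyping, biallelic SNP
    ascertainment, SNP identity and principal component analysis for strain
    comparison; and contig classification against two candidate reference
    genomes with reference-coverage and k-mer-coverage summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    minpack.lm,
    graphics,
    stats,
    utils
Suggests:
    Rsamtools,
    yaml,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
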