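Package: baseedit
Title: Quantification and Specificity Profiling of CRISPR Base-Editing Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize cytosine, adenine and dual base editors from
    targeted amplicon deep sequencing and whole-genome/transcriptome variant
    calls. Classifies amplicon reads into editing outcomes (C-to-T, A-to-G,
    simultaneous, C-to-G, other substitutions, indels), builds per-position
    efficiency profiles and ranked allele tables, aggregates profiles across
    target sites to infer the deaminase editing window, enumerates
    PAM-constrained off-target candidate sites under a mismatch budget and
    attributes observed SNVs to them, and profiles per-plant variant sets
    (six-type SNV spectra, allele-frequency zygosity classes, on-target
    genotype matrices, germline-transmittable fractions, and flanking-context
    sequence logos). Ships a fully seeded synthetic-data generator (amplicon
    reads, toy genomes with planted off-target sites, plant variant cohorts
    with known truth) so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
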