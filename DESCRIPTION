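Package: genospec
Title: Genome-Based Delineation of Prokaryotic Species and Subspecies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pairwise whole-genome similarity measures (fragment-based average
    nucleotide identity, tetranucleotide signature correlation, trimmed-HSP
    genome-BLAST distances on the digital DNA:DNA hybridization scale),
    type-strain radius affiliation and threshold-linkage clustering with a
    linkage fraction for delineating prokaryotic genomic species and
    subspecies, marker-gene (16S rRNA, multilocus) identity and
    Kimura-2-parameter statistics, distance dendrograms with replicate-based
    branch support, biogeographic distribution classification, and a
    coalescent-free simulator of genome sets with planted species structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
SystemRequirements: BLAST+ (blastn, makeblastdb) on the PATH for
    fragment-ANI and genome-BLAST distance computation.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
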