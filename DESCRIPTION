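Package: pioneerscan
Title: Chromatin-State Targeting Analysis for Pioneer Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies transcription-factor binding sites and genomic motif
    instances by the chromatin state they engage. Partitions ChIP-seq peaks by
    preexisting DNase accessibility and nucleosome (H2B) turnover, classifies
    heterochromatin targeting into high/moderate/low local-density subtypes
    from H3K9me3/H3K27me3 signal at sites versus flanks, scans genomes with
    position weight matrices, and classifies every motif instance as bound,
    sampled, or unsampled against a shifted-motif background null. Includes
    replicate-consensus and condition-versus-condition peak comparison,
    chromatin-state overlap enrichment, binned motif enrichment across
    accessibility deciles, and a synthetic-genome generator with planted
    ground truth so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
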