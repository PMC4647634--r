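Package: mitotranscriptr
Title: Strand-Specific Transcriptome Profiling of Multichromosomal Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterizing transcription across multichromosomal
    plant mitochondrial genomes from strand-specific RNA-seq alignments.
    Provides per-base strand-aware coverage tracks and sliding-window
    profiles, detection of expressed intergenic regions with
    mitochondrial-versus-total-cellular enrichment classification, a
    six-frame open reading frame expression screen, a candidate small-RNA
    stack caller that separates discrete small RNAs from degradation
    smears, and a pileup-based C-to-U RNA-editing caller with
    canonical/non-canonical typing, annotation-category assignment,
    read-end artifact rechecking, and repeat-aware deduplication. A
    seeded synthetic-data generator plants expressed genes, intergenic
    transcripts, editing sites, small-RNA stacks, and duplicated repeats
    into a toy multichromosomal genome so that every stage can be
    validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    rtracklayer,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
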