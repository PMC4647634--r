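#' Describe the sequencing libraries of a study
#'
#' A library set records, for each sequencing library, its enrichment role
#' (mitochondrial-enriched or total-cellular), biological replicate, assay
#' (mRNA-seq or small-RNA-seq), and the number of mapped reads used as the
#' denominator for CPM/RPKM normalization.
#'
#' @param library_id Character vector of unique library identifiers.
#' @param role `"mito_enriched"` or `"total_cellular"` per library.
#' @param replicate Integer replicate number (1 or 2) per library.
#' @param assay `"mrna"` or `"smallrna"` per library.
#' @param total_mapped_reads Positive integer count of mapped reads per
#'   library; the normalization denominator.
#'
#' @return A tibble with one row per library and the columns above.
#' @examples
#' library_set(
#'   library_id = c("mito1", "mito2", "tc1", "tc2"),
#'   role = c("mito_enriched", "mito_enriched", "total_cellular", "total_cellular"),
#'   replicate = c(1L, 2L, 1L, 2L),
#'   assay = "mrna",
#'   total_mapped_reads = c(14e6, 14.2e6, 1.6e6, 1.9e6)
#' )
#' @export
library_set <- function(library_id, role, replicate, assay, total_mapped_reads) {
  libs <- tibble(
    library_id = as.character(library_id),
    role = role,
    replicate = as.integer(replicate),
    assay = assay,
    total_mapped_reads = as.numeric(total_mapped_reads)
  )
  if (anyDuplicated(libs$library_id)) {
    abort("library ids must be unique")
  }
  if (!all(libs$role %in% c("mito_enriched", "total_cellular"))) {
    abort("role must be 'mito_enriched' or 'total_cellular'")
  }
  if (!all(libs$assay %in% c("mrna", "smallrna"))) {
    abort("assay must be 'mrna' or 'smallrna'")
  }
  key <- paste(libs$role, libs$replicate, libs$assay)
  if (anyDuplicated(key)) {
    abort("(role, replicate, assay) combinations must be unique")
  }
  if (any(!is.finite(libs$total_mapped_reads)) || any(libs$total_mapped_reads <= 0)) {
    abort("total_mapped_reads must be positive for every library")
  }
  libs
}

# total mapped reads for one library id, with a clear error
library_total <- function(libraries, library_id) {
  i <- match(library_id, libraries$library_id)
  if (is.na(i)) {
    abort(paste0("library '", library_id, "' not found in library set"))
  }
  libraries$total_mapped_reads[[i]]
}

#' Reverse-complement a nucleotide string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] for plain character
#' vectors, used wherever minus-strand sequence is reported.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# complement of single bases, vectorized, staying in plain characters
comp_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x])
}

#' Translate a DNA sequence under the standard genetic code
#'
#' Plant mitochondria use the standard (nuclear) genetic code, so
#' translation here is a direct lookup in [Biostrings::GENETIC_CODE].
#' Codons containing N translate to `"X"`.
#'
#' @param x Character vector of DNA sequences with length divisible by 3.
#' @return Character vector of amino-acid sequences (`*` for stops).
#' @export
translate_dna <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) %% 3L != 0L) abort("sequence length must be divisible by 3")
    codons <- substring(s, seq(1L, nchar(s) - 2L, by = 3L), seq(3L, nchar(s), by = 3L))
    aa <- Biostrings::GENETIC_CODE[codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# genome accessors ------------------------------------------------------

# `genome` is a named character vector (chromosome name -> sequence).
genome_lengths <- function(genome) {
  vapply(genome, nchar, integer(1))
}

genome_subseq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    abort(paste0("unknown chromosome '", chrom, "'"))
  }
  substring(genome[[chrom]], start, end)
}

# split a chromosome into a per-position character vector (cached per call site)
genome_chars <- function(genome, chrom) {
  strsplit(genome[[chrom]], "", fixed = TRUE)[[1]]
}

assert_features <- function(features, genome = NULL) {
  needed <- c("feature_id", "chrom", "start", "end", "strand", "type")
  missing <- setdiff(needed, names(features))
  if (length(missing)) {
    abort(paste("feature table lacks columns:", paste(missing, collapse = ", ")))
  }
  if (any(features$start > features$end)) {
    bad <- features$feature_id[features$start > features$end][1]
    abort(paste0("feature '", bad, "' has start > end"))
  }
  if (!is.null(genome)) {
    lens <- genome_lengths(genome)
    unknown <- !(features$chrom %in% names(genome))
    if (any(unknown)) {
      abort(paste0("feature '", features$feature_id[unknown][1],
                   "' lies on unknown chromosome '", features$chrom[unknown][1], "'"))
    }
    oob <- features$end > lens[features$chrom] | features$start < 1L
    if (any(oob)) {
      abort(paste0("feature '", features$feature_id[oob][1],
                   "' has coordinates outside its chromosome"))
    }
  }
  invisible(features)
}

# mean of a depth vector over [start, end] via a precomputed cumsum
cumsum_mean <- function(cs, start, end) {
  (cs[end + 1L] - cs[start]) / (end - start + 1L)
}

# 1-based inclusive -> BED 0-based half-open conversion, isolated here
to_bed <- function(df) {
  tibble(
    chrom = df$chrom,
    start = df$start - 1L,
    end = df$end,
    name = if ("name" %in% names(df)) df$name else ".",
    score = 0L,
    strand = if ("strand" %in% names(df)) df$strand else "."
  )
}

#' Export genomic intervals as a BED file
#'
#' Internally all coordinates are 1-based fully inclusive (GFF convention);
#' this converts to BED's 0-based half-open intervals at the boundary.
#'
#' @param df Data frame with `chrom`, `start`, `end` and optionally
#'   `name`, `strand` columns (1-based inclusive).
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_bed <- function(df, path) {
  bed <- to_bed(df)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(df)
}
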