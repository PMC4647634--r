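#' Load a reference genome and its feature annotation
#'
#' Reads a (possibly multichromosomal) reference genome from FASTA and a
#' feature annotation from GFF3, validates the annotation against the
#' genome, and returns both in the package's internal conventions:
#' coordinates are 1-based and fully inclusive everywhere, strands are
#' `"+"`/`"-"`.
#'
#' @param genome_path Path to a FASTA file.
#' @param annotation_path Path to a GFF3 file. Recognized feature types are
#'   gene, CDS, exon, intron, tRNA, rRNA, pseudogene, repeat,
#'   plastid_insert and nuclear_insert.
#'
#' @return A list with elements `genome` (named character vector,
#'   chromosome name to sequence) and `features` (tibble with columns
#'   `feature_id`, `chrom`, `start`, `end`, `strand`, `type`, `parent`).
#' @export
load_reference <- function(genome_path, annotation_path) {
  if (!file.exists(genome_path)) abort(paste("no such file:", genome_path))
  if (!file.exists(annotation_path)) abort(paste("no such file:", annotation_path))
  seqs <- Biostrings::readDNAStringSet(genome_path)
  genome <- setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  if (anyDuplicated(names(genome))) abort("duplicate chromosome names in FASTA")
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad)) {
    abort(paste0("chromosome '", names(genome)[bad][1],
                 "' contains bases outside A/C/G/T/N"))
  }

  gr <- rtracklayer::import(annotation_path, format = "gff3")
  md <- as.data.frame(GenomicRanges::mcols(gr))
  parent <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  } else {
    rep(NA_character_, length(gr))
  }
  id <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))
  id[is.na(id) | id == ""] <- paste0("feature_", which(is.na(id) | id == ""))
  features <- tibble(
    feature_id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    parent = parent
  )
  features$strand[!features$strand %in% c("+", "-")] <- "+"
  assert_features(features, genome)
  list(genome = genome, features = features)
}

#' Write a genome and feature table back to FASTA and GFF3
#'
#' Inverse of [load_reference()]; loading the written files reproduces the
#' inputs exactly.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param features Feature tibble as returned by [load_reference()].
#' @param genome_path,annotation_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_reference <- function(genome, features, genome_path, annotation_path) {
  seqs <- Biostrings::DNAStringSet(unname(unlist(genome)))
  names(seqs) <- names(genome)
  Biostrings::writeXStringSet(seqs, genome_path)

  assert_features(features, genome)
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand
  )
  GenomicRanges::mcols(gr)$type <- features$type
  GenomicRanges::mcols(gr)$ID <- features$feature_id
  has_parent <- !is.na(features$parent)
  parent <- rep(list(character(0)), nrow(features))
  parent[has_parent] <- as.list(features$parent[has_parent])
  GenomicRanges::mcols(gr)$Parent <- IRanges::CharacterList(parent)
  suppressWarnings(rtracklayer::export(gr, annotation_path, format = "gff3"))
  invisible(c(genome_path, annotation_path))
}

#' Derive implied introns from exon gaps
#'
#' Introns need not be pre-annotated: for each parent feature with two or
#' more exons, the gaps between consecutive exons are returned as intron
#' features on the parent's strand.
#'
#' @param features Feature tibble.
#' @return Tibble of intron features (possibly empty), same columns.
#' @export
derive_introns <- function(features) {
  exons <- features[features$type == "exon" & !is.na(features$parent), , drop = FALSE]
  if (!nrow(exons)) {
    return(features[0, c("feature_id", "chrom", "start", "end", "strand", "type", "parent")])
  }
  exons |>
    group_by(.data$parent) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      istart = list(.data$end[-n()] + 1L),
      iend = list(.data$start[-1] - 1L),
      .groups = "drop"
    ) |>
    tidyr::unnest(c("istart", "iend")) |>
    filter(.data$istart <= .data$iend) |>
    group_by(.data$parent) |>
    mutate(feature_id = paste0(.data$parent, "_intron", row_number())) |>
    ungroup() |>
    mutate(type = "intron", start = .data$istart, end = .data$iend) |>
    select("feature_id", "chrom", "start", "end", "strand", "type", "parent")
}

#' Load strand-aware alignments from SAM or BAM
#'
#' Reads mapped, primary alignment records for one library. Strand is
#' taken from the reverse flag (0x10), the mismatch count from the `NM`
#' edit-distance tag (recorded as `NA` when the tag is absent), and the
#' query sequence is kept in reference orientation as stored.
#'
#' @param path SAM (converted internally) or BAM file.
#' @param library_id Library identifier attached to every record.
#' @param genome Optional named genome vector; when supplied, header
#'   chromosome names and record bounds are validated against it.
#'
#' @return Tibble with columns `read_id`, `library_id`, `chrom`, `start`,
#'   `end`, `read_length`, `strand`, `mismatch_count`, `cigar`, `seq`,
#'   sorted by chromosome then start.
#' @export
load_alignments <- function(path, library_id, genome = NULL) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, destination = dest,
                                             overwrite = TRUE, indexDestination = FALSE))
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!is.null(genome)) {
    lens <- genome_lengths(genome)
    unknown <- setdiff(names(hdr), names(genome))
    if (length(unknown)) {
      abort(paste0("alignment header names chromosome '", unknown[1],
                   "' absent from the reference"))
    }
    if (!all(hdr == lens[names(hdr)])) {
      abort("alignment header chromosome lengths disagree with the reference")
    }
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE),
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = "NM"
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(rec$qname)
  nm <- rec$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, n)
  seqs <- as.character(rec$seq)
  out <- tibble(
    read_id = rec$qname,
    library_id = library_id,
    chrom = as.character(rec$rname),
    start = rec$pos,
    read_length = nchar(seqs),
    strand = ifelse(bitwAnd(rec$flag, 16L) > 0L, "-", "+"),
    mismatch_count = as.integer(nm),
    cigar = rec$cigar,
    seq = seqs
  )
  out$end <- out$start +
    GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar) - 1L
  out <- out[, c("read_id", "library_id", "chrom", "start", "end",
                 "read_length", "strand", "mismatch_count", "cigar", "seq")]
  if (!is.null(genome)) {
    lens <- genome_lengths(genome)
    oob <- out$start < 1L | out$end > lens[out$chrom]
    if (any(oob)) {
      abort(paste0("alignment '", out$read_id[oob][1],
                   "' extends beyond its chromosome"))
    }
  }
  arrange(out, .data$chrom, .data$start)
}
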