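# ORF scan of one sequence (one strand, transcript orientation);
# returns 1-based transcript-orientation coordinates
scan_orfs_one <- function(s, min_length, mode) {
  n <- nchar(s)
  out <- list()
  for (f in 0:2) {
    n_codons <- (n - f) %/% 3L
    if (n_codons < 2L) next
    cs <- seq.int(f + 1L, by = 3L, length.out = n_codons)
    codons <- substring(s, cs, cs + 2L)
    stops <- which(codons %in% STOP_CODONS)
    atgs <- which(codons == "ATG")
    if (!length(stops) || !length(atgs)) next
    prev <- 0L
    for (st in stops) {
      cand <- atgs[atgs > prev & atgs < st]
      if (length(cand)) {
        starts_c <- if (mode == "maximal") cand[1] else cand
        for (a in starts_c) {
          len <- (st - a + 1L) * 3L
          if (len >= min_length) {
            out[[length(out) + 1L]] <- c(cs[a], cs[st] + 2L, f, len)
          }
        }
      }
      prev <- st
    }
  }
  if (!length(out)) {
    return(tibble(t_start = integer(), t_end = integer(), frame = integer(),
                  length = integer()))
  }
  m <- do.call(rbind, out)
  tibble(t_start = m[, 1], t_end = m[, 2], frame = m[, 3], length = m[, 4])
}

#' Find open reading frames in all six frames
#'
#' Scans both strands of every chromosome for ATG-to-stop spans under the
#' standard genetic code (plant mitochondria translate with the standard
#' nuclear code). ORF length includes the stop codon, so the 201-nt
#' minimum corresponds to 66 codons plus the stop. By default only
#' maximal ORFs are reported (first ATG after the previous in-frame
#' stop); `mode = "all_atg"` reports one ORF per internal ATG as well.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param min_length Minimum ORF length in nt (>= 6 and divisible by 3).
#' @param mode `"maximal"` (default) or `"all_atg"`.
#'
#' @return Tibble of class `orf_table`: `orf_id`, `chrom`, `start`,
#'   `end` (1-based inclusive, stop codon included), `strand`, `frame`,
#'   `length`, `protein_length` (aa, stop excluded).
#' @export
find_orfs <- function(genome, min_length = 201L, mode = c("maximal", "all_atg")) {
  mode <- match.arg(mode)
  if (min_length < 6L || min_length %% 3L != 0L) {
    abort("min_length must be >= 6 and divisible by 3")
  }
  out <- list()
  for (ch in names(genome)) {
    s <- genome[[ch]]
    L <- nchar(s)
    fwd <- scan_orfs_one(s, min_length, mode)
    if (nrow(fwd)) {
      fwd <- mutate(fwd, chrom = ch, start = .data$t_start, end = .data$t_end,
                    strand = "+")
      out[[length(out) + 1L]] <- fwd
    }
    rev <- scan_orfs_one(revcomp(s), min_length, mode)
    if (nrow(rev)) {
      rev <- mutate(rev, chrom = ch, start = L - .data$t_end + 1L,
                    end = L - .data$t_start + 1L, strand = "-")
      out[[length(out) + 1L]] <- rev
    }
  }
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), frame = integer(), length = integer())
  orfs <- if (length(out)) bind_rows(out) else empty
  orfs <- orfs |>
    arrange(.data$chrom, .data$start, .data$strand) |>
    mutate(protein_length = .data$length %/% 3L - 1L,
           orf_id = sprintf("orf_%05d", row_number())) |>
    select("orf_id", "chrom", "start", "end", "strand", "frame",
           "length", "protein_length")
  structure(orfs, class = c("orf_table", class(orfs)))
}

#' Keep ORFs remote from any annotated gene
#'
#' Edge-to-edge distance (number of bases strictly between the ORF and
#' the feature; 0 for overlapping or abutting intervals) to the nearest
#' annotated gene, tRNA, rRNA or pseudogene must be strictly greater
#' than `min_distance`.
#'
#' @param orfs `orf_table` tibble.
#' @param features Feature tibble (may be empty: everything is kept).
#' @param min_distance Distance cutoff in nt, default 2000.
#' @return The remote subset, with a `distance_to_gene` column
#'   (`Inf` when no gene shares data with the genome).
#' @export
filter_remote_orfs <- function(orfs, features, min_distance = 2000L) {
  if (min_distance < 0L) abort("min_distance must be >= 0")
  genes <- gene_like(features)
  if (!nrow(genes) || !nrow(orfs)) {
    orfs$distance_to_gene <- rep(Inf, nrow(orfs))
    return(orfs)
  }
  orf_gr <- GenomicRanges::GRanges(orfs$chrom, IRanges::IRanges(orfs$start, orfs$end))
  gene_gr <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$start, genes$end))
  chrom_levels <- union(unique(orfs$chrom), unique(genes$chrom))
  GenomeInfoDb::seqlevels(orf_gr) <- chrom_levels
  GenomeInfoDb::seqlevels(gene_gr) <- chrom_levels
  hits <- GenomicRanges::distanceToNearest(orf_gr, gene_gr, ignore.strand = TRUE)
  d <- rep(Inf, nrow(orfs))
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  orfs$distance_to_gene <- d
  orfs[d > min_distance, , drop = FALSE]
}

#' Rank ORFs by expression and select the top fraction
#'
#' Annotates each ORF with its mean coding-strand read depth and returns
#' the `ceiling(n * top_fraction)` most expressed, flagging those with
#' mean depth strictly above `depth_floor` as high-depth candidates.
#' Ties break deterministically by (depth desc, chrom, start).
#'
#' @param orfs `orf_table` tibble.
#' @param track Coverage track of the library used for ranking.
#' @param top_fraction Fraction in (0, 1] to select, default 0.05.
#' @param depth_floor Depth for the `high_depth` flag, default 100.
#' @return The selected subset with `mean_depth`, `rank` and
#'   `high_depth` columns.
#' @export
rank_orfs_by_depth <- function(orfs, track, top_fraction = 0.05,
                               depth_floor = 100) {
  if (top_fraction <= 0 || top_fraction > 1) abort("top_fraction must be in (0,1]")
  md <- numeric(nrow(orfs))
  for (ch in unique(orfs$chrom)) {
    idx <- which(orfs$chrom == ch)
    for (strd in c("+", "-")) {
      i2 <- idx[orfs$strand[idx] == strd]
      if (!length(i2)) next
      v <- track_strand_depth(track, ch, if (strd == "+") "forward" else "reverse")
      cs <- c(0, cumsum(as.numeric(v)))
      md[i2] <- (cs[orfs$end[i2] + 1L] - cs[orfs$start[i2]]) /
        (orfs$end[i2] - orfs$start[i2] + 1L)
    }
  }
  orfs$mean_depth <- md
  orfs <- arrange(orfs, desc(.data$mean_depth), .data$chrom, .data$start)
  orfs$rank <- seq_len(nrow(orfs))
  n_sel <- ceiling(nrow(orfs) * top_fraction)
  sel <- orfs[seq_len(n_sel), , drop = FALSE]
  sel$high_depth <- sel$mean_depth > depth_floor
  sel
}

#' Extract ORF nucleotide or protein sequences
#'
#' @param orfs `orf_table` tibble.
#' @param genome Named chromosome sequences.
#' @param translate If `TRUE`, return protein sequences (stop trimmed).
#' @return Character vector named by `orf_id`.
#' @export
orf_sequences <- function(orfs, genome, translate = FALSE) {
  s <- vapply(seq_len(nrow(orfs)), function(i) {
    x <- genome_subseq(genome, orfs$chrom[i], orfs$start[i], orfs$end[i])
    if (orfs$strand[i] == "-") x <- revcomp(x)
    x
  }, character(1))
  if (translate) s <- sub("\\*$", "", translate_dna(s))
  setNames(s, orfs$orf_id)
}

#' Write ORF protein sequences as query-ready FASTA
#'
#' @param orfs `orf_table` tibble.
#' @param genome Named chromosome sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_orf_fasta <- function(orfs, genome, path) {
  aa <- orf_sequences(orfs, genome, translate = TRUE)
  x <- Biostrings::AAStringSet(aa)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
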