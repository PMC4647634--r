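#' Filter small-RNA reads for the candidate screen
#'
#' Retains reads that (1) are 17-25 nt long, (2) match the reference
#' perfectly (edit distance 0; reads with an unknown edit distance are
#' dropped), and (3) do not lie on the coding strand of an annotated
#' protein, tRNA or rRNA gene — antisense overlap is retained, since a
#' read antisense to a gene cannot be a degradation product of that
#' gene's transcript.
#'
#' @param alignments Small-RNA alignment tibble (any libraries).
#' @param features Feature tibble.
#' @param length_range Length bounds in nt, default `c(17, 25)`.
#' @return The filtered subset of `alignments`.
#' @export
filter_smallrna_reads <- function(alignments, features,
                                  length_range = c(17L, 25L)) {
  keep <- alignments$read_length >= length_range[1] &
    alignments$read_length <= length_range[2] &
    !is.na(alignments$mismatch_count) & alignments$mismatch_count == 0L
  a <- alignments[keep, , drop = FALSE]
  if (!nrow(a)) return(a)
  genes <- gene_like(features, types = c("gene", "tRNA", "rRNA"))
  if (nrow(genes)) {
    drop <- logical(nrow(a))
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      drop <- drop | (a$chrom == g$chrom & a$strand == g$strand &
                        a$start <= g$end & a$end >= g$start)
    }
    a <- a[!drop, , drop = FALSE]
  }
  a
}

#' Call candidate small RNAs from read stacks
#'
#' Groups filtered reads by exact (chromosome, start, length, strand): a
#' group is a candidate when its pooled count across mitochondrial-
#' enriched libraries reaches `min_depth` and at most
#' `max_neighbor_overlap` other filtered reads (any library, either
#' strand) overlap its footprint — reads stacking at a single coordinate
#' with clean flanks are the signature of a discrete small RNA, whereas
#' degradation smears scatter overlapping starts.
#'
#' @param filtered Filtered small-RNA alignments from
#'   [filter_smallrna_reads()], all libraries pooled.
#' @param genome Named chromosome sequences (for candidate sequence).
#' @param libraries Library set (identifies mitochondrial-enriched
#'   libraries and CPM denominators).
#' @param min_depth Minimum pooled mitochondrial-library count, default
#'   50.
#' @param max_neighbor_overlap Maximum tolerated overlapping
#'   non-member reads, default 1.
#'
#' @return Tibble of class `smallrna_candidates`: `chrom`, `start`,
#'   `end`, `length`, `strand`, one `n_<library_id>` count column per
#'   library, `neighbor_overlap`, `sequence`; ordered by position so the
#'   result is invariant to input read order.
#' @export
stack_candidates <- function(filtered, genome, libraries, min_depth = 50L,
                             max_neighbor_overlap = 1L) {
  if (min_depth < 1L) abort("min_depth must be >= 1")
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  length = integer(), strand = character(),
                  neighbor_overlap = integer(), sequence = character())
  if (!nrow(filtered)) {
    return(structure(empty, class = c("smallrna_candidates", class(empty))))
  }
  srna_libs <- libraries[libraries$assay == "smallrna", ]
  mito_ids <- srna_libs$library_id[srna_libs$role == "mito_enriched"]

  groups <- filtered |>
    group_by(.data$chrom, .data$start, .data$read_length, .data$strand,
             .data$library_id) |>
    summarise(n = n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "library_id", values_from = "n",
                       values_fill = 0L, names_prefix = "n_")
  for (id in srna_libs$library_id) {
    col <- paste0("n_", id)
    if (!col %in% names(groups)) groups[[col]] <- 0L
  }
  groups$end <- groups$start + groups$read_length - 1L
  mito_cols <- paste0("n_", mito_ids)
  groups$mito_count <- rowSums(as.matrix(groups[, mito_cols, drop = FALSE]))
  cand <- groups[groups$mito_count >= min_depth, , drop = FALSE]
  if (!nrow(cand)) {
    return(structure(empty, class = c("smallrna_candidates", class(empty))))
  }

  # neighbor overlap: reads overlapping the footprint but not in the group
  all_gr <- GenomicRanges::GRanges(filtered$chrom,
                                   IRanges::IRanges(filtered$start, filtered$end))
  cand_gr <- GenomicRanges::GRanges(cand$chrom,
                                    IRanges::IRanges(cand$start, cand$end))
  lv <- unique(filtered$chrom)
  GenomeInfoDb::seqlevels(all_gr) <- lv
  GenomeInfoDb::seqlevels(cand_gr) <- lv
  total_overlap <- GenomicRanges::countOverlaps(cand_gr, all_gr,
                                                ignore.strand = TRUE)
  group_size <- integer(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    group_size[i] <- sum(filtered$chrom == cand$chrom[i] &
                           filtered$start == cand$start[i] &
                           filtered$read_length == cand$read_length[i] &
                           filtered$strand == cand$strand[i])
  }
  cand$neighbor_overlap <- total_overlap - group_size
  cand <- cand[cand$neighbor_overlap <= max_neighbor_overlap, , drop = FALSE]

  cand$length <- cand$read_length
  cand$sequence <- vapply(seq_len(nrow(cand)), function(i) {
    s <- genome_subseq(genome, cand$chrom[i], cand$start[i], cand$end[i])
    if (cand$strand[i] == "-") s <- revcomp(s)
    s
  }, character(1))
  out <- cand |>
    arrange(.data$chrom, .data$start, .data$strand, .data$length) |>
    select("chrom", "start", "end", "length", "strand",
           dplyr::all_of(paste0("n_", srna_libs$library_id)),
           "neighbor_overlap", "sequence")
  structure(out, class = c("smallrna_candidates", class(out)))
}

#' Flag candidates overrepresented in mitochondrial-enriched libraries
#'
#' A candidate is overrepresented when its CPM (count per million mapped
#' reads of the library) is greater in every mitochondrial-enriched
#' replicate than in every total-cellular replicate — the expected
#' pattern for a small RNA that is physically localized to mitochondria.
#'
#' @param candidates `smallrna_candidates` tibble.
#' @param libraries Library set including all four small-RNA libraries.
#' @return `candidates` with a logical `mito_overrepresented` column.
#' @export
flag_mito_overrepresentation <- function(candidates, libraries) {
  srna_libs <- libraries[libraries$assay == "smallrna", ]
  if (any(srna_libs$total_mapped_reads <= 0)) abort("zero library totals")
  mito_ids <- srna_libs$library_id[srna_libs$role == "mito_enriched"]
  tc_ids <- srna_libs$library_id[srna_libs$role == "total_cellular"]
  if (!length(mito_ids) || !length(tc_ids)) {
    abort("need both mitochondrial-enriched and total-cellular small-RNA libraries")
  }
  cpm <- function(id) {
    candidates[[paste0("n_", id)]] * 1e6 / library_total(srna_libs, id)
  }
  m <- vapply(mito_ids, cpm, numeric(nrow(candidates)))
  t <- vapply(tc_ids, cpm, numeric(nrow(candidates)))
  if (nrow(candidates) == 1L) {
    m <- matrix(m, nrow = 1L)
    t <- matrix(t, nrow = 1L)
  }
  candidates$mito_overrepresented <-
    apply(m, 1, min) > apply(t, 1, max)
  candidates
}

#' Correlation between small-RNA and mRNA coverage
#'
#' Pearson correlation of the CPM vectors of two window profiles computed
#' on an identical window grid; a positive correlation indicates that
#' much of the small-RNA population derives from degradation of longer
#' transcripts.
#'
#' @param smallrna_profile,mrna_profile `window_profile` tibbles on the
#'   same grid.
#' @return The Pearson correlation, or `NA` (with a warning) when fewer
#'   than 3 windows are available or either profile has zero variance.
#' @export
smallrna_mrna_correlation <- function(smallrna_profile, mrna_profile) {
  if (nrow(smallrna_profile) != nrow(mrna_profile) ||
        !all(smallrna_profile$chrom == mrna_profile$chrom &
               smallrna_profile$start == mrna_profile$start)) {
    abort("profiles are not on an identical window grid")
  }
  x <- smallrna_profile$cpm
  y <- mrna_profile$cpm
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("correlation undefined: fewer than 3 windows or zero variance")
    return(NA_real_)
  }
  cor(x, y, method = "pearson")
}

#' Write candidate small RNAs as FASTA for external similarity search
#'
#' @param candidates `smallrna_candidates` tibble.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_candidate_fasta <- function(candidates, path) {
  x <- Biostrings::DNAStringSet(candidates$sequence)
  names(x) <- sprintf("%s_%d_%d_%s", candidates$chrom, candidates$start,
                      candidates$end, candidates$strand)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
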