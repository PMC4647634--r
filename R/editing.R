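#' Strand-aware base pileup from ungapped alignments
#'
#' Counts A/C/G/T base calls per reference position, separately per
#' transcript strand (the strand of the contributing read; minus-strand
#' read sequences are stored in reference orientation, so all counts are
#' in reference-base space). Each call is also tallied when it lies
#' within `trim_margin` nt of its read's 3' end — the read region where
#' residual adapter bases and end-of-read errors concentrate.
#'
#' @param alignments Alignment tibble (one or several libraries pooled).
#' @param genome Named chromosome sequences.
#' @param trim_margin 3'-terminal margin in nt for the end-call tally,
#'   default 5.
#'
#' @return Tibble of class `pileup`: `chrom`, `pos`, `strand`, `ref`,
#'   counts `A`, `C`, `G`, `T`, end-region counts `end_A` ... `end_T`,
#'   and `depth`; one row per covered (position, strand).
#' @export
build_pileup <- function(alignments, genome, trim_margin = 5L) {
  if (trim_margin < 0L) abort("trim_margin must be >= 0")
  unknown <- setdiff(unique(alignments$chrom), names(genome))
  if (length(unknown)) {
    abort(paste0("alignments name chromosome '", unknown[1],
                 "' absent from the reference"))
  }
  has_indel <- grepl("[IDNSHP]", alignments$cigar %||% "")
  if (any(has_indel)) {
    warn("alignments with indel/clip CIGARs: only their leading aligned run is piled up")
  }
  out <- list()
  for (ch in sort(unique(alignments$chrom))) {
    a <- alignments[alignments$chrom == ch, , drop = FALSE]
    L <- nchar(genome[[ch]])
    mlen <- a$read_length
    ind <- grepl("[IDNSHP]", a$cigar %||% "")
    if (any(ind)) {
      lead <- suppressWarnings(as.integer(sub("^([0-9]+)M.*$", "\\1", a$cigar[ind])))
      lead[is.na(lead)] <- 0L
      mlen[ind] <- lead
    }
    keep <- mlen > 0L
    a <- a[keep, , drop = FALSE]
    mlen <- mlen[keep]
    if (!nrow(a)) next
    ridx <- rep.int(seq_len(nrow(a)), mlen)
    off <- sequence(mlen)
    pos <- a$start[ridx] + off - 1L
    chars <- unlist(strsplit(substr(a$seq, 1L, mlen), "", fixed = TRUE),
                    use.names = FALSE)
    minus <- a$strand[ridx] == "-"
    d3 <- ifelse(minus, off - 1L, mlen[ridx] - off)
    bidx <- match(chars, c("A", "C", "G", "T"))
    sidx <- as.integer(minus)
    key <- ((pos - 1L) * 2L + sidx) * 4L + bidx
    valid <- !is.na(bidx) & pos >= 1L & pos <= L
    counts <- tabulate(key[valid], nbins = L * 8L)
    end_counts <- tabulate(key[valid & d3 < trim_margin], nbins = L * 8L)
    cm <- matrix(counts, nrow = 4L)
    em <- matrix(end_counts, nrow = 4L)
    depth_col <- colSums(cm)
    nz <- which(depth_col > 0L)
    if (!length(nz)) next
    posv <- (nz - 1L) %/% 2L + 1L
    refc <- genome_chars(genome, ch)
    out[[ch]] <- tibble(
      chrom = ch, pos = posv,
      strand = ifelse((nz - 1L) %% 2L == 1L, "-", "+"),
      ref = refc[posv],
      A = cm[1L, nz], C = cm[2L, nz], G = cm[3L, nz], T = cm[4L, nz],
      end_A = em[1L, nz], end_C = em[2L, nz], end_G = em[3L, nz],
      end_T = em[4L, nz],
      depth = as.integer(depth_col[nz]))
  }
  empty <- tibble(chrom = character(), pos = integer(), strand = character(),
                  ref = character(), A = integer(), C = integer(),
                  G = integer(), T = integer(), end_A = integer(),
                  end_C = integer(), end_G = integer(), end_T = integer(),
                  depth = integer())
  res <- if (length(out)) bind_rows(out) else empty
  structure(res, class = c("pileup", class(res)), trim_margin = trim_margin)
}

canonical_type <- function(strand, ref, var) {
  ifelse((strand == "+" & ref == "C" & var == "T") |
           (strand == "-" & ref == "G" & var == "A"),
         "canonical_CtoU", "noncanonical")
}

#' Call candidate RNA-editing sites from a pileup
#'
#' Emits sites where, on a single transcript strand, depth reaches
#' `min_depth` and the most frequent non-reference base reaches
#' `min_freq` of all calls at the position on that strand (both
#' thresholds inclusive). When both strands pass at a position, the
#' deeper strand is kept (transcript-strand assignment by read
#' majority); a tie keeps the plus strand and flags it ambiguous.
#' Canonical sites are C-to-U on the transcript: genomic C->T on
#' plus-strand transcripts, G->A on minus-strand transcripts.
#'
#' @param pileup A `pileup` from [build_pileup()].
#' @param min_depth Minimum per-strand depth, default 100.
#' @param min_freq Minimum variant frequency, default 0.20.
#' @return Tibble of class `edit_sites`: `chrom`, `pos`, `strand`,
#'   `ref`, `var`, `depth`, `var_count`, `freq`, `editing_type`,
#'   `strand_ambiguous`.
#' @export
call_edit_sites <- function(pileup, min_depth = 100L, min_freq = 0.20) {
  if (min_freq <= 0 || min_freq > 1) abort("min_freq must be in (0, 1]")
  empty <- tibble(chrom = character(), pos = integer(), strand = character(),
                  ref = character(), var = character(), depth = integer(),
                  var_count = integer(), freq = numeric(),
                  editing_type = character(), strand_ambiguous = logical())
  if (!nrow(pileup)) {
    return(structure(empty, class = c("edit_sites", class(empty))))
  }
  bases <- c("A", "C", "G", "T")
  bm <- as.matrix(pileup[, bases])
  ref_idx <- match(pileup$ref, bases)
  vm <- bm
  ok_ref <- !is.na(ref_idx)
  vm[cbind(which(ok_ref), ref_idx[ok_ref])] <- -1L
  var_j <- max.col(vm, ties.method = "first")
  var_count <- vm[cbind(seq_len(nrow(vm)), var_j)]
  freq <- ifelse(pileup$depth > 0, var_count / pileup$depth, 0)
  keep <- ok_ref & pileup$depth >= min_depth & var_count > 0 & freq >= min_freq
  if (!any(keep)) {
    return(structure(empty, class = c("edit_sites", class(empty))))
  }
  sites <- pileup[keep, c("chrom", "pos", "strand", "ref", "depth")]
  sites$var <- bases[var_j[keep]]
  sites$var_count <- as.integer(var_count[keep])
  sites$freq <- freq[keep]
  sites$strand_ambiguous <- FALSE
  # transcript-strand assignment where both strands pass
  sites <- sites |>
    group_by(.data$chrom, .data$pos) |>
    arrange(desc(.data$depth), .data$strand, .by_group = TRUE) |>
    mutate(strand_ambiguous = n() > 1L & .data$depth[1] == max(.data$depth) &
             sum(.data$depth == max(.data$depth)) > 1L) |>
    dplyr::slice(1L) |>
    ungroup()
  sites$editing_type <- canonical_type(sites$strand, sites$ref, sites$var)
  sites <- sites |>
    arrange(.data$chrom, .data$pos) |>
    select("chrom", "pos", "strand", "ref", "var", "depth", "var_count",
           "freq", "editing_type", "strand_ambiguous")
  structure(sites, class = c("edit_sites", class(sites)))
}

# spliced CDS context of a genomic position; segs: CDS rows of one parent
cds_codon_context <- function(genome, segs, pos, parent_id) {
  strand <- segs$strand[1]
  segs <- segs[order(segs$start, decreasing = (strand == "-")), , drop = FALSE]
  seqs <- vapply(seq_len(nrow(segs)), function(i) {
    s <- genome_subseq(genome, segs$chrom[i], segs$start[i], segs$end[i])
    if (strand == "-") s <- revcomp(s)
    s
  }, character(1))
  spliced <- paste(seqs, collapse = "")
  if (nchar(spliced) %% 3L != 0L) {
    abort(paste0("CDS of '", parent_id, "' has length not divisible by 3; ",
                 "codon phase cannot be resolved"))
  }
  seg_len <- segs$end - segs$start + 1L
  prior <- c(0L, cumsum(seg_len))[seq_len(nrow(segs))]
  hit <- which(segs$start <= pos & segs$end >= pos)
  if (!length(hit)) {
    abort(paste0("position ", pos, " not inside CDS of '", parent_id, "'"))
  }
  hit <- hit[1]
  off <- prior[hit] + if (strand == "+") pos - segs$start[hit] + 1L
                      else segs$end[hit] - pos + 1L
  codon_i <- (off - 1L) %/% 3L + 1L
  list(spliced = spliced, offset = off, codon_index = codon_i,
       pos_in_codon = off - (codon_i - 1L) * 3L,
       codon = substr(spliced, (codon_i - 1L) * 3L + 1L, codon_i * 3L))
}

#' Assign editing sites to annotation categories
#'
#' Category precedence: coding sequence (split into synonymous vs
#' nonsynonymous by translating the codon with and without the edit
#' under the standard genetic code; stop-gain counts as nonsynonymous) >
#' pseudogene > intron > UTR > IGS. Intronic sites within
#' `intron_edge_exclusion` nt of an exon boundary are dropped entirely
#' (read mapping across intron/exon boundaries is unreliable there);
#' they are returned in the `excluded_introns` attribute. UTR vs IGS is
#' an arbitrary distance cutoff: sites within `utr_margin` nt of an
#' annotated coding sequence are UTR, the rest IGS.
#'
#' @param sites `edit_sites` tibble.
#' @param genome Named chromosome sequences.
#' @param features Feature tibble (CDS rows drive the coding category;
#'   introns may be annotated or implied by exon gaps).
#' @param utr_margin UTR/IGS distance cutoff in nt, default 2000.
#' @param intron_edge_exclusion Exon-boundary exclusion in nt, default
#'   20.
#' @return `sites` with `category` (and codon columns for coding sites);
#'   intron-edge sites removed and attached as
#'   `attr(, "excluded_introns")`.
#' @export
classify_edit_sites <- function(sites, genome, features, utr_margin = 2000L,
                                intron_edge_exclusion = 20L) {
  cds <- features[features$type == "CDS", , drop = FALSE]
  if (nrow(cds)) {
    cds$group <- ifelse(is.na(cds$parent), cds$feature_id, cds$parent)
  }
  introns <- bind_rows(features[features$type == "intron", , drop = FALSE],
                       derive_introns(features))
  pseudo <- features[features$type == "pseudogene", , drop = FALSE]

  n <- nrow(sites)
  category <- rep(NA_character_, n)
  codon_ref <- codon_alt <- aa_ref <- aa_alt <- rep(NA_character_, n)
  excluded <- logical(n)

  for (i in seq_len(n)) {
    s <- sites[i, ]
    # coding, same transcript strand
    hit <- which(cds$chrom == s$chrom & cds$strand == s$strand &
                   cds$start <= s$pos & cds$end >= s$pos)
    if (length(hit)) {
      grp <- cds$group[hit[1]]
      segs <- cds[cds$group == grp, , drop = FALSE]
      ctx <- cds_codon_context(genome, segs, s$pos, grp)
      var_tx <- if (s$strand == "+") s$var else comp_base(s$var)
      cod_alt <- ctx$codon
      substr(cod_alt, ctx$pos_in_codon, ctx$pos_in_codon) <- var_tx
      aa1 <- Biostrings::GENETIC_CODE[[ctx$codon]]
      aa2 <- Biostrings::GENETIC_CODE[[cod_alt]]
      category[i] <- if (identical(aa1, aa2)) "coding_synonymous"
                     else "coding_nonsynonymous"
      codon_ref[i] <- ctx$codon; codon_alt[i] <- cod_alt
      aa_ref[i] <- aa1; aa_alt[i] <- aa2
      next
    }
    if (nrow(pseudo) && any(pseudo$chrom == s$chrom & pseudo$start <= s$pos &
                              pseudo$end >= s$pos)) {
      category[i] <- "pseudogene"
      next
    }
    ih <- which(introns$chrom == s$chrom & introns$start <= s$pos &
                  introns$end >= s$pos)
    if (length(ih)) {
      it <- introns[ih[1], ]
      edge_d <- min(s$pos - it$start + 1L, it$end - s$pos + 1L)
      if (edge_d <= intron_edge_exclusion) {
        excluded[i] <- TRUE
      } else {
        category[i] <- "intron"
      }
      next
    }
    if (nrow(cds)) {
      near <- cds[cds$chrom == s$chrom, , drop = FALSE]
      if (nrow(near)) {
        gaps <- pmax(near$start - s$pos, s$pos - near$end, 0L)
        if (min(gaps) <= utr_margin) {
          category[i] <- "UTR"
          next
        }
      }
    }
    category[i] <- "IGS"
  }
  sites$category <- category
  sites$codon_ref <- codon_ref
  sites$codon_alt <- codon_alt
  sites$aa_ref <- aa_ref
  sites$aa_alt <- aa_alt
  out <- sites[!excluded, , drop = FALSE]
  attr(out, "excluded_introns") <- sites[excluded, , drop = FALSE]
  out
}

#' Re-check sites after masking read-end base calls
#'
#' Recomputes each site's depth and variant frequency ignoring base
#' calls within `extra_trim` nt of the 3' end of their read — an
#' in-pileup equivalent of remapping after trimming that many bases from
#' every read. Sites that no longer satisfy the calling thresholds are
#' flagged as artifacts: spurious calls driven by residual adapter bases
#' or clustered end-of-read errors collapse under this masking, whereas
#' genuine editing, being uniformly distributed along reads, survives.
#'
#' @param alignments The alignments the sites were called from.
#' @param genome Named chromosome sequences.
#' @param sites `edit_sites` tibble.
#' @param extra_trim Masked 3'-end margin in nt (>= 1), default 5.
#' @param min_depth,min_freq Calling thresholds to re-apply.
#' @return `sites` with logical `artifact`, plus `depth_masked` and
#'   `freq_masked` columns.
#' @export
end_trim_recheck <- function(alignments, genome, sites, extra_trim = 5L,
                             min_depth = 100L, min_freq = 0.20) {
  if (extra_trim < 1L) abort("extra_trim must be >= 1")
  pe <- build_pileup(alignments, genome, trim_margin = extra_trim)
  key <- paste(pe$chrom, pe$pos, pe$strand)
  idx <- match(paste(sites$chrom, sites$pos, sites$strand), key)
  bases <- c("A", "C", "G", "T")
  depth_m <- var_m <- integer(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    j <- idx[i]
    if (is.na(j)) next
    cnt <- unlist(pe[j, bases]) - unlist(pe[j, paste0("end_", bases)])
    depth_m[i] <- sum(cnt)
    var_m[i] <- cnt[match(sites$var[i], bases)]
  }
  sites$depth_masked <- depth_m
  sites$freq_masked <- ifelse(depth_m > 0, var_m / depth_m, 0)
  sites$artifact <- !(depth_m >= min_depth & var_m > 0L &
                        sites$freq_masked >= min_freq)
  sites
}

#' Collapse editing sites duplicated across identical repeats
#'
#' Sites at homologous offsets within an identical repeat pair, with the
#' same base change, are the same event observed twice through
#' cross-mapping; they are collapsed to one unique site. Members keep
#' their rows, gain a shared `duplicate_group` id, and one
#' representative per group is marked.
#'
#' @param sites Classified `edit_sites` tibble.
#' @param repeat_pairs Tibble with columns `pair_id`, `chrom_a`,
#'   `start_a`, `end_a`, `chrom_b`, `start_b`, `end_b` describing
#'   identical-sequence interval pairs (equal lengths required).
#' @return `sites` with `duplicate_group` (NA outside repeats) and
#'   logical `is_representative`.
#' @export
dedupe_edit_sites <- function(sites, repeat_pairs = NULL) {
  sites$duplicate_group <- NA_character_
  sites$is_representative <- TRUE
  if (is.null(repeat_pairs) || !nrow(repeat_pairs)) return(sites)
  len_a <- repeat_pairs$end_a - repeat_pairs$start_a
  len_b <- repeat_pairs$end_b - repeat_pairs$start_b
  if (any(len_a != len_b)) abort("repeat pair intervals have unequal lengths")

  canon_chrom <- sites$chrom
  canon_pos <- sites$pos
  for (i in seq_len(nrow(repeat_pairs))) {
    p <- repeat_pairs[i, ]
    in_b <- sites$chrom == p$chrom_b & sites$pos >= p$start_b &
      sites$pos <= p$end_b
    canon_chrom[in_b] <- p$chrom_a
    canon_pos[in_b] <- p$start_a + (sites$pos[in_b] - p$start_b)
  }
  key <- paste(canon_chrom, canon_pos, sites$ref, sites$var)
  dup_keys <- unique(key[duplicated(key)])
  if (length(dup_keys)) {
    grp_id <- setNames(sprintf("dup%03d", seq_along(dup_keys)), dup_keys)
    in_dup <- key %in% dup_keys
    sites$duplicate_group[in_dup] <- grp_id[key[in_dup]]
    first_of_group <- !duplicated(key)
    sites$is_representative <- !in_dup | first_of_group
  }
  sites
}

#' Summarize editing sites by annotation category
#'
#' Builds a per-category summary of canonical (C-to-U), non-artifact
#' sites: total site count, unique count after collapsing
#' repeat-duplicated sites, and the mean editing frequency over unique
#' sites (a collapsed site's frequency is the mean over its duplicate
#' group). Rows cover the coding subcategories, their protein-coding
#' roll-up, pseudogene, intron, UTR, IGS, and a totals row.
#'
#' @param sites Classified (and ideally deduplicated and artifact-
#'   checked) `edit_sites` tibble.
#' @return Tibble of class `editing_summary`: `category`, `n_sites`,
#'   `n_unique`, `mean_freq_unique`.
#' @export
summarize_editing <- function(sites) {
  s <- sites
  if ("editing_type" %in% names(s)) s <- s[s$editing_type == "canonical_CtoU", ]
  if ("artifact" %in% names(s)) s <- s[!s$artifact, ]
  if (!"duplicate_group" %in% names(s)) {
    s$duplicate_group <- NA_character_
    s$is_representative <- TRUE
  }
  # unique view: one row per duplicate group (mean frequency), all singletons
  uniq <- s |>
    mutate(grp = ifelse(is.na(.data$duplicate_group),
                        paste0("s", row_number()), .data$duplicate_group)) |>
    group_by(.data$category, .data$grp) |>
    summarise(freq = mean(.data$freq), .groups = "drop")
  cats <- c("coding_synonymous", "coding_nonsynonymous", "pseudogene",
            "intron", "UTR", "IGS")
  per_cat <- function(cat) {
    tibble(category = cat,
           n_sites = sum(s$category == cat),
           n_unique = sum(uniq$category == cat),
           mean_freq_unique = if (any(uniq$category == cat)) {
             mean(uniq$freq[uniq$category == cat])
           } else NA_real_)
  }
  rows <- bind_rows(lapply(cats, per_cat))
  coding <- rows[rows$category %in% c("coding_synonymous", "coding_nonsynonymous"), ]
  coding_row <- tibble(
    category = "protein_coding",
    n_sites = sum(coding$n_sites),
    n_unique = sum(coding$n_unique),
    mean_freq_unique = if (sum(coding$n_unique)) {
      mean(uniq$freq[uniq$category %in% c("coding_synonymous",
                                          "coding_nonsynonymous")])
    } else NA_real_)
  total_row <- tibble(
    category = "total",
    n_sites = sum(rows$n_sites),
    n_unique = sum(rows$n_unique),
    mean_freq_unique = if (nrow(uniq)) mean(uniq$freq) else NA_real_)
  out <- bind_rows(coding_row, rows, total_row)
  structure(out, class = c("editing_summary", class(out)))
}

#' Totals implied by per-category unique editing-site counts
#'
#' Given unique (duplicate-collapsed) site counts per annotation
#' category, returns the overall total and the non-coding total
#' (everything outside protein-coding sequence: pseudogenes, introns,
#' UTRs and intergenic sites).
#'
#' @param protein_coding,pseudogene,intron,utr,igs Unique site counts.
#' @return One-row tibble with `total_unique` and `noncoding_unique`.
#' @export
editing_totals <- function(protein_coding, pseudogene, intron, utr, igs) {
  tibble(total_unique = protein_coding + pseudogene + intron + utr + igs,
         noncoding_unique = pseudogene + intron + utr + igs)
}

#' Percentage of canonical (C-to-U) editing sites
#'
#' @param n_sites Total number of editing sites.
#' @param n_noncanonical Number of non-C-to-U sites among them.
#' @return Canonical percentage.
#' @export
canonical_percent <- function(n_sites, n_noncanonical) {
  if (n_sites <= 0) abort("n_sites must be positive")
  100 * (n_sites - n_noncanonical) / n_sites
}

#' Percentage helper for count comparisons
#'
#' @param k Numerator count.
#' @param n Denominator count.
#' @return `100 * k / n`.
#' @export
count_percent <- function(k, n) {
  if (n <= 0) abort("denominator must be positive")
  100 * k / n
}

#' Write editing sites as TSV or a minimal VCF-like text
#'
#' @param sites `edit_sites` tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_edit_sites <- function(sites, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(as_tibble(sites), path)
  } else {
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=STRAND,Number=1,Type=String,Description=\"Transcript strand\">",
             "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Editing type\">",
             "##INFO=<ID=CATEGORY,Number=1,Type=String,Description=\"Annotation category\">",
             "##INFO=<ID=FREQ,Number=1,Type=Float,Description=\"Editing frequency\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    cat_col <- if ("category" %in% names(sites)) sites$category else "."
    filt <- if ("artifact" %in% names(sites)) {
      ifelse(sites$artifact, "artifact", "PASS")
    } else "PASS"
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tSTRAND=%s;TYPE=%s;CATEGORY=%s;FREQ=%.4f",
                    sites$chrom, sites$pos, sites$ref, sites$var, filt,
                    sites$strand, sites$editing_type, cat_col, sites$freq)
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}
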