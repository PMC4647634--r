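STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# ATG + non-stop codons + TAA, n_nt divisible by 3
random_cds <- function(n_nt) {
  stopifnot(n_nt %% 3L == 0L, n_nt >= 9L)
  nonstop <- setdiff(all_codons(), STOP_CODONS)
  body <- sample(nonstop, n_nt / 3L - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

#' Parameters of the synthetic study generator
#'
#' Defines the toy multichromosomal genome and sequencing conditions that
#' [generate_dataset()] realizes: a desk-scale stand-in for a
#' multimegabase plant mitochondrial genome fragmented into dozens of
#' circular-mapping chromosomes, several of which carry no annotated gene.
#'
#' @param n_chromosomes Number of chromosomes (last `n_empty_chromosomes`
#'   of them carry no annotation).
#' @param chrom_length_range Range (nt) chromosome lengths are drawn from;
#'   a chromosome is extended when its planted content needs more room.
#' @param n_genes Number of planted protein-coding genes.
#' @param n_empty_chromosomes Number of annotation-free chromosomes.
#' @param read_length mRNA-assay read length (nt, >= 50).
#' @param smallrna_length_range Length range of small-RNA reads (17-25 nt).
#' @param background_depth Mean depth of genome-wide spurious transcription
#'   on each strand (x).
#' @param tc_attenuation Factor by which mitochondrial-origin transcripts
#'   are depleted in total-cellular libraries (and, symmetrically, by which
#'   plastid/nuclear-origin inserts are depleted in mitochondrial-enriched
#'   libraries).
#' @param utr_margin Transcribed flank (nt) upstream of each coding
#'   sequence.
#' @param seed Integer seed; every stochastic draw flows from it.
#'
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_chromosomes = 8L,
                            chrom_length_range = c(20000L, 60000L),
                            n_genes = 10L,
                            n_empty_chromosomes = 2L,
                            read_length = 100L,
                            smallrna_length_range = c(17L, 25L),
                            background_depth = 2,
                            tc_attenuation = 0.05,
                            utr_margin = 200L,
                            seed = 42L) {
  if (read_length < 50L) abort("mRNA read length must be >= 50 nt")
  if (n_chromosomes < n_empty_chromosomes + 1L) {
    abort("need at least one non-empty chromosome")
  }
  if (any(c(n_chromosomes, n_genes, n_empty_chromosomes) < 0L)) {
    abort("counts must be non-negative")
  }
  if (smallrna_length_range[1] < 17L || smallrna_length_range[2] > 25L) {
    abort("small-RNA lengths must lie within 17-25 nt")
  }
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_range = as.integer(chrom_length_range),
    n_genes = as.integer(n_genes),
    n_empty_chromosomes = as.integer(n_empty_chromosomes),
    read_length = as.integer(read_length),
    smallrna_length_range = as.integer(smallrna_length_range),
    background_depth = background_depth,
    tc_attenuation = tc_attenuation,
    utr_margin = as.integer(utr_margin),
    seed = as.integer(seed)
  ), class = "simulation_spec")
}

# sequential first-fit placement of unit lengths on one chromosome;
# returns start positions, growing the chromosome is the caller's job
place_on_chrom <- function(lens, edge = 2500L, gap = 5000L) {
  starts <- integer(length(lens))
  cursor <- edge
  for (i in seq_along(lens)) {
    starts[i] <- cursor + sample.int(1500L, 1L)
    cursor <- starts[i] + lens[i] + gap
  }
  starts
}

# uniform read starts giving expected plateau depth `depth` over [s, e].
# clamp_right/clamp_left emulate sharp 3' transcript processing: reads that
# would overrun the processed end are stacked so they end exactly there.
unit_read_starts <- function(s, e, depth, rl, chrom_len,
                             clamp_left = NA_integer_, clamp_right = NA_integer_) {
  lo <- max(1L, s - rl + 1L)
  hi <- min(e, chrom_len - rl + 1L)
  if (hi < lo) return(integer(0))
  n <- round(depth * (hi - lo + rl) / rl)
  if (n <= 0) return(integer(0))
  st <- lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
  if (!is.na(clamp_right)) st <- pmin(st, clamp_right - rl + 1L)
  if (!is.na(clamp_left)) st <- pmax(st, clamp_left)
  st
}

# flip the base at genomic position `pos` (reference orientation) to `var`
# on each covering read of `read_strand`, independently with prob `freq`
apply_edit <- function(reads, chrom, pos, read_strand, var, freq) {
  idx <- which(reads$chrom == chrom & reads$strand == read_strand &
                 reads$start <= pos & reads$end >= pos)
  if (!length(idx)) return(reads)
  hit <- idx[runif(length(idx)) < freq]
  if (!length(hit)) return(reads)
  off <- pos - reads$start[hit] + 1L
  s <- reads$seq[hit]
  substr(s, off, off) <- rep(var, length(hit))
  reads$seq[hit] <- s
  reads$mismatch_count[hit] <- reads$mismatch_count[hit] + 1L
  reads
}

finalize_reads <- function(reads, lib_id, genome) {
  if (!nrow(reads)) {
    return(tibble(read_id = character(), library_id = character(),
                  chrom = character(), start = integer(), end = integer(),
                  read_length = integer(), strand = character(),
                  mismatch_count = integer(), cigar = character(),
                  seq = character()))
  }
  reads$library_id <- lib_id
  reads$read_id <- sprintf("%s_r%06d", lib_id, seq_len(nrow(reads)))
  reads$cigar <- paste0(reads$read_length, "M")
  reads[, c("read_id", "library_id", "chrom", "start", "end", "read_length",
            "strand", "mismatch_count", "cigar", "seq")]
}

#' Write alignment records as a coordinate-sorted SAM file
#'
#' Emits standard SAM: a header with `@SQ` lines in genome order, then one
#' line per record with the reverse-strand flag (0x10) and the `NM`
#' edit-distance tag. The generator emits reads pre-mapped, so no
#' FASTQ/alignment round trip is involved and the truth table is exact.
#'
#' @param alignments Alignment tibble (as from [load_alignments()]).
#' @param genome Named character vector of chromosome sequences.
#' @param path Output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), genome_lengths(genome)))
  a <- alignments[order(match(alignments$chrom, names(genome)), alignments$start), ]
  body <- sprintf("%s\t%d\t%s\t%d\t42\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                  a$read_id, ifelse(a$strand == "-", 16L, 0L), a$chrom,
                  a$start, a$cigar, a$seq, a$mismatch_count)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Generate a synthetic mitochondrial transcriptome study
#'
#' Builds a toy multichromosomal genome with planted expressed genes
#' (including one intron-containing gene, one gene with a mid-CDS coverage
#' collapse, and genes with and without sharp 3' transcript processing), a
#' pseudogene, plastid- and nuclear-derived insert regions expressed
#' predominantly in total-cellular libraries, expressed intergenic regions
#' (one containing a planted 729-bp ORF, one containing a verbatim copy of
#' a gene 3' end to provoke cross-mapping), an identical repeat pair, and
#' RNA-editing sites at chosen frequencies, including read-end-biased
#' artifact sites. Four mRNA-assay libraries (two mitochondrial-enriched,
#' two total-cellular) are emitted as coordinate-sorted SAM alongside a
#' machine-readable truth table. Deterministic given `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created if needed).
#' @return An object of class `mito_sim`: a list with `genome`, `features`,
#'   `libraries`, `alignments` (list of per-library tibbles), `paths`
#'   (FASTA/GFF3/SAM/truth files), `truth` (list of truth tibbles), and
#'   `spec`.
#' @export
generate_dataset <- function(spec = simulation_spec(), dir = tempfile("mitosim")) {
  set.seed(spec$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rl <- spec$read_length
  att <- spec$tc_attenuation
  chrom_names <- sprintf("mchr%02d", seq_len(spec$n_chromosomes))
  n_carrier <- spec$n_chromosomes - spec$n_empty_chromosomes
  carriers <- chrom_names[seq_len(n_carrier)]
  empties <- chrom_names[setdiff(seq_len(spec$n_chromosomes), seq_len(n_carrier))]

  # ---- plan units ------------------------------------------------------
  # each unit: an expressed span with per-condition depth scaling
  units <- list()
  add_unit <- function(id, kind, len, depth, strand,
                       mito_scale = 1, tc_scale = att, utr5 = spec$utr_margin,
                       utr3 = 0L) {
    units[[length(units) + 1L]] <<- list(
      id = id, kind = kind, len = as.integer(len), depth = depth,
      strand = strand, mito_scale = mito_scale, tc_scale = tc_scale,
      utr5 = as.integer(utr5), utr3 = as.integer(utr3))
  }

  gene_strands <- rep(c("+", "-"), length.out = spec$n_genes)
  gene_cds_len <- 3L * sample(320:650, spec$n_genes, replace = TRUE)
  gene_depth <- sample(250:800, spec$n_genes, replace = TRUE)
  for (i in seq_len(spec$n_genes)) {
    # genes 9, 10 lack 3' processing (run-on past the stop codon)
    utr3 <- if (i %in% c(9L, 10L) && spec$n_genes >= 10L) 400L else 0L
    add_unit(sprintf("gene%02d", i), "gene", gene_cds_len[i] + 400L * (i == 1L),
             gene_depth[i], gene_strands[i], utr3 = utr3)
  }
  add_unit("pseudo1", "pseudogene", 900L, 320, "+", utr3 = 400L)
  # inserts: expressed from their source genome, so total-cellular
  # libraries see them at full depth while cross-mapping still leaves a
  # substantial signal in the mitochondrial-enriched libraries
  add_unit("plastid1", "plastid_insert", 1500L, 400, "+",
           mito_scale = 0.4, tc_scale = 1)
  add_unit("nuclear1", "nuclear_insert", 1200L, 350, "+",
           mito_scale = 0.4, tc_scale = 1)
  add_unit("igs1", "igs", 2000L, 500, "+", utr5 = 0L)
  add_unit("igs2", "igs", 1400L, 900, "+", utr5 = 0L)   # carries the 729-bp ORF
  add_unit("igs3", "igs", 2000L, 300, "-", utr5 = 0L)   # carries a gene 3'-end copy
  add_unit("rep_a", "repeat", 2000L, 350, "+", utr5 = 0L)
  add_unit("rep_b", "repeat", 2000L, 350, "+", utr5 = 0L)
  add_unit("igs4", "igs", 1600L, 300, "+", utr5 = 0L)
  add_unit("igs5", "igs", 1800L, 400, "-", utr5 = 0L)
  # quiet loci reserved for small-RNA stacks (no mRNA reads)
  for (i in 1:4) add_unit(sprintf("stack%d", i), "stack_site", 25L, 0, "+", utr5 = 0L)

  # assignment: igs4/igs5 on the first empty chromosome, the rest round-robin
  kinds <- vapply(units, `[[`, character(1), "kind")
  ids <- vapply(units, `[[`, character(1), "id")
  chrom_of <- character(length(units))
  on_empty <- ids %in% c("igs4", "igs5") & length(empties) > 0L
  chrom_of[on_empty] <- empties[1]
  chrom_of[!on_empty] <- rep(carriers, length.out = sum(!on_empty))

  # place units, then fix chromosome lengths to fit
  chrom_len <- setNames(
    sample(seq(spec$chrom_length_range[1], spec$chrom_length_range[2]),
           spec$n_chromosomes, replace = TRUE),
    chrom_names)
  starts <- integer(length(units))
  for (ch in chrom_names) {
    sel <- which(chrom_of == ch)
    if (!length(sel)) next
    lens <- vapply(units[sel], `[[`, integer(1), "len")
    st <- place_on_chrom(lens)
    starts[sel] <- st
    need <- max(st + lens) + 2500L
    if (chrom_len[ch] < need) chrom_len[ch] <- need
  }

  genome <- setNames(vapply(chrom_len, random_dna, character(1)), chrom_names)

  # ---- realize unit sequences and annotation ---------------------------
  plant_seq <- function(chrom, at, s) {
    substr(genome[[chrom]], at, at + nchar(s) - 1L) <<- s
  }
  features <- list()
  add_feature <- function(feature_id, chrom, start, end, strand, type, parent = NA) {
    features[[length(features) + 1L]] <<- tibble(
      feature_id = feature_id, chrom = chrom, start = as.integer(start),
      end = as.integer(end), strand = strand, type = type,
      parent = as.character(parent))
  }

  unit_tbl <- tibble(
    id = ids, kind = kinds, chrom = chrom_of, start = starts,
    len = vapply(units, `[[`, integer(1), "len"),
    depth = vapply(units, `[[`, numeric(1), "depth"),
    strand = vapply(units, `[[`, character(1), "strand"),
    mito_scale = vapply(units, `[[`, numeric(1), "mito_scale"),
    tc_scale = vapply(units, `[[`, numeric(1), "tc_scale"),
    utr5 = vapply(units, `[[`, integer(1), "utr5"),
    utr3 = vapply(units, `[[`, integer(1), "utr3"))
  unit_tbl$end <- unit_tbl$start + unit_tbl$len - 1L

  edit_truth <- list()
  add_edit <- function(chrom, pos, strand, ref, var, freq, canonical, category,
                       artifact = FALSE, boundary_excluded = FALSE,
                       repeat_group = NA_character_, depth_unit = NA_real_) {
    edit_truth[[length(edit_truth) + 1L]] <<- tibble(
      chrom = chrom, pos = as.integer(pos), strand = strand, ref = ref,
      var = var, freq = freq, canonical = canonical, category = category,
      artifact = artifact, boundary_excluded = boundary_excluded,
      repeat_group = repeat_group, depth_unit = depth_unit)
  }

  # force the genomic base at a site to the transcript-strand reference
  force_base <- function(chrom, pos, tx_strand, tx_ref) {
    g_ref <- if (tx_strand == "+") tx_ref else comp_base(tx_ref)
    substr(genome[[chrom]], pos, pos) <<- g_ref
    g_ref
  }

  urow <- function(id) unit_tbl[unit_tbl$id == id, ]

  # genes: gene01 gets an intron, gene02 a mid-CDS coverage collapse,
  # genes 3-6 carry canonical editing sites at chosen codon templates
  gene_cds <- list()   # transcript-orientation CDS strings by gene id
  intron_bounds <- NULL
  for (i in seq_len(spec$n_genes)) {
    id <- sprintf("gene%02d", i)
    u <- urow(id)
    cds_len <- gene_cds_len[i]
    cds <- random_cds(cds_len)
    if (i == 1L) {
      # split the CDS after exon1_nt into two exons around a 400-nt intron
      exon1_nt <- 3L * (cds_len %/% 6L)
      intron <- random_dna(400L)
      g_seq <- paste0(substr(cds, 1L, exon1_nt), intron,
                      substr(cds, exon1_nt + 1L, cds_len))
      if (u$strand == "-") g_seq <- revcomp(g_seq)
      plant_seq(u$chrom, u$start, g_seq)
      if (u$strand == "+") {
        e1 <- c(u$start, u$start + exon1_nt - 1L)
        it <- c(e1[2] + 1L, e1[2] + 400L)
        e2 <- c(it[2] + 1L, u$end)
      } else {
        e2 <- c(u$start, u$start + (cds_len - exon1_nt) - 1L)
        it <- c(e2[2] + 1L, e2[2] + 400L)
        e1 <- c(it[2] + 1L, u$end)
      }
      add_feature(id, u$chrom, u$start, u$end, u$strand, "gene")
      add_feature(paste0(id, "_exon1"), u$chrom,
                  if (u$strand == "+") e1[1] else e1[1],
                  if (u$strand == "+") e1[2] else e1[2], u$strand, "exon", id)
      add_feature(paste0(id, "_exon2"), u$chrom, e2[1], e2[2], u$strand, "exon", id)
      add_feature(paste0(id, "_cds1"), u$chrom, e1[1], e1[2], u$strand, "CDS", id)
      add_feature(paste0(id, "_cds2"), u$chrom, e2[1], e2[2], u$strand, "CDS", id)
      intron_bounds <- list(chrom = u$chrom, start = it[1], end = it[2],
                            strand = u$strand)
    } else {
      g_seq <- if (u$strand == "+") cds else revcomp(cds)
      plant_seq(u$chrom, u$start, g_seq)
      add_feature(id, u$chrom, u$start, u$end, u$strand, "gene")
      add_feature(paste0(id, "_exon"), u$chrom, u$start, u$end, u$strand, "exon", id)
      add_feature(paste0(id, "_cds"), u$chrom, u$start, u$end, u$strand, "CDS", id)
    }
    gene_cds[[id]] <- cds
  }

  # codon-templated canonical CDS editing sites; the template codon is
  # overwritten in the genome so the synonymous/nonsynonymous truth is
  # forced by the genetic code
  plant_cds_site <- function(gene_id, codon_index, template, codon_pos, var_tx,
                             freq, category) {
    u <- urow(gene_id)
    cds_len <- nchar(gene_cds[[gene_id]])
    off <- (codon_index - 1L) * 3L                      # transcript offset of codon
    tpl_g <- if (u$strand == "+") template else revcomp(template)
    at <- if (u$strand == "+") u$start + off else u$end - off - 2L
    plant_seq(u$chrom, at, tpl_g)
    substr(gene_cds[[gene_id]], off + 1L, off + 3L) <<- template
    tx_pos_in_codon <- codon_pos
    pos <- if (u$strand == "+") at + tx_pos_in_codon - 1L
           else at + (3L - tx_pos_in_codon)
    g_ref <- substr(genome[[u$chrom]], pos, pos)
    g_var <- if (u$strand == "+") var_tx else comp_base(var_tx)
    add_edit(u$chrom, pos, u$strand, g_ref, g_var, freq,
             canonical = TRUE, category = category, depth_unit = u$depth)
  }
  if (spec$n_genes >= 6L) {
    # CCA(Pro) -> UCA(Ser): nonsynonymous, codon position 1
    plant_cds_site("gene03", 50L, "CCA", 1L, "T", 0.90, "coding_nonsynonymous")
    # CTC(Leu) -> CTT(Leu): synonymous, codon position 3
    plant_cds_site("gene04", 80L, "CTC", 3L, "T", 0.50, "coding_synonymous")
    plant_cds_site("gene05", 120L, "CCA", 1L, "T", 0.35, "coding_nonsynonymous")
    # below the 20 % calling threshold on purpose
    plant_cds_site("gene06", 60L, "CCA", 1L, "T", 0.10, "coding_nonsynonymous")
    # minus-strand gene: TAC(Tyr) -> TAU(Tyr), synonymous at codon position 3
    g_minus <- sprintf("gene%02d", which(gene_strands == "-")[1])
    plant_cds_site(g_minus, 90L, "TAC", 3L, "T", 0.55, "coding_synonymous")
  }

  # intron sites: one interior (kept), one 10 nt from the exon boundary
  # (dropped by the edge-exclusion rule)
  if (!is.null(intron_bounds)) {
    ib <- intron_bounds
    mid <- ib$start + (ib$end - ib$start) %/% 2L
    ref <- force_base(ib$chrom, mid, ib$strand, "C")
    add_edit(ib$chrom, mid, ib$strand, ref,
             if (ib$strand == "+") "T" else "A", 0.50, TRUE, "intron",
             depth_unit = urow("gene01")$depth)
    edge_pos <- ib$start + 9L
    ref2 <- force_base(ib$chrom, edge_pos, ib$strand, "C")
    add_edit(ib$chrom, edge_pos, ib$strand, ref2,
             if (ib$strand == "+") "T" else "A", 0.50, TRUE, "intron",
             boundary_excluded = TRUE, depth_unit = urow("gene01")$depth)
  }

  # UTR site: 80 nt upstream of gene03's CDS, inside the transcribed flank
  if (spec$n_genes >= 3L) {
    u <- urow("gene03")
    pos <- if (u$strand == "+") u$start - 80L else u$end + 80L
    ref <- force_base(u$chrom, pos, u$strand, "C")
    add_edit(u$chrom, pos, u$strand, ref,
             if (u$strand == "+") "T" else "A", 0.45, TRUE, "UTR",
             depth_unit = u$depth)
  }

  # pseudogene: CDS-like sequence interrupted by an internal stop
  {
    u <- urow("pseudo1")
    ps <- random_cds(u$len)
    substr(ps, 301L, 303L) <- "TAA"
    plant_seq(u$chrom, u$start, ps)
    add_feature("pseudo1", u$chrom, u$start, u$end, u$strand, "pseudogene")
    pos <- u$start + 450L
    ref <- force_base(u$chrom, pos, "+", "C")
    add_edit(u$chrom, pos, "+", ref, "T", 0.60, TRUE, "pseudogene",
             depth_unit = u$depth)
  }

  # inserts (annotated, expressed mainly in total-cellular libraries)
  for (id in c("plastid1", "nuclear1")) {
    u <- urow(id)
    add_feature(id, u$chrom, u$start, u$end, u$strand,
                if (id == "plastid1") "plastid_insert" else "nuclear_insert")
  }

  # igs2: plant a 729-bp ORF (242 codons + stop) with a stop codon just
  # upstream in frame; flanks are re-drawn until no competing ORF >= 201 nt
  {
    u <- urow("igs2")
    orf_off <- (u$len - 729L) %/% 2L   # 0-based offset of the ORF in the region
    repeat {
      reg <- random_dna(u$len)
      orf <- random_cds(729L)
      substr(reg, orf_off + 1L, orf_off + 729L) <- orf
      substr(reg, orf_off - 2L, orf_off) <- "TAA"   # in-frame stop upstream
      found <- find_orfs(c(region = reg), min_length = 201L)
      if (nrow(found) == 1L && found$start == orf_off + 1L &&
            found$end == orf_off + 729L && found$strand == "+") break
    }
    plant_seq(u$chrom, u$start, reg)
    orf_at <- u$start + orf_off
    orf_truth <- tibble(chrom = u$chrom, start = orf_at, end = orf_at + 728L,
                        strand = "+", length = 729L, depth = u$depth)
  }

  # igs3: verbatim copy of gene03's final 390 nt (cross-mapping bait)
  if (spec$n_genes >= 3L) {
    u <- urow("igs3")
    g <- urow("gene03")
    copy_src <- substr(genome[[g$chrom]], g$end - 389L, g$end)
    plant_seq(u$chrom, u$start + 800L, copy_src)
  }

  # identical repeat pair, annotated, with an editing site at the same
  # offset in both copies
  {
    a <- urow("rep_a"); b <- urow("rep_b")
    rep_seq <- random_dna(a$len)
    off <- 700L
    substr(rep_seq, off, off) <- "C"
    plant_seq(a$chrom, a$start, rep_seq)
    plant_seq(b$chrom, b$start, rep_seq)
    add_feature("rep_a", a$chrom, a$start, a$end, "+", "repeat")
    add_feature("rep_b", b$chrom, b$start, b$end, "+", "repeat")
    add_edit(a$chrom, a$start + off - 1L, "+", "C", "T", 0.50, TRUE, "IGS",
             repeat_group = "rep1", depth_unit = a$depth)
    add_edit(b$chrom, b$start + off - 1L, "+", "C", "T", 0.50, TRUE, "IGS",
             repeat_group = "rep1", depth_unit = b$depth)
    repeat_pairs <- tibble(pair_id = "rep1",
                           chrom_a = a$chrom, start_a = a$start, end_a = a$end,
                           chrom_b = b$chrom, start_b = b$start, end_b = b$end)
  }

  # igs editing sites (transcript strand = the planted region strand)
  for (site in list(list(id = "igs1", at = 500L, f = 0.60),
                    list(id = "igs1", at = 1400L, f = 0.30),
                    list(id = "igs4", at = 800L, f = 0.60))) {
    u <- urow(site$id)
    pos <- u$start + site$at
    ref <- force_base(u$chrom, pos, u$strand, "C")
    add_edit(u$chrom, pos, u$strand, ref,
             if (u$strand == "+") "T" else "A", site$f, TRUE, "IGS",
             depth_unit = u$depth)
  }

  # read-end-biased artifact sites (non-canonical base changes supported
  # only by calls in the terminal 5 nt of reads)
  artifact_sites <- list(
    list(id = "gene07", at = 400L, ref = "A", var = "G"),
    list(id = "gene08", at = 500L, ref = "T", var = "G"),
    list(id = "igs1", at = 1000L, ref = "A", var = "C"))
  artifact_sites <- Filter(function(s) s$id %in% unit_tbl$id, artifact_sites)
  for (s in artifact_sites) {
    u <- urow(s$id)
    pos <- u$start + s$at
    substr(genome[[u$chrom]], pos, pos) <- s$ref
    add_edit(u$chrom, pos, u$strand, s$ref, s$var, NA_real_, FALSE,
             if (s$id == "igs1") "IGS" else "coding_nonsynonymous",
             artifact = TRUE, depth_unit = u$depth)
  }

  features <- bind_rows(features)
  edit_truth <- bind_rows(edit_truth)
  assert_features(features, genome)

  # ---- small-RNA truth (realized later by generate_smallrna_assay) -----
  stack_rows <- unit_tbl[unit_tbl$kind == "stack_site", ]
  stack_len <- c(22L, 21L, 24L, 19L)
  stack_strand <- c("+", "+", "-", "-")
  stack_counts <- rbind(c(80L, 75L, 3L, 2L),
                        c(40L, 35L, 30L, 28L),
                        c(100L, 90L, 5L, 4L),
                        c(30L, 15L, 1L, 1L))
  stacks <- tibble(
    stack_id = stack_rows$id,
    chrom = stack_rows$chrom,
    start = stack_rows$start,
    length = stack_len[seq_len(nrow(stack_rows))],
    strand = stack_strand[seq_len(nrow(stack_rows))],
    n_mito1 = stack_counts[seq_len(nrow(stack_rows)), 1],
    n_mito2 = stack_counts[seq_len(nrow(stack_rows)), 2],
    n_tc1 = stack_counts[seq_len(nrow(stack_rows)), 3],
    n_tc2 = stack_counts[seq_len(nrow(stack_rows)), 4])
  stacks$end <- stacks$start + stacks$length - 1L

  smear_units <- unit_tbl[unit_tbl$kind %in% c("gene", "igs", "pseudogene"), ]
  smears <- tibble(
    smear_id = paste0("smear_", smear_units$id),
    unit_id = smear_units$id,
    chrom = smear_units$chrom,
    start = smear_units$start,
    end = smear_units$end,
    strand = smear_units$strand,
    n_mito = round(smear_units$depth * 0.6))

  # ---- emit the four mRNA libraries ------------------------------------
  libs <- tibble(
    library_id = c("mito1_mrna", "mito2_mrna", "tc1_mrna", "tc2_mrna"),
    role = c("mito_enriched", "mito_enriched", "total_cellular", "total_cellular"),
    replicate = c(1L, 2L, 1L, 2L),
    assay = "mrna",
    jitter = runif(4, 0.92, 1.08))

  expr_units <- unit_tbl[unit_tbl$kind != "stack_site", ]
  alignments <- list()
  for (k in seq_len(nrow(libs))) {
    lib <- libs[k, ]
    scale_col <- if (lib$role == "mito_enriched") "mito_scale" else "tc_scale"
    reads <- list()
    for (j in seq_len(nrow(expr_units))) {
      u <- expr_units[j, ]
      d <- u$depth * u[[scale_col]] * lib$jitter
      plus <- u$strand == "+"
      s <- u$start - (if (plus) u$utr5 else u$utr3)
      e <- u$end + (if (plus) u$utr3 else u$utr5)
      L <- chrom_len[[u$chrom]]
      clip <- u$kind == "gene" && u$utr3 == 0L
      cl <- if (clip && !plus) u$start else NA_integer_
      cr <- if (clip && plus) u$end else NA_integer_
      if (u$id == "gene02") {
        # coverage collapse 60 % of the way along the transcript: full
        # depth over the transcript-5' part, 2 % of it beyond
        g_mid <- if (plus) u$start + (u$len * 6L) %/% 10L
                 else u$end - (u$len * 6L) %/% 10L
        if (plus) {
          st1 <- unit_read_starts(s, g_mid, d, rl, L, clamp_right = g_mid)
          st2 <- unit_read_starts(g_mid + 1L, e, d * 0.02, rl, L, clamp_right = cr)
        } else {
          st1 <- unit_read_starts(g_mid, e, d, rl, L, clamp_left = g_mid)
          st2 <- unit_read_starts(s, g_mid - 1L, d * 0.02, rl, L, clamp_left = cl)
        }
        st <- c(st1, st2)
      } else {
        st <- unit_read_starts(s, e, d, rl, L, clamp_left = cl, clamp_right = cr)
      }
      if (length(st)) {
        reads[[length(reads) + 1L]] <- tibble(
          chrom = u$chrom, start = st, end = st + rl - 1L,
          read_length = rl, strand = u$strand)
      }
    }
    # background spurious transcription, both strands, genome-wide
    bg_rate <- spec$background_depth *
      (if (lib$role == "mito_enriched") 1 else att)
    for (ch in chrom_names) {
      L <- chrom_len[[ch]]
      n_bg <- round(bg_rate * L / rl)
      if (n_bg <= 0) next
      for (strd in c("+", "-")) {
        st <- sample.int(L - rl + 1L, n_bg, replace = TRUE)
        reads[[length(reads) + 1L]] <- tibble(
          chrom = ch, start = st, end = st + rl - 1L,
          read_length = rl, strand = strd)
      }
    }
    reads <- bind_rows(reads)
    # extract reference sequence
    reads <- reads |> arrange(.data$chrom, .data$start)
    reads$seq <- unlist(lapply(split(reads, reads$chrom), function(g) {
      substring(genome[[g$chrom[1]]], g$start, g$end)
    }), use.names = FALSE)
    reads$mismatch_count <- 0L

    # artifact reads: 3' ends within 5 nt downstream of the site, each
    # carrying the non-canonical mismatch (mitochondrial libraries only)
    if (lib$role == "mito_enriched") {
      for (s in artifact_sites) {
        u <- urow(s$id)
        pos <- u$start + s$at
        n_art <- round(u$depth * 0.9 * lib$jitter)
        if (u$strand == "+") {
          ends <- pos + sample.int(5L, n_art, replace = TRUE) - 1L
          st <- ends - rl + 1L
        } else {
          st <- pos - sample.int(5L, n_art, replace = TRUE) + 1L
          ends <- st + rl - 1L
        }
        sq <- substring(genome[[u$chrom]], st, ends)
        off <- pos - st + 1L
        substr(sq, off, off) <- rep(s$var, n_art)
        reads <- bind_rows(reads, tibble(
          chrom = u$chrom, start = st, end = ends, read_length = rl,
          strand = u$strand, seq = sq, mismatch_count = 1L))
      }
    }

    # realize the planted (true) editing sites
    for (j in seq_len(nrow(edit_truth))) {
      et <- edit_truth[j, ]
      if (et$artifact) next
      reads <- apply_edit(reads, et$chrom, et$pos, et$strand, et$var, et$freq)
    }
    alignments[[lib$library_id]] <- finalize_reads(reads, lib$library_id, genome)
  }

  libraries <- library_set(
    library_id = libs$library_id, role = libs$role, replicate = libs$replicate,
    assay = libs$assay,
    total_mapped_reads = vapply(alignments[libs$library_id], nrow, integer(1)))

  # ---- write everything ------------------------------------------------
  paths <- list(
    genome = file.path(dir, "genome.fasta"),
    annotation = file.path(dir, "annotation.gff3"),
    sam = setNames(file.path(dir, paste0(libs$library_id, ".sam")),
                   libs$library_id))
  write_reference(genome, features, paths$genome, paths$annotation)
  for (id in libs$library_id) write_sam(alignments[[id]], genome, paths$sam[[id]])

  truth <- list(
    units = unit_tbl,
    genes = unit_tbl[unit_tbl$kind == "gene", ],
    igs_regions = unit_tbl[unit_tbl$kind %in% c("igs", "repeat"), ],
    inserts = unit_tbl[unit_tbl$kind %in% c("plastid_insert", "nuclear_insert"), ],
    edit_sites = edit_truth,
    orf = orf_truth,
    smallrna_stacks = stacks,
    smears = smears,
    repeat_pairs = repeat_pairs,
    collapse_gene = if (spec$n_genes >= 2L) {
      g2 <- urow("gene02")
      tibble(gene_id = "gene02", strand = g2$strand,
             breakpoint = if (g2$strand == "+") g2$start + (g2$len * 6L) %/% 10L
                          else g2$end - (g2$len * 6L) %/% 10L)
    } else {
      tibble(gene_id = character(), strand = character(), breakpoint = integer())
    })
  for (nm in names(truth)) {
    p <- file.path(dir, paste0("truth_", nm, ".tsv"))
    readr::write_tsv(truth[[nm]], p)
    paths[[paste0("truth_", nm)]] <- p
  }
  paths$config <- file.path(dir, "simulation_spec.txt")
  writeLines(sprintf("%s\t%s", names(spec),
                     vapply(spec, function(x) paste(x, collapse = ","), character(1))),
             paths$config)

  structure(list(genome = genome, features = features, libraries = libraries,
                 alignments = alignments, paths = paths, truth = truth,
                 spec = spec, dir = dir),
            class = "mito_sim")
}

#' Generate the small-RNA assay libraries for a synthetic study
#'
#' Realizes the small-RNA truth of a [generate_dataset()] study: discrete
#' stacks (reads sharing an exact start and length, the signature of a
#' functional small RNA) at quiet intergenic loci, degradation smears
#' (scattered, overlapping reads) over every expressed unit in proportion
#' to its mRNA expression, plus deliberate rule-breakers: out-of-range
#' read lengths, imperfect matches, and reads antisense to a gene.
#' Deterministic given the study seed.
#'
#' @param sim A `mito_sim` object from [generate_dataset()].
#' @return The `mito_sim` with small-RNA libraries appended to
#'   `alignments`, `libraries` and `paths$sam`.
#' @export
generate_smallrna_assay <- function(sim) {
  spec <- sim$spec
  set.seed(spec$seed + 1000003L)
  genome <- sim$genome
  lens <- genome_lengths(genome)
  stacks <- sim$truth$smallrna_stacks
  if (any(stacks$length < 17L | stacks$length > 25L)) {
    abort("planted stack length outside 17-25 nt")
  }
  smears <- sim$truth$smears
  att <- spec$tc_attenuation
  srna_libs <- tibble(
    library_id = c("mito1_srna", "mito2_srna", "tc1_srna", "tc2_srna"),
    role = c("mito_enriched", "mito_enriched", "total_cellular", "total_cellular"),
    replicate = c(1L, 2L, 1L, 2L),
    assay = "smallrna")
  count_cols <- c("n_mito1", "n_mito2", "n_tc1", "n_tc2")

  alignments <- list()
  for (k in seq_len(nrow(srna_libs))) {
    lib <- srna_libs[k, ]
    reads <- list()
    # stacks: identical coordinates, perfect match
    for (j in seq_len(nrow(stacks))) {
      s <- stacks[j, ]
      n <- s[[count_cols[k]]]
      if (n <= 0) next
      reads[[length(reads) + 1L]] <- tibble(
        chrom = s$chrom, start = rep(s$start, n), end = rep(s$end, n),
        read_length = s$length, strand = s$strand, mismatch_count = 0L)
    }
    # degradation smears: scattered starts, lengths across 17-25 nt
    smear_scale <- if (lib$role == "mito_enriched") 1 else att
    for (j in seq_len(nrow(smears))) {
      sm <- smears[j, ]
      n <- round(sm$n_mito * smear_scale * runif(1, 0.9, 1.1))
      if (n <= 0) next
      wid <- sample(seq(spec$smallrna_length_range[1],
                        spec$smallrna_length_range[2]), n, replace = TRUE)
      st <- sm$start + sample.int(sm$end - sm$start - 25L, n, replace = TRUE) - 1L
      reads[[length(reads) + 1L]] <- tibble(
        chrom = sm$chrom, start = st, end = st + wid - 1L,
        read_length = wid, strand = sm$strand, mismatch_count = 0L)
    }
    # rule-breakers, mito libraries only (they are what gets screened)
    if (lib$role == "mito_enriched") {
      ch1 <- names(genome)[1]
      junk_w <- rep(c(16L, 26L), each = 15L)
      st <- sample.int(lens[[ch1]] - 30L, length(junk_w), replace = TRUE)
      reads[[length(reads) + 1L]] <- tibble(
        chrom = ch1, start = st, end = st + junk_w - 1L, read_length = junk_w,
        strand = "+", mismatch_count = 0L)
      # imperfect matches over igs1
      u <- sim$truth$units[sim$truth$units$id == "igs1", ]
      st <- u$start + sample.int(u$len - 20L, 30L, replace = TRUE) - 1L
      reads[[length(reads) + 1L]] <- tibble(
        chrom = u$chrom, start = st, end = st + 19L, read_length = 20L,
        strand = "+", mismatch_count = 1L)
      # antisense to gene03 (retained by the coding-strand rule)
      g <- sim$truth$units[sim$truth$units$id == "gene03", ]
      anti <- if (g$strand == "+") "-" else "+"
      st <- g$start + sample.int(g$len - 25L, 40L, replace = TRUE) - 1L
      wid <- sample(17:25, 40L, replace = TRUE)
      reads[[length(reads) + 1L]] <- tibble(
        chrom = g$chrom, start = st, end = st + wid - 1L, read_length = wid,
        strand = anti, mismatch_count = 0L)
    }
    reads <- bind_rows(reads) |> arrange(.data$chrom, .data$start)
    reads$seq <- unlist(lapply(split(reads, reads$chrom), function(g) {
      substring(genome[[g$chrom[1]]], g$start, g$end)
    }), use.names = FALSE)
    # realize the single-mismatch reads by flipping a mid-read base
    mm <- which(reads$mismatch_count > 0L)
    if (length(mm)) {
      sq <- reads$seq[mm]
      mid <- pmax(2L, reads$read_length[mm] %/% 2L)
      old <- substr(sq, mid, mid)
      flip <- c(A = "G", C = "A", G = "T", T = "C")[old]
      substr(sq, mid, mid) <- unname(flip)
      reads$seq[mm] <- sq
    }
    alignments[[lib$library_id]] <- finalize_reads(reads, lib$library_id, genome)
  }

  srna_set <- library_set(
    library_id = srna_libs$library_id, role = srna_libs$role,
    replicate = srna_libs$replicate, assay = srna_libs$assay,
    total_mapped_reads = vapply(alignments[srna_libs$library_id], nrow, integer(1)))
  sim$libraries <- bind_rows(sim$libraries, srna_set)
  sim$alignments <- c(sim$alignments, alignments)
  for (id in srna_libs$library_id) {
    p <- file.path(sim$dir, paste0(id, ".sam"))
    write_sam(alignments[[id]], genome, p)
    sim$paths$sam[[id]] <- p
  }
  sim
}

#' Generate a complete synthetic study (mRNA + small-RNA assays)
#'
#' Convenience wrapper: [generate_dataset()] followed by
#' [generate_smallrna_assay()].
#'
#' @inheritParams generate_dataset
#' @return A `mito_sim` object with all eight libraries.
#' @export
generate_study <- function(spec = simulation_spec(), dir = tempfile("mitosim")) {
  generate_smallrna_assay(generate_dataset(spec, dir))
}

#' @export
print.mito_sim <- function(x, ...) {
  cat("<mito_sim> synthetic mitochondrial transcriptome study\n")
  cat("  chromosomes:", length(x$genome),
      sprintf("(%s nt total)", format(sum(genome_lengths(x$genome)), big.mark = ",")), "\n")
  cat("  features:", nrow(x$features), " libraries:", nrow(x$libraries), "\n")
  cat("  planted edit sites:", nrow(x$truth$edit_sites),
      " stacks:", nrow(x$truth$smallrna_stacks), "\n")
  invisible(x)
}
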