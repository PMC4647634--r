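test_that("pileup: single read, disagreement, and brute-force oracle", {
  g <- tiny_genome(81, c(c1 = 500L))
  one <- make_reads(g, "c1", 100L, 30L, "+")
  pu <- build_pileup(one, g)
  expect_equal(nrow(pu), 30L)
  expect_true(all(pu$depth == 1L))
  # every column matches the reference base
  base_counts <- as.matrix(pu[, c("A", "C", "G", "T")])
  expect_true(all(base_counts[cbind(1:30, match(pu$ref, c("A", "C", "G", "T")))] == 1L))

  # two overlapping reads disagreeing at one position
  two <- make_reads(g, "c1", c(100L, 110L), 30L, "+")
  p <- 115L
  off <- p - two$start[2] + 1L
  ref_base <- substring(g[["c1"]], p, p)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  substr(two$seq[2], off, off) <- alt
  two$mismatch_count[2] <- 1L
  pu2 <- build_pileup(two, g)
  col <- pu2[pu2$pos == p, ]
  expect_equal(col$depth, 2L)
  expect_equal(col[[ref_base]], 1L)
  expect_equal(col[[alt]], 1L)

  # random alignments against the per-column counting oracle
  withr::with_seed(82, {
    reads <- make_reads(g, "c1", sample(400L, 120L, TRUE),
                        sample(20:40, 120L, TRUE),
                        sample(c("+", "-"), 120L, TRUE))
    # sprinkle mismatches
    for (i in sample(120L, 30L)) {
      k <- sample(reads$read_length[i], 1L)
      substr(reads$seq[i], k, k) <- sample(c("A", "C", "G", "T"), 1L)
    }
  })
  got <- build_pileup(reads, g)
  want <- oracle_pileup(reads, g)
  long <- tidyr::pivot_longer(got[, c("chrom", "pos", "strand", "A", "C", "G", "T")],
                              cols = c("A", "C", "G", "T"),
                              names_to = "base", values_to = "n")
  long <- dplyr::arrange(long[long$n > 0L, ], chrom, pos, strand, base)
  expect_equal(as.data.frame(long), as.data.frame(want))
})

test_that("end-region tagging follows the read 3' end on both strands", {
  g <- tiny_genome(83, c(c1 = 500L))
  reads <- make_reads(g, "c1", c(100L, 100L), 20L, c("+", "-"))
  pu <- build_pileup(reads, g, trim_margin = 5L)
  plus <- pu[pu$strand == "+", ]
  minus <- pu[pu$strand == "-", ]
  end_total <- function(x) x$end_A + x$end_C + x$end_G + x$end_T
  # plus-strand 3' end is the rightmost 5 positions
  expect_equal(plus$pos[end_total(plus) == 1L], 115:119)
  # minus-strand 3' end is the leftmost 5 positions
  expect_equal(minus$pos[end_total(minus) == 1L], 100:104)
})

test_that("calling thresholds are inclusive at 100x depth and 20 percent", {
  mk_pileup <- function(depth, var_count, ref = "C", var = "T") {
    counts <- setNames(rep(0L, 4), c("A", "C", "G", "T"))
    counts[ref] <- depth - var_count
    counts[var] <- var_count
    structure(tibble::tibble(
      chrom = "c1", pos = 50L, strand = "+", ref = ref,
      A = counts[["A"]], C = counts[["C"]], G = counts[["G"]], T = counts[["T"]],
      end_A = 0L, end_C = 0L, end_G = 0L, end_T = 0L,
      depth = as.integer(depth)), class = c("pileup", "tbl_df", "tbl", "data.frame"))
  }
  expect_equal(nrow(call_edit_sites(mk_pileup(99L, 50L), 100L, 0.2)), 0L)
  expect_equal(nrow(call_edit_sites(mk_pileup(100L, 50L), 100L, 0.2)), 1L)
  expect_equal(nrow(call_edit_sites(mk_pileup(1000L, 190L), 100L, 0.2)), 0L)
  called <- call_edit_sites(mk_pileup(1000L, 200L), 100L, 0.2)
  expect_equal(nrow(called), 1L)
  expect_equal(called$freq, 0.2)
  expect_equal(called$editing_type, "canonical_CtoU")
  # G->A on the minus strand is canonical; on the plus strand it is not
  gplus <- mk_pileup(500L, 250L, ref = "G", var = "A")
  expect_equal(call_edit_sites(gplus, 100L, 0.2)$editing_type, "noncanonical")
  gminus <- gplus
  gminus$strand <- "-"
  expect_equal(call_edit_sites(gminus, 100L, 0.2)$editing_type, "canonical_CtoU")
})

test_that("codon-aware classification is forced by the genetic code", {
  # plus-strand CDS starting CCA...: genomic C->T at codon position 1
  # turns CCA (Pro) into TCA (Ser)
  cds_seq <- paste0("ATG", "CCA", "GGG", "TAA")
  g <- c(c1 = paste0(strrep("T", 50), cds_seq, strrep("T", 50)))
  feats <- tibble::tibble(
    feature_id = c("g1", "g1_cds"), chrom = "c1", start = 51L, end = 62L,
    strand = "+", type = c("gene", "CDS"), parent = c(NA, "g1"))
  site <- tibble::tibble(chrom = "c1", pos = 54L, strand = "+", ref = "C",
                         var = "T", depth = 500L, var_count = 250L, freq = 0.5,
                         editing_type = "canonical_CtoU",
                         strand_ambiguous = FALSE)
  got <- classify_edit_sites(site, g, feats)
  expect_equal(got$category, "coding_nonsynonymous")
  expect_equal(got$codon_ref, "CCA")
  expect_equal(got$codon_alt, "TCA")
  expect_equal(got$aa_ref, "P")
  expect_equal(got$aa_alt, "S")

  # minus-strand CDS with codon TAC: genomic G->A at codon position 3
  # gives TAC -> TAT on the transcript (Tyr -> Tyr, synonymous)
  cds_m <- paste0("ATG", "TAC", "GGG", "TAA")
  g2 <- c(c1 = paste0(strrep("T", 50), revcomp(cds_m), strrep("T", 50)))
  feats2 <- tibble::tibble(
    feature_id = c("g2", "g2_cds"), chrom = "c1", start = 51L, end = 62L,
    strand = "-", type = c("gene", "CDS"), parent = c(NA, "g2"))
  # transcript offset of the codon-3 base: position 6 -> genomic end-6+1
  pos_g <- 62L - 6L + 1L
  site2 <- tibble::tibble(chrom = "c1", pos = pos_g, strand = "-", ref = "G",
                          var = "A", depth = 500L, var_count = 250L, freq = 0.5,
                          editing_type = "canonical_CtoU",
                          strand_ambiguous = FALSE)
  got2 <- classify_edit_sites(site2, g2, feats2)
  expect_equal(got2$category, "coding_synonymous")
  expect_equal(got2$codon_ref, "TAC")
  expect_equal(got2$codon_alt, "TAT")

  # stop-gain counts as nonsynonymous: CAA -> TAA at codon position 1
  cds3 <- paste0("ATG", "CAA", "GGG", "TAA")
  g3 <- c(c1 = paste0(strrep("T", 50), cds3, strrep("T", 50)))
  feats3 <- tibble::tibble(
    feature_id = c("g3", "g3_cds"), chrom = "c1", start = 51L, end = 62L,
    strand = "+", type = c("gene", "CDS"), parent = c(NA, "g3"))
  site3 <- site
  got3 <- classify_edit_sites(site3, g3, feats3)
  expect_equal(got3$category, "coding_nonsynonymous")
  expect_equal(got3$aa_alt, "*")
})

test_that("synonymous labels agree with exhaustive codon-table lookup", {
  # every codon with a C, each possible C->T position: label must match a
  # direct genetic-code comparison
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  for (cod in codons) {
    for (k in 1:3) {
      if (substr(cod, k, k) != "C") next
      alt <- cod
      substr(alt, k, k) <- "T"
      cds_seq <- paste0("ATG", cod, "TAA")
      g <- c(c1 = paste0(strrep("A", 30), cds_seq, strrep("A", 30)))
      feats <- tibble::tibble(
        feature_id = c("g", "g_cds"), chrom = "c1", start = 31L, end = 39L,
        strand = "+", type = c("gene", "CDS"), parent = c(NA, "g"))
      site <- tibble::tibble(chrom = "c1", pos = 33L + k, strand = "+",
                             ref = "C", var = "T", depth = 500L,
                             var_count = 250L, freq = 0.5,
                             editing_type = "canonical_CtoU",
                             strand_ambiguous = FALSE)
      got <- classify_edit_sites(site, g, feats)
      want <- if (Biostrings::GENETIC_CODE[[cod]] == Biostrings::GENETIC_CODE[[alt]]) {
        "coding_synonymous"
      } else {
        "coding_nonsynonymous"
      }
      expect_equal(got$category, want, info = paste(cod, k))
    }
  }
})

test_that("intron sites near exon boundaries are excluded; interior kept", {
  g <- tiny_genome(84, c(c1 = 2000L))
  feats <- tibble::tibble(
    feature_id = c("g1", "e1", "e2"),
    chrom = "c1", start = c(100L, 100L, 701L), end = c(1000L, 400L, 1000L),
    strand = "+", type = c("gene", "exon", "exon"),
    parent = c(NA, "g1", "g1"))
  # intron spans 401-700; distances from the boundary: 19, 20, 21 nt
  mk_site <- function(pos) {
    tibble::tibble(chrom = "c1", pos = pos, strand = "+", ref = "C", var = "T",
                   depth = 300L, var_count = 150L, freq = 0.5,
                   editing_type = "canonical_CtoU", strand_ambiguous = FALSE)
  }
  s19 <- classify_edit_sites(mk_site(419L), g, feats)     # 19 nt in
  s20 <- classify_edit_sites(mk_site(420L), g, feats)     # 20 nt in
  s21 <- classify_edit_sites(mk_site(421L), g, feats)     # 21 nt in
  expect_equal(nrow(s19), 0L)
  expect_equal(nrow(s20), 0L)
  expect_equal(nrow(s21), 1L)
  expect_equal(s21$category, "intron")
  expect_equal(nrow(attr(s19, "excluded_introns")), 1L)
  # the same distances from the downstream boundary
  expect_equal(nrow(classify_edit_sites(mk_site(681L), g, feats)), 0L)
  expect_equal(classify_edit_sites(mk_site(680L), g, feats)$category, "intron")
})

test_that("UTR/IGS split respects the 2-kb cutoff from coding sequence", {
  g <- tiny_genome(85, c(c1 = 10000L))
  feats <- tibble::tibble(
    feature_id = c("g1", "g1_cds"), chrom = "c1", start = 3000L, end = 3999L,
    strand = "+", type = c("gene", "CDS"), parent = c(NA, "g1"))
  mk_site <- function(pos) {
    tibble::tibble(chrom = "c1", pos = pos, strand = "+", ref = "C", var = "T",
                   depth = 300L, var_count = 150L, freq = 0.5,
                   editing_type = "canonical_CtoU", strand_ambiguous = FALSE)
  }
  expect_equal(classify_edit_sites(mk_site(2000L), g, feats)$category, "UTR")
  expect_equal(classify_edit_sites(mk_site(5999L), g, feats)$category, "UTR")
  expect_equal(classify_edit_sites(mk_site(6001L), g, feats)$category, "IGS")
  expect_equal(classify_edit_sites(mk_site(900L), g, feats)$category, "IGS")
})

test_that("end-trim recheck flags end-supported sites and keeps mid-read ones", {
  g <- tiny_genome(86, c(c1 = 2000L))
  p <- 500L
  substr(g[["c1"]], p, p) <- "A"
  # 150 reads whose final 3 nt cover the site, all mismatching there
  ends <- p + rep(0:2, length.out = 150L)
  art <- make_reads(g, "c1", ends - 30L + 1L, 30L, "+")
  off <- p - art$start + 1L
  sq <- art$seq
  substr(sq, off, off) <- rep("G", nrow(art))
  art$seq <- sq
  art$mismatch_count <- 1L
  # background coverage without the mismatch
  bg <- make_reads(g, "c1", rep(seq(p - 60L, p - 11L, by = 7L), each = 7L),
                   30L, "+")
  aln <- dplyr::bind_rows(art, bg)
  pu <- build_pileup(aln, g, trim_margin = 5L)
  sites <- call_edit_sites(pu, 100L, 0.2)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$var, "G")
  checked <- end_trim_recheck(aln, g, sites, 5L, 100L, 0.2)
  expect_true(checked$artifact)

  # a mid-read-supported site at 0.5 frequency survives the recheck
  g2 <- tiny_genome(87, c(c1 = 2000L))
  substr(g2[["c1"]], p, p) <- "C"
  reads <- make_reads(g2, "c1", rep(seq(p - 80L, p - 20L, by = 1L), 4L), 100L, "+")
  withr::with_seed(88, {
    hit <- sample(nrow(reads), nrow(reads) %/% 2L)
  })
  sq2 <- reads$seq
  off2 <- p - reads$start + 1L
  substr(sq2[hit], off2[hit], off2[hit]) <- rep("T", length(hit))
  reads$seq <- sq2
  pu2 <- build_pileup(reads, g2, trim_margin = 5L)
  sites2 <- call_edit_sites(pu2, 100L, 0.2)
  expect_equal(nrow(sites2), 1L)
  checked2 <- end_trim_recheck(reads, g2, sites2, 5L, 100L, 0.2)
  expect_false(checked2$artifact)
})

test_that("repeat deduplication collapses homologous sites", {
  sites <- tibble::tibble(
    chrom = c("c1", "c2", "c1"),
    pos = c(700L, 1700L, 900L),
    strand = "+", ref = "C", var = "T",
    depth = 400L, var_count = 200L, freq = c(0.5, 0.52, 0.3),
    editing_type = "canonical_CtoU", strand_ambiguous = FALSE,
    category = "IGS")
  pairs <- tibble::tibble(pair_id = "p1", chrom_a = "c1", start_a = 501L,
                          end_a = 1500L, chrom_b = "c2", start_b = 1501L,
                          end_b = 2500L)
  got <- dedupe_edit_sites(sites, pairs)
  expect_equal(sum(!is.na(got$duplicate_group)), 2L)
  expect_equal(sum(got$is_representative), 2L)
  # unequal pair lengths are fatal
  bad <- pairs
  bad$end_b <- 2400L
  expect_error(dedupe_edit_sites(sites, bad), "unequal")
  # a different base change at the homologous offset does not collapse
  sites2 <- sites
  sites2$var[2] <- "G"
  sites2$editing_type[2] <- "noncanonical"
  got2 <- dedupe_edit_sites(sites2, pairs)
  expect_true(all(is.na(got2$duplicate_group)))
})

test_that("category summaries aggregate exactly (brute-force cross-check)", {
  withr::with_seed(91, {
    n <- 60L
    cats <- sample(c("coding_synonymous", "coding_nonsynonymous", "pseudogene",
                     "intron", "UTR", "IGS"), n, replace = TRUE)
    freq <- round(runif(n, 0.2, 1), 3)
    dup <- rep(NA_character_, n)
    dup[1:6] <- rep(c("dupA", "dupB", "dupC"), each = 2L)
    cats[1:6] <- rep(c("IGS", "intron", "pseudogene"), each = 2L)
    rep_flag <- rep(TRUE, n)
    rep_flag[c(2L, 4L, 6L)] <- FALSE
  })
  sites <- tibble::tibble(
    chrom = "c1", pos = seq_len(n), strand = "+", ref = "C", var = "T",
    depth = 300L, var_count = 150L, freq = freq,
    editing_type = "canonical_CtoU", strand_ambiguous = FALSE,
    category = cats, artifact = FALSE, duplicate_group = dup,
    is_representative = rep_flag)
  got <- summarize_editing(sites)
  # brute force per category
  for (cat in c("pseudogene", "intron", "UTR", "IGS")) {
    idx <- cats == cat
    expect_equal(got$n_sites[got$category == cat], sum(idx), info = cat)
    n_dup_extra <- sum(idx & !rep_flag)
    expect_equal(got$n_unique[got$category == cat], sum(idx) - n_dup_extra,
                 info = cat)
  }
  tot <- got[got$category == "total", ]
  expect_equal(tot$n_sites, n)
  expect_equal(tot$n_unique, n - 3L)
  pc <- got[got$category == "protein_coding", ]
  expect_equal(pc$n_sites,
               sum(cats %in% c("coding_synonymous", "coding_nonsynonymous")))
  # column sums: subcategories add up to the totals row
  sub <- got[!got$category %in% c("protein_coding", "total"), ]
  expect_equal(sum(sub$n_sites), tot$n_sites)
  expect_equal(sum(sub$n_unique), tot$n_unique)
  # artifacts and noncanonical sites never enter the summary
  sites2 <- sites
  sites2$artifact[1] <- TRUE
  sites2$editing_type[10] <- "noncanonical"
  got2 <- summarize_editing(sites2)
  expect_equal(got2$n_sites[got2$category == "total"], n - 2L)
})

test_that("planted editing truth is recovered end to end", {
  sim <- default_sim()
  ed <- default_editing()
  sites <- ed$sites
  truth <- sim$truth$edit_sites

  # every plantable site (freq >= 0.3, not boundary-excluded) is called
  callable <- truth[!truth$artifact & !truth$boundary_excluded &
                      truth$freq >= 0.3, ]
  for (i in seq_len(nrow(callable))) {
    tr <- callable[i, ]
    hit <- sites[sites$chrom == tr$chrom & sites$pos == tr$pos, ]
    expect_equal(nrow(hit), 1L, info = paste(tr$chrom, tr$pos))
    expect_equal(hit$strand, tr$strand)
    expect_equal(hit$ref, tr$ref)
    expect_equal(hit$var, tr$var)
    expect_false(hit$artifact)
    expect_equal(hit$editing_type,
                 ifelse(tr$canonical, "canonical_CtoU", "noncanonical"))
    expect_equal(hit$category, tr$category, info = paste(tr$chrom, tr$pos))
    tol <- 4 * sqrt(tr$freq * (1 - tr$freq) / hit$depth)
    expect_lt(abs(hit$freq - tr$freq), tol)
  }
  # the sub-threshold site stays uncalled
  low <- truth[!truth$artifact & truth$freq < 0.2, ]
  for (i in seq_len(nrow(low))) {
    expect_equal(nrow(sites[sites$chrom == low$chrom[i] &
                              sites$pos == low$pos[i], ]), 0L)
  }
  # the boundary intron site is excluded from the classified set
  bex <- truth[truth$boundary_excluded, ]
  expect_equal(nrow(sites[sites$chrom == bex$chrom & sites$pos == bex$pos, ]), 0L)

  # artifact sites are called, then flagged by the end-trim recheck
  art <- truth[truth$artifact, ]
  for (i in seq_len(nrow(art))) {
    hit <- sites[sites$chrom == art$chrom[i] & sites$pos == art$pos[i], ]
    expect_equal(nrow(hit), 1L, info = paste("artifact", art$pos[i]))
    expect_true(hit$artifact)
    expect_equal(hit$editing_type, "noncanonical")
  }
  # no canonical site is affected by the recheck
  expect_false(any(sites$artifact[sites$editing_type == "canonical_CtoU"]))

  # repeat-pair duplicates collapse to one unique site
  rep_sites <- truth[!is.na(truth$repeat_group), ]
  hits <- sites[paste(sites$chrom, sites$pos) %in%
                  paste(rep_sites$chrom, rep_sites$pos), ]
  expect_equal(nrow(hits), 2L)
  expect_equal(length(unique(hits$duplicate_group)), 1L)
  expect_false(any(is.na(hits$duplicate_group)))
  expect_equal(sum(hits$is_representative), 1L)

  # no reported intronic site lies within 20 nt of an exon boundary
  intr <- sites[sites$category == "intron", ]
  introns <- derive_introns(sim$features)
  for (i in seq_len(nrow(intr))) {
    it <- introns[introns$chrom == intr$chrom[i] &
                    introns$start <= intr$pos[i] &
                    introns$end >= intr$pos[i], ]
    d <- min(intr$pos[i] - it$start + 1L, it$end - intr$pos[i] + 1L)
    expect_gt(d, 20L)
  }
})

test_that("editing calls are invariant under genome reverse-complement", {
  g <- tiny_genome(95, c(c1 = 1500L))
  p <- 700L
  substr(g[["c1"]], p, p) <- "C"
  reads <- make_reads(g, "c1", rep(seq(p - 80L, p - 20L, by = 1L), 3L), 100L, "+")
  withr::with_seed(96, {
    hit <- sample(nrow(reads), round(nrow(reads) * 0.6))
  })
  sq <- reads$seq
  off <- p - reads$start + 1L
  substr(sq[hit], off[hit], off[hit]) <- rep("T", length(hit))
  reads$seq <- sq
  fwd_sites <- call_edit_sites(build_pileup(reads, g), 100L, 0.2)

  # mirror the experiment: reverse-complement genome and reads
  L <- nchar(g[["c1"]])
  g_rc <- c(c1 = revcomp(g[["c1"]]))
  reads_rc <- reads
  reads_rc$start <- L - reads$end + 1L
  reads_rc$end <- L - reads$start + 1L
  reads_rc$strand <- "-"
  reads_rc$seq <- revcomp(reads$seq)
  rc_sites <- call_edit_sites(build_pileup(reads_rc, g_rc), 100L, 0.2)

  expect_equal(nrow(fwd_sites), 1L)
  expect_equal(nrow(rc_sites), 1L)
  expect_equal(rc_sites$pos, L - fwd_sites$pos + 1L)
  expect_equal(rc_sites$ref, "G")
  expect_equal(rc_sites$var, "A")
  expect_equal(rc_sites$editing_type, fwd_sites$editing_type)
  expect_equal(rc_sites$freq, fwd_sites$freq)
})

test_that("worked-example totals and percentages compute correctly", {
  tot <- editing_totals(protein_coding = 10, pseudogene = 2, intron = 3,
                        utr = 4, igs = 5)
  expect_equal(tot$total_unique, 24)
  expect_equal(tot$noncoding_unique, 14)
  expect_equal(canonical_percent(200, 10), 95)
  expect_equal(count_percent(1, 4), 25)
  expect_error(canonical_percent(0, 0), "positive")
})
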