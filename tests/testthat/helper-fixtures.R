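# shared fixtures: built once per test run, cached in this environment
.fixture_env <- new.env(parent = emptyenv())

# the default synthetic study (all eight libraries), generated once
default_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- generate_study(simulation_spec(seed = 20151114),
                                       dir = file.path(tempdir(), "default_sim"))
  }
  .fixture_env$sim
}

# pooled mito-enriched mRNA pileup + called/classified/rechecked sites
default_editing <- function() {
  if (is.null(.fixture_env$editing)) {
    sim <- default_sim()
    pooled <- dplyr::bind_rows(sim$alignments[c("mito1_mrna", "mito2_mrna")])
    pu <- build_pileup(pooled, sim$genome, trim_margin = 5L)
    sites <- call_edit_sites(pu, 100L, 0.20)
    sites <- classify_edit_sites(sites, sim$genome, sim$features)
    sites <- end_trim_recheck(pooled, sim$genome, sites, 5L, 100L, 0.20)
    sites <- dedupe_edit_sites(sites, sim$truth$repeat_pairs)
    .fixture_env$editing <- list(pileup = pu, sites = sites, pooled = pooled)
  }
  .fixture_env$editing
}

# a small deterministic genome for unit-scale tests
tiny_genome <- function(seed = 1, lens = c(chrA = 3000L, chrB = 2000L)) {
  withr::with_seed(seed, {
    vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
  })
}

# hand-built alignment tibble with reference-matching sequences
make_reads <- function(genome, chrom, start, read_length, strand,
                       library_id = "libA", mismatch_count = 0L, seq = NULL) {
  n <- max(length(chrom), length(start), length(read_length), length(strand))
  chrom <- rep_len(chrom, n); start <- rep_len(as.integer(start), n)
  read_length <- rep_len(as.integer(read_length), n)
  strand <- rep_len(strand, n)
  end <- start + read_length - 1L
  if (is.null(seq)) {
    seq <- vapply(seq_len(n), function(i) {
      substring(genome[[chrom[i]]], start[i], end[i])
    }, character(1))
  }
  tibble::tibble(
    read_id = sprintf("r%04d", seq_len(n)), library_id = library_id,
    chrom = chrom, start = start, end = end, read_length = read_length,
    strand = strand, mismatch_count = rep_len(as.integer(mismatch_count), n),
    cigar = paste0(read_length, "M"), seq = seq)
}

# four-library set with equal totals, for CPM-sensitive unit tests
flat_libraries <- function(total = 1e6, assay = "mrna") {
  library_set(
    library_id = paste0(c("mito1_", "mito2_", "tc1_", "tc2_"), assay),
    role = c("mito_enriched", "mito_enriched",
             "total_cellular", "total_cellular"),
    replicate = c(1L, 2L, 1L, 2L), assay = assay,
    total_mapped_reads = rep(total, 4))
}

# coverage track built directly from depth vectors (bypasses alignments)
manual_track <- function(depth_list, library_id = "libA", assay = "mrna") {
  structure(list(
    depth = depth_list, library_id = library_id, assay = assay,
    chrom_lengths = vapply(depth_list, function(d) length(d$`+`), integer(1))),
    class = "coverage_track")
}
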