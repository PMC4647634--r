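#' Pipeline configuration
#'
#' All numeric thresholds of the analysis in one place. Defaults are the
#' package's standard operating point: 500/250-nt windows for mRNA
#' profiles and 50/25 for small-RNA profiles, a 100x depth floor for
#' expressed regions chosen as the ~5 % upper tail of window depths,
#' 201-nt minimum ORFs more than 2 kb from annotated genes with the top
#' 5 % by depth selected, 17-25-nt small RNAs stacked at >= 50 pooled
#' mitochondrial reads with at most one overlapping neighbor, editing
#' calls at >= 100x depth and >= 20 % variant frequency with a 5-nt
#' read-end recheck, a 20-nt intron-boundary exclusion, a 2-kb UTR/IGS
#' cutoff, 50-nt cross-mapping k-mers and a 2-fold enrichment call.
#'
#' @param mrna_window,mrna_step mRNA window/step (nt).
#' @param smallrna_window,smallrna_step Small-RNA window/step (nt).
#' @param region_depth_floor Expressed-region depth threshold (x).
#' @param tail_fraction Upper-tail fraction defining the data-driven
#'   threshold alternative.
#' @param orf_min_length Minimum ORF length (nt).
#' @param orf_distance Minimum ORF distance from genes (nt).
#' @param orf_top_fraction Fraction of ORFs selected by depth.
#' @param smallrna_min_length,smallrna_max_length Small-RNA length
#'   bounds (nt).
#' @param stack_min_depth Minimum pooled mito count for a stack.
#' @param max_neighbor_overlap Maximum overlapping neighbor reads.
#' @param edit_min_depth,edit_min_freq Editing-call thresholds.
#' @param end_trim Read-end recheck margin (nt).
#' @param intron_edge_exclusion Intron-boundary exclusion (nt).
#' @param utr_margin UTR/IGS distance cutoff (nt).
#' @param crossmap_k Cross-mapping k-mer length (nt).
#' @param enrichment_fold Pooled fold for enrichment classification.
#' @param seed Seed used by any stochastic stage.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(mrna_window = 500L, mrna_step = 250L,
                            smallrna_window = 50L, smallrna_step = 25L,
                            region_depth_floor = 100, tail_fraction = 0.05,
                            orf_min_length = 201L, orf_distance = 2000L,
                            orf_top_fraction = 0.05,
                            smallrna_min_length = 17L, smallrna_max_length = 25L,
                            stack_min_depth = 50L, max_neighbor_overlap = 1L,
                            edit_min_depth = 100L, edit_min_freq = 0.20,
                            end_trim = 5L, intron_edge_exclusion = 20L,
                            utr_margin = 2000L, crossmap_k = 50L,
                            enrichment_fold = 2.0, seed = 1L) {
  cfg <- list(
    mrna_window = as.integer(mrna_window), mrna_step = as.integer(mrna_step),
    smallrna_window = as.integer(smallrna_window),
    smallrna_step = as.integer(smallrna_step),
    region_depth_floor = region_depth_floor, tail_fraction = tail_fraction,
    orf_min_length = as.integer(orf_min_length),
    orf_distance = as.integer(orf_distance),
    orf_top_fraction = orf_top_fraction,
    smallrna_min_length = as.integer(smallrna_min_length),
    smallrna_max_length = as.integer(smallrna_max_length),
    stack_min_depth = as.integer(stack_min_depth),
    max_neighbor_overlap = as.integer(max_neighbor_overlap),
    edit_min_depth = as.integer(edit_min_depth),
    edit_min_freq = edit_min_freq, end_trim = as.integer(end_trim),
    intron_edge_exclusion = as.integer(intron_edge_exclusion),
    utr_margin = as.integer(utr_margin), crossmap_k = as.integer(crossmap_k),
    enrichment_fold = enrichment_fold, seed = as.integer(seed))
  num <- vapply(cfg, is.numeric, logical(1))
  if (any(vapply(cfg[num], function(x) x < 0, logical(1)))) {
    abort("config values must be non-negative")
  }
  if (cfg$tail_fraction <= 0 || cfg$tail_fraction >= 1 ||
        cfg$orf_top_fraction <= 0 || cfg$orf_top_fraction > 1 ||
        cfg$edit_min_freq <= 0 || cfg$edit_min_freq > 1) {
    abort("fractions must lie in (0, 1)")
  }
  structure(cfg, class = "pipeline_config")
}

#' Write/read a pipeline configuration as flat key-value text
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a `pipeline_config` equal to the one written.
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s\t%s", names(config),
                     vapply(config, format, character(1), digits = 15)),
             path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  kv <- readr::read_tsv(path, col_names = c("key", "value"),
                        col_types = "cc", progress = FALSE)
  args <- setNames(as.list(as.numeric(kv$value)), kv$key)
  do.call(pipeline_config, args)
}

#' Run the full transcriptome characterization pipeline
#'
#' Orchestrates every stage on one study: strand-specific coverage and
#' window profiles per library, expressed-region detection with
#' enrichment classification and cross-mapping flags, per-gene RPKM and
#' 3' drop-off diagnostics, the ORF expression screen, the small-RNA
#' stack screen with the small-RNA/mRNA correlation, and the
#' editing-site caller with end-trim recheck, repeat deduplication and
#' the category summary. All tabular outputs are written as TSV (regions
#' also as BED) into `out_dir` with a run manifest.
#'
#' @param config A [pipeline_config()].
#' @param genome_path,annotation_path Reference FASTA and GFF3.
#' @param sam_paths Named character vector of SAM/BAM paths, names =
#'   library ids.
#' @param libraries Library set describing each id in `sam_paths`
#'   (`total_mapped_reads` may be `NA`: it is then set to the number of
#'   mapped records loaded).
#' @param repeat_pairs Optional repeat-pair tibble for editing
#'   deduplication.
#' @param out_dir Output directory.
#' @return Invisibly, a list with every stage's result tibbles.
#' @export
run_pipeline <- function(config, genome_path, annotation_path, sam_paths,
                         libraries, repeat_pairs = NULL,
                         out_dir = tempfile("mito_run")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  ref <- stage("load_reference", load_reference(genome_path, annotation_path))
  genome <- ref$genome
  features <- ref$features

  aln <- list()
  for (id in names(sam_paths)) {
    aln[[id]] <- stage(paste0("load_alignments:", id),
                       load_alignments(sam_paths[[id]], id, genome))
  }
  # fill unknown library totals with loaded record counts
  for (i in seq_len(nrow(libraries))) {
    if (is.na(libraries$total_mapped_reads[i])) {
      libraries$total_mapped_reads[i] <- nrow(aln[[libraries$library_id[i]]])
    }
  }
  mrna <- libraries[libraries$assay == "mrna", ]
  srna <- libraries[libraries$assay == "smallrna", ]
  mito_mrna <- mrna$library_id[mrna$role == "mito_enriched"]
  tc_mrna <- mrna$library_id[mrna$role == "total_cellular"]

  tracks <- lapply(setNames(nm = names(aln)), function(id) {
    assay <- libraries$assay[match(id, libraries$library_id)]
    stage(paste0("compute_depth:", id),
          compute_depth(aln[[id]], genome, id, assay = assay))
  })
  profiles <- lapply(setNames(nm = mrna$library_id), function(id) {
    window_profile(tracks[[id]], config$mrna_window, config$mrna_step,
                   libraries, "combined")
  })

  # pooled mito coverage for region calling and ORF ranking
  mito_avg <- stage("average_profiles", average_profiles(profiles[mito_mrna]))
  regions <- stage("detect_expressed_regions", {
    r <- detect_expressed_regions(mito_avg, config$region_depth_floor,
                                  features, utr_margin_region(config))
    r <- classify_enrichment(r, profiles[mito_mrna], profiles[tc_mrna],
                             config$enrichment_fold)
    flag_cross_mapping(r, genome, features, config$crossmap_k)
  })

  rpkm <- stage("gene_expression_rpkm", {
    genes <- gene_like(features)
    gene_expression_rpkm(genes, bind_rows(aln[mrna$library_id]), libraries)
  })

  mito_pool_track <- stage("pool_mito_tracks", {
    pooled <- bind_rows(aln[mito_mrna])
    pooled$library_id <- "mito_pooled"
    compute_depth(pooled, genome, "mito_pooled")
  })

  dropoff <- stage("cds_coverage_dropoff", {
    cds_feats <- features[features$type == "CDS", , drop = FALSE]
    cds_feats$group <- ifelse(is.na(cds_feats$parent), cds_feats$feature_id,
                              cds_feats$parent)
    # per gene, the 3'-terminal CDS segment in transcription order
    bind_rows(lapply(split(cds_feats, cds_feats$group), function(g) {
      g <- g[order(g$start), ]
      seg <- if (g$strand[1] == "+") g[nrow(g), ] else g[1, ]
      seg$feature_id <- seg$group
      cds_coverage_dropoff(mito_pool_track, seg)
    }))
  })

  orfs <- stage("orf_screen", {
    all_orfs <- find_orfs(genome, config$orf_min_length)
    remote <- filter_remote_orfs(all_orfs, features, config$orf_distance)
    rank_orfs_by_depth(remote, mito_pool_track, config$orf_top_fraction,
                       config$region_depth_floor)
  })

  smallrna <- NULL
  correlation <- NA_real_
  if (nrow(srna)) {
    smallrna <- stage("smallrna_screen", {
      pooled <- bind_rows(aln[srna$library_id])
      filtered <- filter_smallrna_reads(
        pooled, features,
        c(config$smallrna_min_length, config$smallrna_max_length))
      cand <- stack_candidates(filtered, genome, libraries,
                               config$stack_min_depth,
                               config$max_neighbor_overlap)
      flag_mito_overrepresentation(cand, libraries)
    })
    correlation <- stage("smallrna_mrna_correlation", {
      mito_srna <- srna$library_id[srna$role == "mito_enriched"]
      sp <- lapply(srna$library_id[srna$role == "mito_enriched"],
                   function(id) window_profile(tracks[[id]], config$mrna_window,
                                               config$mrna_step, libraries,
                                               "combined"))
      srna_avg <- average_profiles(sp)
      smallrna_mrna_correlation(srna_avg, mito_avg)
    })
  }

  editing <- stage("editing_caller", {
    pooled <- bind_rows(aln[mito_mrna])
    pu <- build_pileup(pooled, genome, trim_margin = config$end_trim)
    sites <- call_edit_sites(pu, config$edit_min_depth, config$edit_min_freq)
    sites <- classify_edit_sites(sites, genome, features, config$utr_margin,
                                 config$intron_edge_exclusion)
    sites <- end_trim_recheck(pooled, genome, sites, config$end_trim,
                              config$edit_min_depth, config$edit_min_freq)
    dedupe_edit_sites(sites, repeat_pairs)
  })
  edit_summary <- summarize_editing(editing)

  # ---- write outputs ---------------------------------------------------
  w <- function(x, name) readr::write_tsv(as_tibble(x), file.path(out_dir, name))
  for (id in names(profiles)) w(profiles[[id]], paste0("profile_", id, ".tsv"))
  w(regions, "expressed_regions.tsv")
  if (nrow(regions)) {
    write_bed(mutate(regions, name = paste0("region_", row_number())),
              file.path(out_dir, "expressed_regions.bed"))
  }
  w(rpkm, "gene_rpkm.tsv")
  w(dropoff, "cds_dropoff.tsv")
  w(orfs, "orf_candidates.tsv")
  if (!is.null(smallrna)) w(smallrna, "smallrna_candidates.tsv")
  write_edit_sites(editing, file.path(out_dir, "edit_sites.tsv"))
  write_edit_sites(editing, file.path(out_dir, "edit_sites.vcf"), "vcf")
  w(edit_summary, "editing_summary.tsv")
  write_config(config, file.path(out_dir, "config_manifest.txt"))
  manifest <- tibble(
    input = c(genome_path, annotation_path, unname(sam_paths)),
    md5 = vapply(c(genome_path, annotation_path, unname(sam_paths)),
                 function(p) unname(tools::md5sum(p)), character(1)))
  w(manifest, "input_manifest.tsv")

  invisible(list(genome = genome, features = features, libraries = libraries,
                 tracks = tracks, profiles = profiles, regions = regions,
                 rpkm = rpkm, dropoff = dropoff, orfs = orfs,
                 smallrna = smallrna, smallrna_mrna_r = correlation,
                 edit_sites = editing, edit_summary = edit_summary,
                 out_dir = out_dir))
}

# the exclusion margin around genes used when flagging regions
utr_margin_region <- function(config) config$utr_margin
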