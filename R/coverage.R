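#' Strand-specific per-base read depth
#'
#' Each alignment increments depth by one at every reference position it
#' covers, on its own strand. Records whose CIGAR contains indels
#' contribute over their reference span (insertions/deletions are not
#' resolved position-by-position); a warning is raised once per call.
#'
#' @param alignments Alignment tibble for a single library.
#' @param genome Named character vector of chromosome sequences.
#' @param library_id Optional library id; defaults to the one found in
#'   `alignments`.
#' @param assay Assay label stored on the track.
#'
#' @return A `coverage_track`: list with `depth[[chrom]][[strand]]`
#'   integer vectors of per-position depth, plus `library_id`, `assay`
#'   and `chrom_lengths`.
#' @export
compute_depth <- function(alignments, genome, library_id = NULL, assay = "mrna") {
  lens <- genome_lengths(genome)
  if (nrow(alignments)) {
    if (length(unique(alignments$library_id)) > 1L) {
      abort("compute_depth expects alignments from a single library")
    }
    oob <- alignments$start < 1L | alignments$end > lens[alignments$chrom]
    if (any(oob)) {
      abort(paste0("alignment '", alignments$read_id[oob][1],
                   "' lies outside its chromosome"))
    }
    if (any(grepl("[IDNSHP]", alignments$cigar %||% ""))) {
      warn("alignments with indel/clip CIGARs: depth uses their reference span only")
    }
  }
  library_id <- library_id %||%
    (if (nrow(alignments)) alignments$library_id[1] else NA_character_)
  depth <- lapply(names(genome), function(ch) {
    L <- lens[[ch]]
    lapply(c(`+` = "+", `-` = "-"), function(strd) {
      a <- alignments[alignments$chrom == ch & alignments$strand == strd, ]
      if (!nrow(a)) return(integer(L))
      cumsum(tabulate(a$start, L) - tabulate(a$end + 1L, L))
    })
  })
  names(depth) <- names(genome)
  structure(list(depth = depth, library_id = library_id, assay = assay,
                 chrom_lengths = lens),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track>", x$library_id, "(", x$assay, ")\n")
  tot <- sum(vapply(x$depth, function(ch) sum(as.numeric(ch$`+`)) +
                      sum(as.numeric(ch$`-`)), numeric(1)))
  cat("  chromosomes:", length(x$depth),
      " total depth mass:", format(tot, big.mark = ","), "\n")
  invisible(x)
}

# strand vectors of one chromosome combined per strand_mode
track_strand_depth <- function(track, chrom, strand_mode) {
  d <- track$depth[[chrom]]
  switch(strand_mode,
         combined = d$`+` + d$`-`,
         forward = d$`+`,
         reverse = d$`-`,
         abort("strand_mode must be combined/forward/reverse"))
}

#' Sliding-window coverage profile
#'
#' Tiles every chromosome with windows starting at 1, 1+step, ...; the
#' final window is truncated at the chromosome end and its mean uses the
#' truncated length. Window means are means of per-position depth
#' (strands summed when `strand_mode = "combined"`); CPM is the window
#' mean scaled by million mapped reads of the library.
#'
#' @param track A `coverage_track` from [compute_depth()].
#' @param window_size,step Window and step sizes in nt
#'   (`window_size >= step >= 1`).
#' @param libraries Library set (for the CPM denominator).
#' @param strand_mode `"combined"`, `"forward"` or `"reverse"`.
#'
#' @return A tibble of class `window_profile` with columns `chrom`,
#'   `start`, `end`, `mean_depth`, `cpm` and attributes `window_size`,
#'   `step`, `strand_mode`, `library_id`.
#' @export
window_profile <- function(track, window_size, step, libraries,
                           strand_mode = c("combined", "forward", "reverse")) {
  strand_mode <- match.arg(strand_mode)
  if (step < 1L || window_size < step) abort("need window_size >= step >= 1")
  total <- library_total(libraries, track$library_id)
  out <- lapply(names(track$depth), function(ch) {
    L <- track$chrom_lengths[[ch]]
    v <- track_strand_depth(track, ch, strand_mode)
    cs <- c(0, cumsum(as.numeric(v)))
    s <- seq.int(1L, L, by = step)
    e <- pmin(s + window_size - 1L, L)
    tibble(chrom = ch, start = s, end = e,
           mean_depth = (cs[e + 1L] - cs[s]) / (e - s + 1L))
  })
  out <- bind_rows(out)
  out$cpm <- out$mean_depth * 1e6 / total
  structure(out, class = c("window_profile", class(out)),
            window_size = as.integer(window_size), step = as.integer(step),
            strand_mode = strand_mode, library_id = track$library_id)
}

#' Average window profiles across libraries
#'
#' Averages per-library CPM (and mean depth) over profiles computed on an
#' identical window grid, e.g. the two mitochondrial-enriched replicates.
#'
#' @param profiles List of `window_profile` tibbles on the same grid.
#' @return A `window_profile` with averaged `mean_depth` and `cpm`.
#' @export
average_profiles <- function(profiles) {
  if (!length(profiles)) abort("no profiles given")
  p0 <- profiles[[1]]
  for (p in profiles[-1]) {
    if (nrow(p) != nrow(p0) || !all(p$chrom == p0$chrom & p$start == p0$start)) {
      abort("profiles are not on an identical window grid")
    }
  }
  out <- p0
  out$mean_depth <- rowMeans(vapply(profiles, function(p) p$mean_depth,
                                    numeric(nrow(p0))))
  out$cpm <- rowMeans(vapply(profiles, function(p) p$cpm, numeric(nrow(p0))))
  attr(out, "library_id") <- paste(
    vapply(profiles, function(p) attr(p, "library_id"), character(1)),
    collapse = "+")
  out
}

#' Empirical tail threshold of a window-depth distribution
#'
#' Returns the depth above which the stated upper-tail fraction of window
#' means lies, using the nearest-rank quantile on the sorted means.
#'
#' @param profile A `window_profile`.
#' @param tail_fraction Upper-tail fraction in (0, 1); 0.05 reproduces a
#'   "~5 % tail" threshold choice.
#' @return A single depth value.
#' @export
tail_threshold <- function(profile, tail_fraction = 0.05) {
  if (!nrow(profile)) abort("empty profile")
  if (tail_fraction <= 0 || tail_fraction >= 1) abort("tail_fraction must be in (0,1)")
  x <- sort(profile$mean_depth)
  x[max(1L, ceiling((1 - tail_fraction) * length(x)))]
}

# gene-like annotation rows used for margins/distances throughout
gene_like <- function(features, types = c("gene", "tRNA", "rRNA", "pseudogene")) {
  features[features$type %in% types, , drop = FALSE]
}

#' Detect expressed regions from a window profile
#'
#' Windows with mean depth strictly above the threshold are kept and
#' merged into maximal regions wherever they overlap or abut (within
#' `merge_gap` nt). Regions within `exclusion_margin` nt of an annotated
#' gene, tRNA, rRNA or pseudogene are flagged `overlaps_annotation`
#' rather than removed.
#'
#' @param profile A `window_profile`.
#' @param threshold Depth threshold (kept windows have mean depth
#'   strictly greater).
#' @param annotation Optional feature tibble for the annotation flag.
#' @param exclusion_margin Margin (nt) around annotated genes, default
#'   2000.
#' @param track Optional `coverage_track`; when given, the region mean
#'   depth is recomputed exactly over the merged footprint (otherwise it
#'   is the mean of member-window means).
#' @param merge_gap Maximum gap (nt) between kept windows that still
#'   merges them; default 0 (overlapping or abutting only).
#'
#' @return Tibble of class `expressed_regions`: `chrom`, `start`, `end`,
#'   `mean_depth`, `mean_cpm`, `n_windows`, `overlaps_annotation`.
#' @export
detect_expressed_regions <- function(profile, threshold, annotation = NULL,
                                     exclusion_margin = 2000L, track = NULL,
                                     merge_gap = 0L) {
  if (threshold < 0) abort("threshold must be >= 0")
  keep <- profile[profile$mean_depth > threshold, , drop = FALSE]
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  mean_depth = numeric(), mean_cpm = numeric(),
                  n_windows = integer(), overlaps_annotation = logical())
  if (!nrow(keep)) {
    return(structure(empty, class = c("expressed_regions", class(empty))))
  }
  strand_mode <- attr(profile, "strand_mode") %||% "combined"
  regions <- keep |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    mutate(new_region = cumsum(
      c(1L, as.integer(.data$start[-1] > head(.data$end, -1) + 1L + merge_gap)))) |>
    group_by(.data$chrom, .data$new_region) |>
    summarise(start = min(.data$start), end = max(.data$end),
              mean_depth = mean(.data$mean_depth), mean_cpm = mean(.data$cpm),
              n_windows = n(), .groups = "drop") |>
    select(-"new_region")
  if (!is.null(track)) {
    for (i in seq_len(nrow(regions))) {
      v <- track_strand_depth(track, regions$chrom[i], strand_mode)
      span <- regions$start[i]:regions$end[i]
      exact <- mean(v[span])
      scale <- if (regions$mean_depth[i] > 0) exact / regions$mean_depth[i] else 1
      regions$mean_depth[i] <- exact
      regions$mean_cpm[i] <- regions$mean_cpm[i] * scale
    }
  }
  regions$overlaps_annotation <- FALSE
  if (!is.null(annotation)) {
    genes <- gene_like(annotation)
    if (nrow(genes)) {
      for (i in seq_len(nrow(regions))) {
        g <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
        regions$overlaps_annotation[i] <- any(
          g$start - exclusion_margin <= regions$end[i] &
            g$end + exclusion_margin >= regions$start[i])
      }
    }
  }
  structure(regions, class = c("expressed_regions", class(regions)))
}

# mean CPM of one region under one profile (windows overlapping the footprint)
region_profile_cpm <- function(region, profile) {
  w <- profile[profile$chrom == region$chrom &
                 profile$start <= region$end & profile$end >= region$start, ]
  if (!nrow(w)) abort("region lies outside the profile's coverage")
  mean(w$cpm)
}

#' Classify regions as mitochondrial- or total-cellular-enriched
#'
#' A region is `mito_enriched` when its mean CPM is higher in the
#' mitochondrial-enriched profile than in the total-cellular profile for
#' every replicate pairing and the pooled fold change reaches
#' `fold_threshold`; `tc_enriched` under the mirrored condition (the
#' signature of transcripts cross-mapped from plastid or nuclear
#' genomes); otherwise `ambiguous`.
#'
#' @param regions `expressed_regions` tibble.
#' @param mito_profiles,tc_profiles Lists of `window_profile`s, one per
#'   replicate, from the two conditions.
#' @param fold_threshold Pooled fold-change requirement, default 2.
#' @return `regions` with an `enrichment` column.
#' @export
classify_enrichment <- function(regions, mito_profiles, tc_profiles,
                                fold_threshold = 2) {
  if (!length(mito_profiles) || !length(tc_profiles)) {
    abort("need at least one profile per condition")
  }
  lab <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    m <- vapply(mito_profiles, function(p) region_profile_cpm(r, p), numeric(1))
    t <- vapply(tc_profiles, function(p) region_profile_cpm(r, p), numeric(1))
    pooled_m <- mean(m); pooled_t <- mean(t)
    lab[i] <- if (all(outer(m, t, `>`)) && pooled_m >= fold_threshold * pooled_t) {
      "mito_enriched"
    } else if (all(outer(t, m, `>`)) && pooled_t >= fold_threshold * pooled_m) {
      "tc_enriched"
    } else {
      "ambiguous"
    }
  }
  regions$enrichment <- lab
  regions
}

#' Per-gene expression in RPKM
#'
#' Counts reads overlapping each feature by at least one base on its
#' coding strand and scales by feature length (kb) and library size
#' (millions of mapped reads).
#'
#' @param features Feature tibble (any rows; typically genes).
#' @param alignments Alignment tibble (one or more libraries).
#' @param libraries Library set supplying `total_mapped_reads`.
#' @return Tibble `feature_id`, `library_id`, `n_reads`, `rpkm`.
#' @export
gene_expression_rpkm <- function(features, alignments, libraries) {
  assert_features(features)
  libs <- unique(alignments$library_id)
  if (!length(libs)) libs <- libraries$library_id
  out <- list()
  for (lib in libs) {
    total <- library_total(libraries, lib)
    a <- alignments[alignments$library_id == lib, ]
    n <- integer(nrow(features))
    for (i in seq_len(nrow(features))) {
      f <- features[i, ]
      n[i] <- sum(a$chrom == f$chrom & a$strand == f$strand &
                    a$start <= f$end & a$end >= f$start)
    }
    len_kb <- (features$end - features$start + 1L) / 1000
    out[[lib]] <- tibble(feature_id = features$feature_id, library_id = lib,
                         n_reads = n, rpkm = n / (len_kb * total / 1e6))
  }
  bind_rows(out)
}

#' Coverage drop-off diagnostics for a coding sequence
#'
#' Compares mean depth over the final `flank` nt of the CDS with the
#' `flank` nt immediately downstream of the stop codon (in transcription
#' direction): a sharp post-stop drop-off is the signature of efficient
#' 3' transcript processing. A scan over interior positions flags
#' mid-CDS coverage collapses (transcripts that die out before the
#' in-frame stop codon).
#'
#' @param track Coverage track (depth is read on the coding strand).
#' @param cds One-row feature tibble (`chrom`, `start`, `end`, `strand`).
#' @param flank Window length in nt, default 100.
#' @param ratio_cutoff Ratio below which a drop counts as sharp, default
#'   0.1.
#' @return One-row tibble: `feature_id`, `mean_depth_cds_tail`,
#'   `mean_depth_after_stop`, `ratio_after_stop`,
#'   `has_sharp_3prime_dropoff`, `internal_min_ratio`,
#'   `internal_min_position` (transcript-relative nt), `has_internal_drop`.
#' @export
cds_coverage_dropoff <- function(track, cds, flank = 100L, ratio_cutoff = 0.1) {
  stopifnot(nrow(cds) == 1L)
  L <- track$chrom_lengths[[cds$chrom]]
  strand_mode <- if (cds$strand == "+") "forward" else "reverse"
  v <- track_strand_depth(track, cds$chrom, strand_mode)
  cds_len <- cds$end - cds$start + 1L
  f <- flank
  if (cds_len < flank) {
    warn("CDS shorter than the flank; statistics use the available length")
    f <- cds_len
  }
  if (cds$strand == "+") {
    tail_span <- (cds$end - f + 1L):cds$end
    after_span <- (cds$end + 1L):min(cds$end + flank, L)
    tx <- v[cds$start:cds$end]
  } else {
    tail_span <- cds$start:(cds$start + f - 1L)
    after_span <- max(1L, cds$start - flank):(cds$start - 1L)
    tx <- rev(v[cds$start:cds$end])
  }
  mean_tail <- mean(v[tail_span])
  mean_after <- mean(v[after_span])
  ratio <- if (mean_tail > 0) mean_after / mean_tail else NA_real_

  # interior scan in transcript orientation
  int_min <- NA_real_
  int_pos <- NA_integer_
  if (cds_len >= 2L * f) {
    cs <- c(0, cumsum(as.numeric(tx)))
    p <- f:(cds_len - f)
    before <- (cs[p + 1L] - cs[p - f + 1L]) / f
    after <- (cs[p + f + 1L] - cs[p + 1L]) / f
    ratios <- ifelse(before > 0, after / before, NA_real_)
    if (any(!is.na(ratios))) {
      j <- which.min(ratios)
      int_min <- ratios[j]
      int_pos <- p[j]
    }
  }
  tibble(
    feature_id = if ("feature_id" %in% names(cds)) cds$feature_id else NA_character_,
    mean_depth_cds_tail = mean_tail,
    mean_depth_after_stop = mean_after,
    ratio_after_stop = ratio,
    has_sharp_3prime_dropoff = !is.na(ratio) && ratio < ratio_cutoff,
    internal_min_ratio = int_min,
    internal_min_position = int_pos,
    has_internal_drop = !is.na(int_min) && int_min < ratio_cutoff)
}

# k-mer set of a sequence (forward orientation)
kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Flag regions whose depth may come from cross-mapping
#'
#' A region is flagged when its sequence shares at least one exact k-mer
#' (either orientation) with an annotated gene located elsewhere in the
#' genome — the situation in which reads from the intact gene map equally
#' well to the region and inflate its apparent expression.
#'
#' @param regions `expressed_regions` tibble.
#' @param genome Named chromosome sequences.
#' @param features Feature tibble; gene, tRNA and rRNA rows are used.
#' @param k Exact-match k-mer length, default 50 (minimum 20).
#' @return `regions` with a logical `cross_map` column.
#' @export
flag_cross_mapping <- function(regions, genome, features, k = 50L) {
  if (k < 20L) abort("k must be >= 20")
  genes <- gene_like(features, types = c("gene", "tRNA", "rRNA"))
  gene_kmers <- lapply(seq_len(nrow(genes)), function(i) {
    s <- genome_subseq(genome, genes$chrom[i], genes$start[i], genes$end[i])
    c(kmer_set(s, k), kmer_set(revcomp(s), k))
  })
  flag <- logical(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    rk <- kmer_set(genome_subseq(genome, r$chrom, r$start, r$end), k)
    if (!length(rk)) next
    for (j in seq_len(nrow(genes))) {
      overlapping <- genes$chrom[j] == r$chrom &&
        genes$start[j] <= r$end && genes$end[j] >= r$start
      if (overlapping) next
      if (any(rk %in% gene_kmers[[j]])) {
        flag[i] <- TRUE
        break
      }
    }
  }
  regions$cross_map <- flag
  regions
}
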