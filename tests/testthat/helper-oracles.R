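# independent brute-force reference implementations used as oracles

# per-position depth by looping over every read and every covered position
oracle_depth <- function(alignments, genome) {
  lens <- vapply(genome, nchar, integer(1))
  out <- lapply(names(genome), function(ch) {
    list(`+` = integer(lens[[ch]]), `-` = integer(lens[[ch]]))
  })
  names(out) <- names(genome)
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    for (p in a$start:a$end) {
      out[[a$chrom]][[a$strand]][p] <- out[[a$chrom]][[a$strand]][p] + 1L
    }
  }
  out
}

# window means by explicit slicing
oracle_window_means <- function(depth_vec, window_size, step) {
  L <- length(depth_vec)
  starts <- seq(1L, L, by = step)
  vapply(starts, function(s) {
    e <- min(s + window_size - 1L, L)
    mean(depth_vec[s:e])
  }, numeric(1))
}

# nearest-rank upper-tail quantile by explicit sorting
oracle_tail_threshold <- function(x, tail_fraction) {
  sort(x)[max(1L, ceiling((1 - tail_fraction) * length(x)))]
}

# six-frame ORF scan working position-by-position, structured differently
# from the package implementation (per-ATG forward walk)
oracle_orfs <- function(seq_one, min_length, mode = "maximal") {
  stops <- c("TAA", "TAG", "TGA")
  hits <- list()
  scan <- function(s, strand, L) {
    n <- nchar(s)
    for (i in seq_len(max(0L, n - 2L))) {
      if (substr(s, i, i + 2L) != "ATG") next
      # walk to the first in-frame stop
      j <- i + 3L
      stop_at <- NA_integer_
      while (j + 2L <= n) {
        if (substr(s, j, j + 2L) %in% stops) {
          stop_at <- j
          break
        }
        j <- j + 3L
      }
      if (is.na(stop_at)) next
      len <- stop_at + 2L - i + 1L
      if (len < min_length) next
      if (mode == "maximal") {
        # reject if an in-frame ATG exists earlier in the same stop-free span
        k <- i - 3L
        maximal <- TRUE
        while (k >= 1L) {
          cod <- substr(s, k, k + 2L)
          if (cod %in% stops) break
          if (cod == "ATG") {
            maximal <- FALSE
            break
          }
          k <- k - 3L
        }
        if (!maximal) next
      }
      if (strand == "+") {
        hits[[length(hits) + 1L]] <<- c(i, stop_at + 2L)
      } else {
        hits[[length(hits) + 1L]] <<- c(L - (stop_at + 2L) + 1L, L - i + 1L)
      }
    }
  }
  L <- nchar(seq_one)
  scan(seq_one, "+", L)
  scan(revcomp(seq_one), "-", L)
  if (!length(hits)) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  m <- do.call(rbind, hits)
  dplyr::arrange(tibble::tibble(start = m[, 1], end = m[, 2]), start, end)
}

# pairwise gap distance between two closed intervals (0 when overlapping
# or adjacent)
oracle_gap <- function(s1, e1, s2, e2) {
  if (e1 < s2) max(0L, s2 - e1 - 1L) else if (e2 < s1) max(0L, s1 - e2 - 1L) else 0L
}

# per-position, per-strand base counts by iterating reads base-by-base
oracle_pileup <- function(alignments, genome) {
  counts <- list()
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    chars <- strsplit(a$seq, "")[[1]]
    for (k in seq_len(a$read_length)) {
      key <- paste(a$chrom, a$start + k - 1L, a$strand, chars[k])
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  if (!length(counts)) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          strand = character(), base = character(),
                          n = integer()))
  }
  parts <- do.call(rbind, strsplit(names(counts), " "))
  dplyr::arrange(
    tibble::tibble(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                   strand = parts[, 3], base = parts[, 4],
                   n = unlist(counts, use.names = FALSE)),
    chrom, pos, strand, base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared k-mer test by full set construction on both orientations
oracle_shares_kmer <- function(s1, s2, k) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) character(0) else substring(s, 1:(n - k + 1L), k:n)
  }
  any(kmers(s1) %in% c(kmers(s2), kmers(revcomp(s2))))
}
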