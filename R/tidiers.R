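#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a coverage track into per-chromosome summaries
#'
#' @param x A `coverage_track`.
#' @param ... Unused.
#' @return Tibble with `chrom`, `strand`, `length`, `mean_depth`,
#'   `max_depth`.
#' @export
tidy.coverage_track <- function(x, ...) {
  bind_rows(lapply(names(x$depth), function(ch) {
    bind_rows(lapply(c("+", "-"), function(strd) {
      v <- x$depth[[ch]][[strd]]
      tibble(chrom = ch, strand = strd, length = length(v),
             mean_depth = mean(v), max_depth = max(v))
    }))
  }))
}

#' One-row summary of a window profile
#'
#' @param x A `window_profile`.
#' @param ... Unused.
#' @return Tibble with window geometry and depth/CPM summaries.
#' @export
glance.window_profile <- function(x, ...) {
  tibble(n_windows = nrow(x),
         window_size = attr(x, "window_size"),
         step = attr(x, "step"),
         strand_mode = attr(x, "strand_mode"),
         library_id = attr(x, "library_id"),
         median_depth = stats::median(x$mean_depth),
         max_depth = max(x$mean_depth),
         max_cpm = max(x$cpm))
}

#' Genome-wide coverage plot of a window profile
#'
#' One panel per chromosome, CPM (log10) against window midpoint, in the
#' style of genome-wide sliding-window transcript-abundance figures.
#'
#' @param object A `window_profile`.
#' @param log10_cpm Plot log10(CPM + pseudocount) when `TRUE` (default).
#' @param pseudocount Added before the log transform.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.window_profile <- function(object, log10_cpm = TRUE,
                                    pseudocount = 0.01, ...) {
  df <- as_tibble(object)
  df$mid <- (df$start + df$end) / 2
  df$y <- if (log10_cpm) log10(df$cpm + pseudocount) else df$cpm
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid / 1000, y = .data$y)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (kb)",
                  y = if (log10_cpm) "log10 CPM" else "CPM",
                  title = attr(object, "library_id")) +
    ggplot2::theme_bw()
}

#' Mean editing frequency per annotation category
#'
#' @param object An `editing_summary`.
#' @param ... Unused.
#' @return A ggplot bar chart of mean unique-site editing frequency with
#'   unique-site counts as labels.
#' @export
autoplot.editing_summary <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!df$category %in% c("protein_coding", "total"), ]
  df$category <- factor(df$category, levels = df$category)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category,
                                   y = 100 * .data$mean_freq_unique)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_unique), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "mean editing frequency (%)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Per-region depth overview plot
#'
#' @param object An `expressed_regions` tibble.
#' @param ... Unused.
#' @return A ggplot object: region mean depth by chromosome, colored by
#'   enrichment label when present.
#' @export
autoplot.expressed_regions <- function(object, ...) {
  df <- as_tibble(object)
  df$mid <- (df$start + df$end) / 2
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid / 1000,
                                        y = .data$mean_depth))
  p <- if ("enrichment" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$enrichment), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "position (kb)", y = "mean depth (x)") +
    ggplot2::theme_bw()
}

#' One-row summary of called editing sites
#'
#' @param x An `edit_sites` tibble.
#' @param ... Unused.
#' @return Tibble with site counts by type and the canonical percentage.
#' @export
glance.edit_sites <- function(x, ...) {
  n <- nrow(x)
  n_canon <- sum(x$editing_type == "canonical_CtoU")
  tibble(n_sites = n,
         n_canonical = n_canon,
         n_noncanonical = n - n_canon,
         canonical_pct = if (n > 0) 100 * n_canon / n else NA_real_,
         n_artifact = if ("artifact" %in% names(x)) sum(x$artifact) else NA_integer_,
         mean_freq = if (n > 0) mean(x$freq) else NA_real_)
}
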