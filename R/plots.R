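# ggplot2 displays for the main result types.

#' Plot contig bins: the GC-vs-depth "blob" view
#'
#' The classic decontamination diagnostic: each contig as a point at its GC
#' fraction and mean depth (log scale), sized by length and coloured by the
#' assigned label.
#'
#' @param object a [classify_contigs()] / [bin_contigs()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.endosieve_bins <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$gc_fraction, y = .data$mean_depth,
                               colour = .data$label, size = .data$length)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "GC fraction", y = "Mean read depth (x, log scale)",
                  colour = "Bin", size = "Length (bp)") +
    ggplot2::theme_minimal()
}

#' Plot an RSCU table as per-family codon usage bars
#'
#' @param object an [rscu()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rscu_table <- function(object, ...) {
  df <- filter(as_tibble(object), !is.na(.data$rscu), .data$family_size > 1L)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$codon, y = .data$rscu)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$amino_acid), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "RSCU") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Dot plot of synteny blocks
#'
#' Draws each block as a segment from its A-span onto its B-span, the usual
#' synteny dot-plot summary; inverted blocks slope downwards.
#'
#' @param object a `synteny_blocks` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.synteny_blocks <- function(object, ...) {
  df <- as_tibble(object)
  df$y_start <- ifelse(df$orientation == "same", df$start_b, df$end_b)
  df$y_end <- ifelse(df$orientation == "same", df$end_b, df$start_b)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start_a, xend = .data$end_a,
                                       y = .data$y_start, yend = .data$y_end,
                                       colour = .data$orientation),
                          linewidth = 1.2) +
    ggplot2::facet_grid(ggplot2::vars(.data$contig_b),
                        ggplot2::vars(.data$contig_a)) +
    ggplot2::labs(x = "Genome A position (bp)", y = "Genome B position (bp)",
                  colour = "Orientation") +
    ggplot2::theme_minimal()
}

#' Histogram of per-gene mean bootstrap supports with the filter threshold
#'
#' @param scores a [filter_genes()] result.
#' @param threshold threshold line to draw (default 70).
#' @return a ggplot object.
#' @export
plot_gene_support <- function(scores, threshold = 70) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$mean_support,
                                       fill = .data$selected)) +
    ggplot2::geom_histogram(binwidth = 2, boundary = 0) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "Mean bootstrap support (%)", y = "Genes",
                  fill = "Selected") +
    ggplot2::theme_minimal()
}
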