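# ggplot2 visualisations for the main result types ---------------------------

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_segment
#'   geom_text facet_grid labs theme_minimal scale_size_area
NULL

#' @export
ggplot2::autoplot

#' RSCU bar chart
#'
#' One bar per codon, grouped by amino-acid family, in the style of published
#' codon-usage figures.
#'
#' @param object A `codon_usage` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot codon_usage
#' @export
autoplot.codon_usage <- function(object, ...) {
  d <- dplyr::arrange(object$codons, .data$aa, .data$codon)
  ggplot(d, aes(x = .data$codon, y = .data$rscu, fill = .data$aa)) +
    geom_col(show.legend = FALSE) +
    facet_grid(~aa, scales = "free_x", space = "free_x") +
    labs(x = NULL, y = "RSCU") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Haplotype network plot
#'
#' Nodes are haplotypes with area proportional to frequency; edges are
#' labelled with the number of mutational steps.
#'
#' @param object A `haplotype_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot haplotype_network
#' @export
autoplot.haplotype_network <- function(object, ...) {
  g <- as_igraph(object)
  xy <- igraph::layout_with_fr(g)
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- dplyr::left_join(object$edges,
                            dplyr::select(nodes, .data$haplotype,
                                          x1 = .data$x, y1 = .data$y),
                            by = c(from = "haplotype"))
  edges <- dplyr::left_join(edges,
                            dplyr::select(nodes, .data$haplotype,
                                          x2 = .data$x, y2 = .data$y),
                            by = c(to = "haplotype"))
  ggplot() +
    geom_segment(data = edges,
                 aes(x = .data$x1, y = .data$y1,
                     xend = .data$x2, yend = .data$y2), colour = "grey50") +
    geom_point(data = nodes,
               aes(x = .data$x, y = .data$y, size = .data$count),
               colour = "steelblue", alpha = 0.8) +
    geom_text(data = nodes,
              aes(x = .data$x, y = .data$y, label = .data$haplotype),
              vjust = -1.2, size = 3) +
    scale_size_area(max_size = 18) +
    labs(x = NULL, y = NULL, size = "frequency") +
    theme_minimal()
}

#' AT/GC content against skew across genomes
#'
#' Scatter of A+T content against AT-skew (and G+C content against GC-skew)
#' for a set of genomes, the standard view for comparing strand asymmetry
#' across taxa.
#'
#' @param stats Tibble with columns `id`, `at_content`, `gc_content`,
#'   `at_skew`, `gc_skew` (one row per genome, e.g. rows of
#'   `composition_report()$genome_stats`).
#' @return A ggplot.
#' @export
plot_skew <- function(stats) {
  d <- dplyr::bind_rows(
    tibble(id = stats$id, skew = stats$at_skew,
           content = stats$at_content, which = "A+T"),
    tibble(id = stats$id, skew = stats$gc_skew,
           content = stats$gc_content, which = "G+C")
  )
  ggplot(d, aes(x = .data$skew, y = .data$content, label = .data$id)) +
    geom_point(colour = "firebrick") +
    geom_text(vjust = -0.8, size = 3) +
    facet_grid(~which) +
    labs(x = "skew", y = "content") +
    theme_minimal()
}

#' Per-copy identity profile of a tandem-repeat array
#'
#' @param array One row of a [find_tandem_repeats()] result.
#' @return A ggplot of copy identity along the array, with incomplete copies
#'   highlighted.
#' @export
plot_repeat_array <- function(array) {
  copies <- array$copies[[1]]
  ggplot(copies, aes(x = .data$copy, y = .data$identity,
                     fill = .data$complete)) +
    geom_col() +
    labs(x = "copy", y = "identity to consensus", fill = "complete") +
    theme_minimal()
}
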