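#' Plot a gene mutation-burden table
#'
#' Horizontal bar chart of the top genes by mutated-sample frequency, the
#' standard view of a catalog summary.
#'
#' @param burdens Burden tibble from [summarize_burden()].
#' @param top_n Number of genes shown (default 20).
#' @return A ggplot object.
#' @export
plot_burden <- function(burdens, top_n = 20) {
  d <- head(arrange(burdens, desc(.data$frequency), .data$gene), top_n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$frequency,
    y = stats::reorder(.data$gene, .data$frequency))) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "samples mutated", y = NULL,
                  title = "Most frequently mutated genes") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_burden `autoplot` dispatch for ranking objects: Q score
#'   versus final rank.
#' @param object,... Ranking object and unused arguments.
#' @export
autoplot.allnet_ranking <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$final_rank,
                                       y = .data$q_score)) +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "final rank", y = "Q score",
                  title = "Order-statistic prioritization") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_burden `autoplot` dispatch for networks: force-directed
#'   layout with node degree mapped to size.
#' @export
autoplot.confident_network <- function(object, ...) {
  g <- as_igraph(object)
  set.seed(42)  # layout only; reproducible figure
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(gene = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
                  degree = igraph::degree(g))
  edges <- object$edges %>%
    left_join(select(nodes, "gene", xa = "x", ya = "y"),
              by = c(protein_a = "gene")) %>%
    left_join(select(nodes, "gene", xb = "x", yb = "y"),
              by = c(protein_b = "gene"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb),
                          color = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$degree),
                        color = "firebrick", alpha = 0.8) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Confident interaction network", size = "degree")
}

#' Plot candidate scores
#'
#' Bar chart of shared-partner counts for candidate genes, passing candidates
#' highlighted.
#'
#' @param candidates Output of [candidate_filter()].
#' @return A ggplot object.
#' @export
plot_candidates <- function(candidates) {
  ggplot2::ggplot(candidates, ggplot2::aes(
    x = stats::reorder(.data$partner, -.data$n_seed_partners),
    y = .data$n_seed_partners, fill = .data$passes)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "purple4",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = NULL, y = "ALL-gene partners", fill = "candidate",
                  title = "Guilt-by-association candidates") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
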