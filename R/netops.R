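canonical_pair <- function(a, b) {
  tibble(protein_a = pmin(a, b), protein_b = pmax(a, b))
}

#' Aggregate PPI evidence rows into undirected interactions
#'
#' Collapses an evidence table (one row per publication/method supporting a
#' pair) into one row per unordered protein pair, with its de-duplicated
#' evidence list nested alongside. Orientation is ignored (`A–B` and `B–A` are
#' the same pair), detection-method strings are trimmed and lower-cased before
#' de-duplication, and self-interactions are dropped with a count reported in
#' attribute `n_self_loops`.
#'
#' @param rows Tibble with columns `protein_a`, `protein_b`, `pubmed_id`,
#'   `method`, one row per evidence item (the shape of IntAct/HPRD/BioGRID
#'   exports).
#' @return A tibble with one row per pair: `protein_a`, `protein_b` (sorted
#'   within pair), `n_publications`, `n_methods`, and list-column `evidence`.
#' @export
aggregate_edges <- function(rows) {
  required <- c("protein_a", "protein_b", "pubmed_id", "method")
  missing_cols <- setdiff(required, names(rows))
  if (length(missing_cols) > 0) {
    abort(paste0("evidence table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "allnet_format_error")
  }
  rows <- as_tibble(rows)
  self <- rows$protein_a == rows$protein_b
  n_self <- sum(self)
  if (n_self > 0) {
    inform(paste0(n_self, " self-interaction row(s) dropped"))
  }
  rows <- rows[!self, ]
  out <- rows %>%
    mutate(canonical_pair(.data$protein_a, .data$protein_b),
           method = tolower(trimws(.data$method))) %>%
    distinct(.data$protein_a, .data$protein_b, .data$pubmed_id,
             .data$method) %>%
    group_by(.data$protein_a, .data$protein_b) %>%
    summarise(n_publications = n_distinct(.data$pubmed_id),
              n_methods = n_distinct(.data$method),
              evidence = list(tibble(pubmed_id = pubmed_id,
                                     method = method)),
              .groups = "drop") %>%
    arrange(.data$protein_a, .data$protein_b)
  attr(out, "n_self_loops") <- n_self
  out
}

new_confident_network <- function(nodes, edges) {
  structure(list(nodes = sort(unique(nodes)),
                 edges = as_tibble(edges)),
            class = "confident_network")
}

#' Keep only confidently supported interactions
#'
#' Applies the literature-curation confidence rule: an interaction is kept
#' when it is supported by at least two distinct publications OR detected by
#' at least two distinct methods. The filter is idempotent, so it can be
#' re-applied to an already-filtered network without change.
#'
#' @param interactions Output of [aggregate_edges()], or an existing
#'   `confident_network`.
#' @return A `confident_network`: a list with `nodes` (character vector) and
#'   `edges` (tibble `protein_a`, `protein_b`, `n_publications`, `n_methods`).
#' @export
confidence_filter <- function(interactions) {
  if (inherits(interactions, "confident_network")) {
    edges <- interactions$edges
    extra_nodes <- interactions$nodes
  } else {
    edges <- select(interactions, "protein_a", "protein_b",
                    "n_publications", "n_methods")
    extra_nodes <- character()
  }
  kept <- filter(edges, .data$n_publications >= 2 | .data$n_methods >= 2)
  new_confident_network(c(extra_nodes, kept$protein_a, kept$protein_b), kept)
}

#' @export
print.confident_network <- function(x, ...) {
  cat("<confident_network> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Induce the subnetwork over a gene set
#'
#' Restricts a confident network to a set of genes: edges survive only when
#' both endpoints are in the set, and genes absent from the network are kept
#' as isolated nodes so that connectivity statistics (how many of the disease
#' genes are interconnected at all) remain computable.
#'
#' @param net A `confident_network`.
#' @param genes Character vector of gene symbols.
#' @return A `confident_network` whose node set is exactly `genes`.
#' @export
induce_subnetwork <- function(net, genes) {
  stopifnot(inherits(net, "confident_network"))
  genes <- unique(as.character(genes))
  kept <- filter(net$edges, .data$protein_a %in% genes,
                 .data$protein_b %in% genes)
  structure(list(nodes = sort(genes), edges = kept),
            class = "confident_network")
}

#' Degree table of a confident network
#'
#' @param net A `confident_network`.
#' @return Tibble `gene`, `degree`, sorted by descending degree then symbol.
#'   Isolated nodes appear with degree 0; the degree sum equals twice the
#'   edge count.
#' @export
degree_table <- function(net) {
  stopifnot(inherits(net, "confident_network"))
  deg <- table(factor(c(net$edges$protein_a, net$edges$protein_b),
                      levels = net$nodes))
  tibble(gene = names(deg), degree = as.integer(deg)) %>%
    arrange(desc(.data$degree), .data$gene)
}

neighbor_sets <- function(net) {
  adj <- c(split(net$edges$protein_b, net$edges$protein_a),
           split(net$edges$protein_a, net$edges$protein_b))
  tapply(unlist(adj, use.names = FALSE),
         rep(names(adj), lengths(adj)),
         unique, simplify = FALSE)
}

#' Find shared partners of a seed gene set
#'
#' Guilt-by-association screening: reports network nodes outside the seed set
#' whose confident interaction partners include at least `min_partners` seed
#' genes (the paper-scale analogue of "proteins interacting with at least 2
#' ALL-gene products").
#'
#' @param net A `confident_network`.
#' @param seed_genes Character vector of seed (disease) gene symbols.
#' @param min_partners Minimum number of seed neighbors (default 2).
#' @return Tibble `partner`, `n_seed_partners`, list-column `seed_neighbors`,
#'   sorted by descending count then symbol.
#' @export
shared_partners <- function(net, seed_genes, min_partners = 2) {
  stopifnot(inherits(net, "confident_network"), min_partners >= 1)
  seed_genes <- unique(as.character(seed_genes))
  nbrs <- neighbor_sets(net)
  candidates <- setdiff(names(nbrs), seed_genes)
  hits <- purrr::map(setNames(candidates, candidates),
                     ~ sort(intersect(nbrs[[.x]], seed_genes)))
  hits <- hits[lengths(hits) >= min_partners]
  tibble(partner = names(hits),
         n_seed_partners = unname(lengths(hits)),
         seed_neighbors = unname(hits)) %>%
    arrange(desc(.data$n_seed_partners), .data$partner)
}

#' Overlay per-sample mutation co-occurrence on a network
#'
#' For each interaction whose two genes are both mutated somewhere in the
#' cohort, counts the samples in which both are mutated together. A pair of
#' interacting genes that are each mutated yet never in the same sample is
#' flagged `exclusive` — the mutually exclusive alteration pattern.
#'
#' @param net A `confident_network`. Co-occurrence is computed on its edges;
#'   set `all_pairs = TRUE` to scan every pair of mutated network genes
#'   instead.
#' @param sample_genes Tibble with columns `sample_id` and `gene` (one row per
#'   mutated gene per sample), or a named list mapping sample id to a gene
#'   vector.
#' @param all_pairs Compute over all gene pairs rather than network edges.
#' @return Tibble `protein_a`, `protein_b`, `n_cooccurring`, `exclusive`,
#'   sorted by descending `n_cooccurring` then pair.
#' @export
cooccurrence_overlay <- function(net, sample_genes, all_pairs = FALSE) {
  stopifnot(inherits(net, "confident_network"))
  if (is.list(sample_genes) && !is.data.frame(sample_genes)) {
    sample_genes <- tibble(
      sample_id = rep(names(sample_genes), lengths(sample_genes)),
      gene = unlist(sample_genes, use.names = FALSE))
  }
  gene_samples <- sample_genes %>%
    distinct(.data$gene, .data$sample_id) %>%
    (\(d) split(d$sample_id, d$gene))()
  pairs <- if (all_pairs) {
    mutated <- intersect(net$nodes, names(gene_samples))
    if (length(mutated) < 2) {
      tibble(protein_a = character(), protein_b = character())
    } else {
      cmb <- utils::combn(sort(mutated), 2)
      tibble(protein_a = cmb[1, ], protein_b = cmb[2, ])
    }
  } else {
    select(net$edges, "protein_a", "protein_b")
  }
  pairs %>%
    filter(.data$protein_a %in% names(gene_samples),
           .data$protein_b %in% names(gene_samples)) %>%
    mutate(n_cooccurring = purrr::map2_int(
      .data$protein_a, .data$protein_b,
      ~ length(intersect(gene_samples[[.x]], gene_samples[[.y]]))),
      exclusive = .data$n_cooccurring == 0L) %>%
    arrange(desc(.data$n_cooccurring), .data$protein_a, .data$protein_b)
}

#' @describeIn tidy-allnet Edge table of a network, one row per confident
#'   interaction.
#' @export
tidy.confident_network <- function(x, ...) x$edges

#' Tidy and summary accessors
#'
#' `tidy()` returns the row-per-record view of an allnet object; `glance()`
#' returns a one-row summary.
#'
#' @param x A `confident_network` or ranking object.
#' @param ... Unused.
#' @name tidy-allnet
NULL

#' @describeIn tidy-allnet One-row network summary: node count, edge count,
#'   number of connected (degree >= 1) nodes.
#' @export
glance.confident_network <- function(x, ...) {
  deg <- degree_table(x)
  tibble(n_nodes = length(x$nodes),
         n_edges = nrow(x$edges),
         n_connected = sum(deg$degree > 0))
}
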