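#' Read a PPI evidence table
#'
#' @param path TSV with header columns `protein_a`, `protein_b`, `pubmed_id`,
#'   `method`, one row per evidence item.
#' @return Evidence tibble.
#' @export
read_evidence <- function(path) {
  rows <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          na = character(), progress = FALSE)
  required <- c("protein_a", "protein_b", "pubmed_id", "method")
  missing_cols <- setdiff(required, names(rows))
  if (length(missing_cols) > 0) {
    abort(paste0("evidence file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "allnet_format_error")
  }
  bad <- which(rows$protein_a == "" | rows$protein_b == "")
  if (length(bad) > 0) {
    abort(paste0("malformed evidence row at line ", bad[1] + 1,
                 ": empty protein symbol"),
          class = "allnet_format_error")
  }
  rows
}

#' Read a binary expression table
#'
#' @param path TSV with a `gene` column and one 0/1 column per cell line.
#' @return Tibble with integer call columns.
#' @export
read_expression <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(gene = "c",
                                                       .default = "i"),
                         progress = FALSE)
  if (!"gene" %in% names(out)) {
    abort("expression file must have a 'gene' column",
          class = "allnet_format_error")
  }
  out
}

#' Export a network as SIF
#'
#' Simple interaction format, one `nodeA pp nodeB` line per edge plus one
#' bare line per isolated node, loadable in Cytoscape.
#'
#' @param net A `confident_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "confident_network"))
  lines <- paste(net$edges$protein_a, "pp", net$edges$protein_b, sep = "\t")
  isolated <- setdiff(net$nodes, c(net$edges$protein_a, net$edges$protein_b))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Read a SIF file back into an edge table
#'
#' @param path SIF file.
#' @return Tibble `protein_a`, `protein_b` (pair-sorted) with attribute
#'   `isolated` listing the bare-node lines.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  is_edge <- lengths(parts) >= 3
  a <- vapply(parts[is_edge], `[[`, "", 1)
  b <- vapply(parts[is_edge], `[[`, "", 3)
  out <- arrange(canonical_pair(a, b), .data$protein_a, .data$protein_b)
  attr(out, "isolated") <- vapply(parts[!is_edge], `[[`, "", 1)
  out
}

as_igraph <- function(net, cooccurrence = NULL) {
  edges <- net$edges
  if (!is.null(cooccurrence)) {
    edges <- left_join(edges,
                       select(cooccurrence, "protein_a", "protein_b",
                              "n_cooccurring", "exclusive"),
                       by = c("protein_a", "protein_b"))
  }
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Export a network as GraphML
#'
#' GraphML with per-edge attributes `n_publications` and `n_methods`, plus
#' `n_cooccurring` and `exclusive` when a co-occurrence overlay is supplied;
#' loadable in Cytoscape. The edge set is identical to the SIF export of the
#' same network.
#'
#' @param net A `confident_network`.
#' @param path Output path.
#' @param cooccurrence Optional output of [cooccurrence_overlay()].
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path, cooccurrence = NULL) {
  stopifnot(inherits(net, "confident_network"))
  igraph::write_graph(as_igraph(net, cooccurrence), path, format = "graphml")
  invisible(path)
}

#' Read a GraphML file back into an edge table
#'
#' @param path GraphML file.
#' @return Tibble `protein_a`, `protein_b` (pair-sorted) plus any edge
#'   attributes.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ends <- igraph::as_edgelist(g)
  out <- canonical_pair(ends[, 1], ends[, 2])
  for (attr_name in igraph::edge_attr_names(g)) {
    out[[attr_name]] <- igraph::edge_attr(g, attr_name)
  }
  arrange(out, .data$protein_a, .data$protein_b)
}

#' Read a YAML run configuration
#'
#' Validates keys against the documented run-configuration schema; unknown
#' keys are rejected so that typos cannot silently disable a threshold.
#'
#' @param path YAML file.
#' @return Named list of settings merged over the documented defaults.
#' @export
read_run_config <- function(path) {
  defaults <- list(
    catalog = NULL, evidence = NULL, expression = NULL, cds = NULL,
    census = NULL, out_dir = ".", disease_filter = NULL, column_map = NULL,
    min_distinct = 1, min_samples = 1, top_k = Inf, burden_key = "n_samples",
    min_partners = 2, min_expression = 0.6,
    criteria = c("n_distinct", "n_samples", "degree"), seed = 1)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown run-config key(s): ",
                 paste(unknown, collapse = ", ")),
          class = "allnet_config_error")
  }
  num <- c("min_distinct", "min_samples", "top_k", "min_partners",
           "min_expression", "seed")
  for (k in intersect(names(cfg), num)) {
    if (!is.numeric(cfg[[k]])) abort(paste0("run-config key '", k,
                                            "' must be numeric"),
                                     class = "allnet_config_error")
  }
  modifyList(defaults, cfg, keep.null = TRUE)
}
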