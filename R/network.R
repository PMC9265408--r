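#' Build the DE-restricted miRNA-TF-gene regulatory network
#'
#' Keeps a catalog edge iff both its regulator and its target are called
#' differentially expressed; nodes are the DE features participating in at
#' least one retained edge. Multiple evidence rows for one
#' (regulator, target) pair collapse into a single edge carrying the sorted,
#' comma-joined evidence set. Edge type follows the regulator class
#' (`tf-target` / `mirna-target`). A symbol classed as both gene and TF is
#' treated as a TF.
#'
#' @param de A tibble with columns `feature`, `class`, `status` (from
#'   [diff_expression()] / [tidy()]), or an `ffl_de` object.
#' @param catalog An [interaction_catalog()].
#' @return A `regnet` object: list with tibbles `nodes` (`node`, `class`,
#'   `direction`, `M` if available) and `edges` (`regulator`, `target`,
#'   `edge_type`, `evidence`).
#' @export
build_network <- function(de, catalog) {
  if (inherits(de, "ffl_de")) de <- de$table
  de_feats <- filter(de, .data$status != "not-DE")
  edges <- as_tibble(catalog) |>
    filter(.data$regulator %in% de_feats$feature,
           .data$target %in% de_feats$feature) |>
    mutate(edge_type = ifelse(.data$regulator_class == "TF", "tf-target", "mirna-target")) |>
    group_by(.data$regulator, .data$target, .data$edge_type) |>
    summarise(evidence = paste(sort(unique(.data$evidence)), collapse = ","),
              .groups = "drop") |>
    arrange(.data$regulator, .data$target)
  participants <- union(edges$regulator, edges$target)
  nodes <- de_feats |>
    filter(.data$feature %in% participants) |>
    transmute(node = .data$feature, class = .data$class, direction = .data$status,
              M = if ("M" %in% names(de_feats)) .data$M else NA_real_) |>
    arrange(.data$node)
  new_regnet(nodes, edges)
}

new_regnet <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "regnet")
}

#' @export
print.regnet <- function(x, ...) {
  cls <- table(factor(x$nodes$class, levels = c("TF", "miRNA", "gene")))
  cat(sprintf(
    "<regnet> %d nodes (%d TFs, %d miRNAs, %d genes), %d edges\n",
    nrow(x$nodes), cls[["TF"]], cls[["miRNA"]], cls[["gene"]], nrow(x$edges)
  ))
  invisible(x)
}

#' @rdname build_network
#' @param x A `regnet`.
#' @param ... Unused.
#' @export
tidy.regnet <- function(x, ...) x$edges

#' @rdname build_network
#' @export
glance.regnet <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_tfs = sum(x$nodes$class == "TF"),
    n_mirnas = sum(x$nodes$class == "miRNA"),
    n_genes = sum(x$nodes$class == "gene"),
    n_edges = nrow(x$edges),
    n_tf_target = sum(x$edges$edge_type == "tf-target"),
    n_mirna_target = sum(x$edges$edge_type == "mirna-target")
  )
}

# igraph view of a regnet (directed unless symmetrize).
regnet_igraph <- function(network, directed = TRUE) {
  g <- igraph::graph_from_data_frame(
    network$edges[c("regulator", "target")],
    directed = directed,
    vertices = network$nodes["node"]
  )
  if (!directed) g <- igraph::simplify(g)
  g
}

#' Node-centred sub-network
#'
#' The induced subgraph on a node together with all its direct regulators
#' and direct targets.
#'
#' @param network A `regnet`.
#' @param node_id Node identifier.
#' @return A `regnet` restricted to the neighborhood.
#' @export
node_subnetwork <- function(network, node_id) {
  if (!node_id %in% network$nodes$node) {
    stop_fflnet(sprintf("unknown node '%s'", node_id), class = "fflnet_unknown_node")
  }
  nbrs <- union(
    network$edges$target[network$edges$regulator == node_id],
    network$edges$regulator[network$edges$target == node_id]
  )
  keep <- union(node_id, nbrs)
  edges <- filter(network$edges, .data$regulator %in% keep, .data$target %in% keep)
  nodes <- filter(network$nodes, .data$node %in% keep)
  new_regnet(nodes, edges)
}
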