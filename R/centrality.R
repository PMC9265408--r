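centrality_measures <- c("DC", "BC", "CC", "EC", "SC", "IC", "LAC", "NC")

# Undirected simple adjacency matrix of a regnet / igraph.
as_undirected_adjacency <- function(network) {
  g <- if (inherits(network, "regnet")) {
    regnet_igraph(network, directed = FALSE)
  } else if (igraph::is_igraph(network)) {
    igraph::simplify(igraph::as_undirected(network, mode = "collapse"))
  } else {
    stop_fflnet("`network` must be a regnet or an igraph object")
  }
  if (igraph::vcount(g) == 0) stop_fflnet("cannot compute centralities on an empty graph")
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  A[A > 0] <- 1
  diag(A) <- 0
  A
}

# Principal eigenvector by power iteration on A + I (the shift removes the
# bipartite +/- lambda ambiguity without changing eigenvectors); computed on
# the largest connected component, 0 elsewhere; L2-normalized, nonnegative.
eigen_centrality_power <- function(A, tol = 1e-12, max_iter = 1e5) {
  n <- nrow(A)
  ec <- rep(0, n)
  comp <- components_from_adjacency(A)
  sizes <- tabulate(comp)
  main <- which(comp == which.max(sizes))
  if (length(main) < 2 || sum(A[main, main]) == 0) return(ec)
  B <- A[main, main, drop = FALSE] + diag(length(main))
  x <- rep(1 / sqrt(length(main)), length(main))
  for (i in seq_len(max_iter)) {
    x_new <- as.vector(B %*% x)
    x_new <- x_new / sqrt(sum(x_new^2))
    if (max(abs(x_new - x)) < tol) {
      x <- x_new
      break
    }
    x <- x_new
  }
  ec[main] <- abs(x)
  ec
}

# Connected component labels via BFS on the adjacency matrix.
components_from_adjacency <- function(A) {
  n <- nrow(A)
  comp <- rep(0L, n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] != 0L) next
    cur <- cur + 1L
    frontier <- v
    comp[v] <- cur
    while (length(frontier) > 0) {
      nbr <- which(colSums(A[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nbr] <- cur
      frontier <- nbr
    }
  }
  comp
}

# Stephenson-Zelen information centrality, per connected component:
# C = (L + J)^{-1}; IC(v) = 1 / (C_vv + (T - 2 R_v) / n_c).
information_centrality <- function(A) {
  n <- nrow(A)
  ic <- rep(0, n)
  comp <- components_from_adjacency(A)
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    nc <- length(idx)
    if (nc < 2) next
    Ac <- A[idx, idx, drop = FALSE]
    L <- diag(rowSums(Ac)) - Ac
    C <- solve(L + matrix(1, nc, nc))
    Tr <- sum(diag(C))
    R <- rowSums(C)
    ic[idx] <- 1 / (diag(C) + (Tr - 2 * R) / nc)
  }
  ic
}

#' Eight node-centrality measures of a regulatory network
#'
#' Computes, on the symmetrized simple undirected graph, the measure set
#' used for hub detection: degree (DC), betweenness (BC), closeness (CC,
#' component-wise `(n_c - 1) / sum of distances`), eigenvector (EC, power
#' iteration on the largest component), subgraph (SC, `sum_j u_j(v)^2
#' exp(lambda_j)` from the adjacency eigendecomposition), information (IC,
#' Stephenson-Zelen current-flow form), local average connectivity (LAC,
#' mean within-neighborhood degree of a node's neighbors) and
#' edge-clustering centrality (NC, sum over incident edges of the edge
#' clustering coefficient `z / min(deg - 1, deg - 1)`). Isolated nodes score
#' 0 on every measure by convention.
#'
#' @param network A `regnet` or igraph object (directions are dropped).
#' @return A tibble with columns `node`, `class` (if available) and the
#'   eight measures.
#' @export
compute_centralities <- function(network) {
  A <- as_undirected_adjacency(network)
  n <- nrow(A)
  deg <- rowSums(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")

  bc <- igraph::betweenness(g, directed = FALSE)

  dist <- igraph::distances(g)
  comp <- components_from_adjacency(A)
  cc <- vapply(seq_len(n), function(v) {
    members <- which(comp == comp[v])
    if (length(members) < 2) return(0)
    (length(members) - 1) / sum(dist[v, members])
  }, double(1))

  ec <- eigen_centrality_power(A)

  es <- eigen(A, symmetric = TRUE)
  sc <- as.vector((es$vectors^2) %*% exp(es$values))

  ic <- information_centrality(A)

  lac <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) == 0) return(0)
    sum(A[nb, nb]) / length(nb)
  }, double(1))

  Z <- A %*% A          # common-neighbor counts
  nc <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) == 0) return(0)
    denom <- pmin(deg[v] - 1, deg[nb] - 1)
    ecc <- ifelse(denom > 0, Z[v, nb] / denom, 0)
    sum(ecc)
  }, double(1))

  out <- tibble(
    node = rownames(A), DC = unname(deg), BC = unname(bc), CC = cc, EC = ec,
    SC = sc, IC = ic, LAC = lac, NC = nc
  )
  # degree-0 convention: every measure is 0 for isolated nodes
  iso <- out$DC == 0
  out[iso, centrality_measures] <- 0
  if (inherits(network, "regnet")) {
    out <- left_join(out, select(network$nodes, "node", "class"), by = "node") |>
      relocate("class", .after = "node")
  }
  out
}

#' Hub selection by top-fraction intersection across all centrality measures
#'
#' For each measure, nodes scoring at or above the `(1 - fraction)` quantile
#' of that measure are retained (ties at the threshold are all retained);
#' the hub set is the intersection of the eight retained sets.
#'
#' @param table A centrality tibble from [compute_centralities()].
#' @param fraction Fraction of nodes to retain per measure (default 0.5).
#' @return A `hub_set` object: list with `hubs` (tibble of hub nodes),
#'   `retained` (named list of per-measure retained node vectors),
#'   `table` (input table with per-measure retained flags and `is_hub`),
#'   and `fraction`.
#' @export
select_hubs <- function(table, fraction = 0.5) {
  if (nrow(table) == 0) stop_fflnet("centrality table is empty")
  if (fraction <= 0 || fraction > 1) stop_fflnet("`fraction` must be in (0, 1]")
  retained <- lapply(centrality_measures, function(m) {
    thr <- stats::quantile(table[[m]], 1 - fraction, names = FALSE, type = 7)
    table$node[table[[m]] >= thr]
  })
  names(retained) <- centrality_measures
  hubs <- Reduce(intersect, retained)
  flags <- as_tibble(setNames(
    lapply(retained, function(r) table$node %in% r),
    paste0("retained_", centrality_measures)
  ))
  out_tab <- bind_cols(table, flags)
  out_tab$is_hub <- table$node %in% hubs
  structure(list(
    hubs = filter(out_tab, .data$is_hub) |>
      select(any_of(c("node", "class")), all_of(centrality_measures)),
    retained = retained,
    table = out_tab,
    fraction = fraction
  ), class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("<hub_set> %d hubs of %d nodes (top %.0f%% intersection of %d measures)\n",
              nrow(x$hubs), nrow(x$table), 100 * x$fraction, length(x$retained)))
  invisible(x)
}

#' @rdname select_hubs
#' @param x A `hub_set`.
#' @param ... Unused.
#' @export
tidy.hub_set <- function(x, ...) x$table

#' @rdname select_hubs
#' @export
glance.hub_set <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$table), n_hubs = nrow(x$hubs), fraction = x$fraction,
    n_hub_tfs = if ("class" %in% names(x$hubs)) sum(x$hubs$class == "TF") else NA_integer_,
    n_hub_mirnas = if ("class" %in% names(x$hubs)) sum(x$hubs$class == "miRNA") else NA_integer_,
    n_hub_genes = if ("class" %in% names(x$hubs)) sum(x$hubs$class == "gene") else NA_integer_
  )
}
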