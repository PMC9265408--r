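# Independent oracles used to cross-check the implementation. These are
# deliberately naive (enumeration, truncated series, pseudo-inverse algebra)
# and share no code with the package internals.

# Random simple undirected graph as an adjacency matrix with letter names.
random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  A <- A + t(A)
  dimnames(A) <- list(letters[seq_len(n)], letters[seq_len(n)])
  A
}

adjacency_igraph <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# Betweenness by exhaustive enumeration of all simple paths between every
# unordered pair, keeping shortest ones and counting pass-throughs.
oracle_betweenness <- function(A) {
  n <- nrow(A)
  bc <- rep(0, n)
  all_paths <- function(from, to, visited) {
    if (from == to) return(list(visited))
    out <- list()
    for (nxt in which(A[from, ] > 0)) {
      if (nxt %in% visited) next
      out <- c(out, all_paths(nxt, to, c(visited, nxt)))
    }
    out
  }
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      paths <- all_paths(s, t, s)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      inner <- unlist(lapply(shortest, function(p) p[-c(1, length(p))]))
      if (length(inner) > 0) {
        tab <- table(inner)
        idx <- as.integer(names(tab))
        bc[idx] <- bc[idx] + as.vector(tab) / sigma
      }
    }
  }
  bc
}

# Subgraph centrality via the matrix exponential series, run far enough that
# the truncation remainder is negligible at the comparison tolerance.
oracle_subgraph <- function(A, kmax = 60) {
  n <- nrow(A)
  S <- diag(n)
  P <- diag(n)
  for (k in seq_len(kmax)) {
    P <- P %*% A / k
    S <- S + P
  }
  diag(S)
}

# Information centrality from pairwise effective resistances obtained from
# the Laplacian pseudo-inverse, harmonically averaged per component.
oracle_information <- function(A) {
  n <- nrow(A)
  ic <- rep(0, n)
  comp <- igraph::components(adjacency_igraph(A))$membership
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    nc <- length(idx)
    if (nc < 2) next
    Ac <- A[idx, idx, drop = FALSE]
    L <- diag(rowSums(Ac)) - Ac
    Lp <- MASS::ginv(L)
    for (a in seq_len(nc)) {
      r <- Lp[a, a] + diag(Lp) - 2 * Lp[a, ]
      ic[idx[a]] <- nc / sum(r)
    }
  }
  ic
}

# Exhaustive triple-loop FFL enumeration over a regnet.
oracle_ffls <- function(network) {
  nodes <- network$nodes
  edges <- network$edges
  has <- function(a, b) any(edges$regulator == a & edges$target == b)
  tfs <- nodes$node[nodes$class == "TF"]
  mirs <- nodes$node[nodes$class == "miRNA"]
  genes <- nodes$node[nodes$class == "gene"]
  out <- list()
  for (t in tfs) for (m in mirs) for (g in genes) {
    if (has(t, g) && has(m, g) && (has(t, m) || has(m, t))) {
      out[[length(out) + 1]] <- c(t, m, g)
    }
  }
  if (length(out) == 0) return(character(0))
  sort(vapply(out, paste, character(1), collapse = "|"))
}

# Random regnet over TFs/miRNAs/genes for property tests.
random_regnet <- function(n_tf = 8, n_mir = 8, n_gene = 14, p = 0.08) {
  nodes <- tibble::tibble(
    node = c(sprintf("t%02d", 1:n_tf), sprintf("m%02d", 1:n_mir),
             sprintf("g%02d", 1:n_gene)),
    class = rep(c("TF", "miRNA", "gene"), c(n_tf, n_mir, n_gene)),
    direction = sample(c("up", "down"), n_tf + n_mir + n_gene, replace = TRUE),
    M = rnorm(n_tf + n_mir + n_gene)
  )
  regs <- nodes[nodes$class != "gene", ]
  pairs <- expand.grid(regulator = regs$node, target = nodes$node,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  cls <- stats::setNames(nodes$class, nodes$node)
  # drop miRNA -> miRNA
  pairs <- pairs[!(cls[pairs$regulator] == "miRNA" & cls[pairs$target] == "miRNA"), ]
  keep <- runif(nrow(pairs)) < p
  edges <- tibble::as_tibble(pairs[keep, ]) |>
    dplyr::mutate(
      edge_type = ifelse(cls[regulator] == "TF", "tf-target", "mirna-target"),
      evidence = sample(c("ChIP-Seq", "TargetScan", "predicted"), sum(keep),
                        replace = TRUE)
    )
  used <- union(edges$regulator, edges$target)
  fflnet:::new_regnet(nodes[nodes$node %in% used, ], edges)
}

# Hand log-rank: pooled E/V accumulation over distinct event times.
oracle_logrank <- function(a, b) {
  df <- rbind(data.frame(time = a$time, event = a$event, g = 0),
              data.frame(time = b$time, event = b$event, g = 1))
  times <- sort(unique(df$time[df$event == 1]))
  O <- E <- V <- 0
  for (tt in times) {
    at_risk <- df$time >= tt
    n <- sum(at_risk)
    n_a <- sum(at_risk & df$g == 0)
    d <- sum(df$time == tt & df$event == 1)
    d_a <- sum(df$time == tt & df$event == 1 & df$g == 0)
    O <- O + d_a
    E <- E + d * n_a / n
    if (n > 1) V <- V + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# A three-node network shaped like the discovered miRNA-TF-gene loop.
triad_network <- function() {
  de <- tibble::tibble(
    feature = c("hsa-miR-9-5p", "FOXO1", "CPEB3"),
    class = c("miRNA", "TF", "gene"),
    status = c("up", "down", "down"),
    M = c(4.0, -2.5, -2.0),
    mean_tumor = c(1000, 50, 40),
    mean_adjacent = c(60, 300, 170)
  )
  catalog <- interaction_catalog(tibble::tibble(
    regulator = c("hsa-miR-9-5p", "hsa-miR-9-5p", "FOXO1"),
    regulator_class = c("miRNA", "miRNA", "TF"),
    target = c("FOXO1", "CPEB3", "CPEB3"),
    target_class = c("TF", "gene", "gene"),
    evidence = c("TargetScan", "TargetScan", "ChIP-Seq")
  ))
  build_network(de, catalog)
}
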