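#' Enumerate TF-miRNA-gene feed-forward loops
#'
#' A feed-forward loop is a triple (TF t, miRNA m, gene g) such that the
#' network contains the edges `t -> g` and `m -> g`, and at least one of
#' `t -> m` or `m -> t`. Each qualifying triple is reported once, with its
#' subtype: `TF-FFL` (only `t -> m`), `miRNA-FFL` (only `m -> t`) or
#' `composite-FFL` (both).
#'
#' @param network A `regnet` from [build_network()].
#' @return A tibble with one row per loop: `tf`, `mirna`, `gene`,
#'   `ffl_type`, the DE direction pattern (`mirna_dir`, `tf_dir`,
#'   `gene_dir`) and the participating edges' evidence strings
#'   (`ev_tf_gene`, `ev_mirna_gene`, `ev_tf_mirna`, `ev_mirna_tf`; `NA`
#'   where an edge is absent).
#' @export
enumerate_ffls <- function(network) {
  nodes <- network$nodes
  edges <- network$edges
  empty <- tibble(
    tf = character(), mirna = character(), gene = character(),
    ffl_type = character(), mirna_dir = character(), tf_dir = character(),
    gene_dir = character(), ev_tf_gene = character(), ev_mirna_gene = character(),
    ev_tf_mirna = character(), ev_mirna_tf = character()
  )
  if (nrow(edges) == 0) return(empty)
  cls <- setNames(nodes$class, nodes$node)
  dir <- setNames(nodes$direction, nodes$node)
  ev <- setNames(edges$evidence, paste(edges$regulator, edges$target, sep = "\r"))
  edge_ev <- function(a, b) unname(ev[paste(a, b, sep = "\r")])
  has_edge <- function(a, b) !is.na(edge_ev(a, b))

  to_gene <- filter(edges, cls[.data$target] == "gene")
  genes <- unique(to_gene$target)
  rows <- list()
  for (g in genes) {
    regs <- to_gene$regulator[to_gene$target == g]
    tfs <- regs[cls[regs] == "TF"]
    mirs <- regs[cls[regs] == "miRNA"]
    if (length(tfs) == 0 || length(mirs) == 0) next
    for (t in tfs) {
      for (m in mirs) {
        t2m <- has_edge(t, m)
        m2t <- has_edge(m, t)
        if (!t2m && !m2t) next
        type <- if (t2m && m2t) "composite-FFL" else if (t2m) "TF-FFL" else "miRNA-FFL"
        rows[[length(rows) + 1]] <- tibble(
          tf = t, mirna = m, gene = g, ffl_type = type,
          mirna_dir = unname(dir[m]), tf_dir = unname(dir[t]),
          gene_dir = unname(dir[g]),
          ev_tf_gene = edge_ev(t, g), ev_mirna_gene = edge_ev(m, g),
          ev_tf_mirna = edge_ev(t, m), ev_mirna_tf = edge_ev(m, t)
        )
      }
    }
  }
  if (length(rows) == 0) return(empty)
  bind_rows(rows) |> arrange(.data$tf, .data$mirna, .data$gene)
}

#' Classify a feed-forward loop by its TF-miRNA edge orientation
#'
#' @param network A `regnet`.
#' @param tf,mirna Node ids of the loop's TF and miRNA.
#' @return `"TF-FFL"`, `"miRNA-FFL"` or `"composite-FFL"`.
#' @export
classify_ffl <- function(network, tf, mirna) {
  e <- network$edges
  t2m <- any(e$regulator == tf & e$target == mirna)
  m2t <- any(e$regulator == mirna & e$target == tf)
  if (!t2m && !m2t) {
    stop_fflnet("not a feed-forward loop: no TF-miRNA edge in either direction")
  }
  if (t2m && m2t) "composite-FFL" else if (t2m) "TF-FFL" else "miRNA-FFL"
}

#' Candidate-filter configuration for key feed-forward loops
#'
#' @param allowed_evidence Evidence labels accepted as reliable support for
#'   an edge (default ChIP-Seq and TargetScan).
#' @param min_hub_expression Minimum mean expression of each member in its
#'   higher condition (RSEM units).
#' @param min_abs_log2fc Minimum absolute log2 fold change of each member.
#' @param assoc_corr_cutoff Absolute Spearman correlation above which a
#'   feature counts as methylation/CNV-associated (default 0.3).
#' @param assoc_fdr_cutoff BH-FDR cutoff for the association test
#'   (default 0.05).
#' @return A `candidate_filter_config` list.
#' @export
candidate_filter_config <- function(allowed_evidence = c("ChIP-Seq", "TargetScan"),
                                    min_hub_expression = 20, min_abs_log2fc = 1,
                                    assoc_corr_cutoff = 0.3, assoc_fdr_cutoff = 0.05) {
  if (min_hub_expression < 0 || min_abs_log2fc < 0 ||
      assoc_corr_cutoff <= 0 || assoc_fdr_cutoff <= 0) {
    stop_fflnet("candidate-filter cutoffs must be positive")
  }
  structure(list(
    allowed_evidence = allowed_evidence, min_hub_expression = min_hub_expression,
    min_abs_log2fc = min_abs_log2fc, assoc_corr_cutoff = assoc_corr_cutoff,
    assoc_fdr_cutoff = assoc_fdr_cutoff
  ), class = "candidate_filter_config")
}

# Spearman rho between matched rows of two feature-by-sample matrices, with
# a joint permutation null (one sample permutation per draw, shared across
# features, which preserves cross-feature structure).
spearman_perm <- function(expr_mat, cov_mat, n_perm, seed) {
  n <- ncol(expr_mat)
  scale_ranks <- function(m) {
    r <- t(apply(m, 1, rank))
    r <- r - rowMeans(r)
    norm <- sqrt(rowSums(r^2))
    list(scaled = r / ifelse(norm > 0, norm, 1), degenerate = norm == 0)
  }
  a <- scale_ranks(expr_mat)
  b <- scale_ranks(cov_mat)
  degenerate <- a$degenerate | b$degenerate
  rho <- rowSums(a$scaled * b$scaled)
  rho[degenerate] <- NA_real_
  exceed <- rep(0L, nrow(expr_mat))
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      perm <- sample.int(n)
      rho_null <- rowSums(a$scaled * b$scaled[, perm, drop = FALSE])
      exceed <- exceed + (abs(rho_null) >= abs(rho))
    }
  })
  p <- (1 + exceed) / (n_perm + 1)
  p[degenerate] <- NA_real_
  list(rho = rho, p = p, degenerate = degenerate)
}

#' Methylation / copy-number association flags
#'
#' Tests, per gene or TF, whether expression is associated with the
#' feature's methylation beta and copy-number value across shared tumor
#' samples: Spearman correlation with a permutation p-value and BH-FDR
#' across features per covariate. A feature is `affected` iff
#' `|rho| >= assoc_corr_cutoff` and `FDR < assoc_fdr_cutoff`. Features with
#' a constant expression or covariate vector get `affected = FALSE` with a
#' warning.
#'
#' @param expr A tumor `expr_matrix`.
#' @param methylation,cnv Long tibbles (`feature`, `sample`, `value`) as
#'   produced by [simulate_cohort()] / [read_covariate()]; either may be
#'   `NULL` or empty.
#' @param config A [candidate_filter_config()].
#' @param n_perm Number of permutations (>= 999 recommended).
#' @param seed Permutation seed.
#' @return A tibble `feature`, `covariate`, `rho`, `p_perm`, `fdr`,
#'   `affected`.
#' @export
methylation_cnv_association <- function(expr, methylation = NULL, cnv = NULL,
                                        config = candidate_filter_config(),
                                        n_perm = 999, seed = 1L) {
  one_covariate <- function(cov, label) {
    if (is.null(cov) || nrow(cov) == 0) return(NULL)
    cov_wide <- tidyr::pivot_wider(cov, names_from = "sample", values_from = "value")
    feats <- intersect(cov_wide$feature, rownames(expr$values))
    samples <- sort(intersect(colnames(expr$values), setdiff(names(cov_wide), "feature")))
    if (length(samples) < 5) {
      stop_fflnet(sprintf("fewer than 5 shared samples for %s association", label))
    }
    cm <- as.matrix(cov_wide[match(feats, cov_wide$feature), samples])
    em <- expr$values[feats, samples, drop = FALSE]
    res <- spearman_perm(em, cm, n_perm, seed)
    if (any(res$degenerate)) {
      rlang::warn(sprintf(
        "%d feature(s) with constant values in %s association; marked unaffected",
        sum(res$degenerate), label
      ))
    }
    fdr <- stats::p.adjust(res$p, method = "BH")
    tibble(
      feature = feats, covariate = label, rho = res$rho, p_perm = res$p, fdr = fdr,
      affected = !is.na(res$rho) & abs(res$rho) >= config$assoc_corr_cutoff &
        !is.na(fdr) & fdr < config$assoc_fdr_cutoff
    )
  }
  out <- bind_rows(
    one_covariate(methylation, "methylation"),
    one_covariate(cnv, "cnv")
  )
  if (nrow(out) == 0) {
    out <- tibble(feature = character(), covariate = character(), rho = double(),
                  p_perm = double(), fdr = double(), affected = logical())
  }
  out
}

evidence_ok <- function(ev_string, allowed) {
  if (is.na(ev_string)) return(TRUE)  # absent optional edge imposes no constraint
  any(strsplit(ev_string, ",", fixed = TRUE)[[1]] %in% allowed)
}

#' Filter and rank candidate key feed-forward loops
#'
#' Applies the candidate cascade: (a) all three members are hub nodes,
#' (b) every participating edge carries at least one allowed evidence label,
#' (c) every member has mean expression in its higher condition at or above
#' `min_hub_expression` and `|log2FC| >= min_abs_log2fc`, (d) neither the TF
#' nor the gene is methylation- or CNV-affected. Surviving loops are ranked
#' by the sum of members' absolute log2 fold changes (descending), ties
#' broken lexicographically by (tf, mirna, gene).
#'
#' @param ffls Loop tibble from [enumerate_ffls()].
#' @param de Per-feature DE tibble (needs `feature`, `M`, `mean_tumor`,
#'   `mean_adjacent`), or an `ffl_de`.
#' @param hubs A `hub_set` from [select_hubs()].
#' @param assoc Association tibble from [methylation_cnv_association()]
#'   (may be empty: nothing is flagged affected).
#' @param config A [candidate_filter_config()].
#' @return `ffls` with logical columns `hubs_ok`, `evidence_ok`,
#'   `expression_ok`, `assoc_ok`, `keep`, ranking score `score` and `rank`
#'   (`NA` for dropped loops), sorted kept-first by rank.
#' @export
filter_candidates <- function(ffls, de, hubs, assoc = NULL,
                              config = candidate_filter_config()) {
  if (inherits(de, "ffl_de")) de <- de$table
  if (nrow(ffls) == 0) {
    return(mutate(ffls, hubs_ok = logical(), evidence_ok = logical(),
                  expression_ok = logical(), assoc_ok = logical(),
                  keep = logical(), score = double(), rank = integer()))
  }
  hub_nodes <- hubs$hubs$node
  de_idx <- match(ffls$tf, de$feature)
  stats_for <- function(ids) {
    i <- match(ids, de$feature)
    tibble(
      M = de$M[i],
      hi = pmax(de$mean_tumor[i], de$mean_adjacent[i])
    )
  }
  s_tf <- stats_for(ffls$tf)
  s_mir <- stats_for(ffls$mirna)
  s_gene <- stats_for(ffls$gene)
  affected <- if (is.null(assoc) || nrow(assoc) == 0) character()
              else unique(assoc$feature[assoc$affected])
  member_ok <- function(s) {
    !is.na(s$M) & abs(s$M) >= config$min_abs_log2fc & s$hi >= config$min_hub_expression
  }
  out <- ffls |>
    mutate(
      hubs_ok = .data$tf %in% hub_nodes & .data$mirna %in% hub_nodes &
        .data$gene %in% hub_nodes,
      evidence_ok = map_lgl(seq_len(n()), function(i) {
        all(vapply(
          c(ffls$ev_tf_gene[i], ffls$ev_mirna_gene[i], ffls$ev_tf_mirna[i],
            ffls$ev_mirna_tf[i]),
          evidence_ok, logical(1), allowed = config$allowed_evidence
        ))
      }),
      expression_ok = member_ok(s_tf) & member_ok(s_mir) & member_ok(s_gene),
      assoc_ok = !(.data$tf %in% affected) & !(.data$gene %in% affected),
      keep = .data$hubs_ok & .data$evidence_ok & .data$expression_ok & .data$assoc_ok,
      score = abs(s_tf$M) + abs(s_mir$M) + abs(s_gene$M)
    ) |>
    arrange(desc(.data$keep), desc(.data$score), .data$tf, .data$mirna, .data$gene)
  out$rank <- NA_integer_
  out$rank[out$keep] <- seq_len(sum(out$keep))
  out
}
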