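#' Run the full feed-forward-loop discovery pipeline on a cohort
#'
#' Executes, in order: cohort simulation (or a supplied cohort), paired
#' differential expression, DE-restricted network construction, eight-measure
#' centrality and hub selection, loop enumeration, methylation/CNV
#' association, candidate filtering/ranking, and best-versus-worst survival
#' stratification on the top-ranked loop. A manifest records the seed, a
#' parameter hash and per-stage status, so a run is self-describing and two
#' runs with the same inputs are identical.
#'
#' @param config A [sim_config()] (ignored when `cohort` is supplied).
#' @param cohort Optionally, an existing `ffl_cohort`.
#' @param thresholds A [de_thresholds()].
#' @param hub_fraction Per-measure retention fraction for hub selection.
#' @param filter_config A [candidate_filter_config()].
#' @param horizon_months Survival truncation horizon (default 60 months).
#' @param n_perm Permutations for the association test (computed over the
#'   network's genes and TFs, the candidates the filter applies to).
#' @return An `ffl_pipeline` list: `cohort`, `de`, `network`, `centrality`,
#'   `hubs`, `ffls` (filtered/ranked), `assoc`, `survival` (or `NULL` when
#'   no loop was found) and `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), cohort = NULL,
                         thresholds = de_thresholds(), hub_fraction = 0.5,
                         filter_config = candidate_filter_config(),
                         horizon_months = 60, n_perm = 999) {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  seed <- cohort$config$seed %||% config$seed
  stages <- character()
  done <- function(name) stages <<- c(stages, name)

  de <- diff_expression(cohort$tumor, cohort$adjacent, thresholds,
                        seed = derive_seed(seed, "noise"))
  done("diffexp")

  network <- build_network(de, cohort$catalog)
  done("network")

  if (nrow(network$nodes) > 0) {
    cent <- compute_centralities(network)
    hubs <- select_hubs(cent, fraction = hub_fraction)
  } else {
    cent <- tibble(node = character())
    hubs <- structure(list(hubs = tibble(node = character()), retained = list(),
                           table = tibble(node = character()), fraction = hub_fraction),
                      class = "hub_set")
  }
  done("hubs")

  ffls <- enumerate_ffls(network)
  # the affected-by-methylation/CNV filter applies to the candidate genes and
  # TFs of the network, so the association (and its FDR) runs over those
  cand <- network$nodes$node[network$nodes$class %in% c("gene", "TF")]
  assoc <- if (length(cand) > 0) {
    expr_cand <- cohort$tumor
    expr_cand$values <- expr_cand$values[intersect(rownames(expr_cand$values), cand), ,
                                         drop = FALSE]
    methylation_cnv_association(
      expr_cand, cohort$methylation, cohort$cnv, config = filter_config,
      n_perm = n_perm, seed = derive_seed(seed, "permutation")
    )
  } else {
    methylation_cnv_association(cohort$tumor, NULL, NULL, config = filter_config)
  }
  ranked <- filter_candidates(ffls, de, hubs, assoc, filter_config)
  done("ffl")

  surv <- NULL
  top <- filter(ranked, .data$keep)
  if (nrow(top) == 0 && nrow(ranked) > 0) top <- ranked[1, ]
  if (nrow(top) > 0) {
    directions <- setNames(c("low", "high", "high"),
                           c(top$mirna[1], top$tf[1], top$gene[1]))
    rule <- grouping_rule("multi-median", directions)
    surv <- survival_report(cohort$clinical, cohort$tumor, rule,
                            horizon_months = horizon_months)
  }
  done("survival")

  params <- list(
    config = cohort$config, thresholds = thresholds, hub_fraction = hub_fraction,
    filter_config = filter_config, horizon_months = horizon_months, n_perm = n_perm
  )
  manifest <- list(
    package = "fflnet",
    version = as.character(utils::packageVersion("fflnet")),
    seed = seed,
    parameter_hash = rlang::hash(params),
    stages = c("simulate", stages),
    n_de = sum(de$table$status != "not-DE"),
    n_nodes = nrow(network$nodes),
    n_edges = nrow(network$edges),
    n_hubs = nrow(hubs$hubs),
    n_ffls = nrow(ranked),
    n_ffls_kept = sum(ranked$keep)
  )
  structure(list(
    cohort = cohort, de = de, network = network, centrality = cent, hubs = hubs,
    ffls = ranked, assoc = assoc, survival = surv, manifest = manifest
  ), class = "ffl_pipeline")
}

#' @export
print.ffl_pipeline <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<ffl_pipeline> seed %d | %d DE features -> %d-node/%d-edge network -> %d hubs -> %d loop(s), %d kept\n",
    m$seed, m$n_de, m$n_nodes, m$n_edges, m$n_hubs, m$n_ffls, m$n_ffls_kept
  ))
  if (!is.null(x$survival)) {
    cat(sprintf("  best-vs-worst log-rank p = %.4g\n", x$survival$logrank$p))
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits the simulated cohort TSVs, the per-feature DE table, the network
#' (GraphML + edge TSV), the centrality/hub table, the ranked loop table and
#' a JSON manifest.
#'
#' @param result An `ffl_pipeline`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_cohort(result$cohort, file.path(dir, "cohort"))
  readr::write_tsv(result$de$table, file.path(dir, "de_results.tsv"), progress = FALSE)
  if (nrow(result$network$edges) > 0) {
    export_network(result$network, file.path(dir, "network.graphml"), "graphml")
    export_network(result$network, file.path(dir, "network_edges.tsv"), "tsv")
  }
  if (nrow(result$hubs$table) > 0) {
    readr::write_tsv(result$hubs$table, file.path(dir, "hubs.tsv"), progress = FALSE)
  }
  readr::write_tsv(result$ffls, file.path(dir, "ffls.tsv"), progress = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
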