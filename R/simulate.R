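#' Configuration for a synthetic paired tumor/adjacent cohort
#'
#' Defines the study conditions emulated by [simulate_cohort()]: a paired
#' tumor versus matched-adjacent design with RSEM-like continuous counts,
#' a regulatory interaction catalog containing planted feed-forward loops,
#' survival times whose hazard depends on the expression of the first
#' planted loop, and methylation/copy-number covariates.
#'
#' Expression is log-normal: each feature draws a baseline log-mean from
#' `Normal(baseline_log_mean, baseline_log_sd)`; every sample multiplies the
#' baseline by replicate noise `exp(Normal(0, noise_log_sd))`, and tumor
#' samples of differentially expressed features additionally multiply by
#' `2^log2fc` with the planted fold change.
#'
#' @param n_genes,n_tfs,n_mirnas Number of features per class.
#' @param n_pairs Number of tumor/adjacent sample pairs (>= 2).
#' @param de_fraction Fraction of all features given a planted fold change.
#' @param planted_log2fc_range Interval (log2 units) from which planted
#'   absolute fold changes are drawn; lower bound must be >= 1.
#' @param baseline_log_mean,baseline_log_sd Natural-log mean and sd of the
#'   per-feature baseline expression.
#' @param noise_log_sd Natural-log sd of the multiplicative replicate noise.
#' @param catalog_density Expected number of catalog edges per regulator.
#' @param n_planted_ffls Number of planted (TF, miRNA, gene) loops. Each is
#'   planted with the direction pattern miRNA up, TF down, gene down, and
#'   its edges enter the catalog with ChIP-Seq (TF to gene) or TargetScan
#'   (miRNA to TF / miRNA to gene) evidence.
#' @param hazard_beta Survival log-hazard increase per unit of the loop
#'   activity score `z(miRNA) - z(TF) - z(gene)` (cohort z-scores of tumor
#'   expression of the first planted loop).
#' @param baseline_hazard Baseline exponential event rate per month.
#' @param censor_fraction Target fraction of censored subjects.
#' @param lost_fraction Fraction of subjects flagged lost to follow-up.
#' @param meth_affected,cnv_affected Features whose methylation / copy
#'   number is planted to correlate with their expression: either a count
#'   (sampled among genes and TFs) or a character vector of feature ids.
#' @param seed Integer seed; the same seed yields bit-identical cohorts.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 300, n_tfs = 40, n_mirnas = 30, n_pairs = 50,
                       de_fraction = 0.1, planted_log2fc_range = c(1.5, 4),
                       baseline_log_mean = 6, baseline_log_sd = 0.5,
                       noise_log_sd = 0.06, catalog_density = 50,
                       n_planted_ffls = 1, hazard_beta = 1,
                       baseline_hazard = log(2) / 36, censor_fraction = 0.3,
                       lost_fraction = 0.05, meth_affected = 0,
                       cnv_affected = 0, seed = 1L) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    n_tfs = check_count(n_tfs, "n_tfs"),
    n_mirnas = check_count(n_mirnas, "n_mirnas"),
    n_pairs = check_count(n_pairs, "n_pairs"),
    de_fraction = check_fraction(de_fraction, "de_fraction"),
    planted_log2fc_range = as.double(planted_log2fc_range),
    baseline_log_mean = as.double(baseline_log_mean),
    baseline_log_sd = as.double(baseline_log_sd),
    noise_log_sd = as.double(noise_log_sd),
    catalog_density = as.double(catalog_density),
    n_planted_ffls = as.integer(n_planted_ffls),
    hazard_beta = as.double(hazard_beta),
    baseline_hazard = as.double(baseline_hazard),
    censor_fraction = check_fraction(censor_fraction, "censor_fraction"),
    lost_fraction = check_fraction(lost_fraction, "lost_fraction"),
    meth_affected = meth_affected,
    cnv_affected = cnv_affected,
    seed = as.integer(seed)
  )
  if (cfg$n_pairs < 2) {
    stop_fflnet("`n_pairs` must be >= 2 (within-condition noise needs sample pairs)")
  }
  if (length(cfg$planted_log2fc_range) != 2 ||
      cfg$planted_log2fc_range[1] > cfg$planted_log2fc_range[2]) {
    stop_fflnet("`planted_log2fc_range` must be an interval c(lo, hi) with lo <= hi")
  }
  if (cfg$de_fraction > 0 && cfg$planted_log2fc_range[1] < 1) {
    stop_fflnet("`planted_log2fc_range` lower bound must be >= 1 log2 unit")
  }
  if (cfg$n_planted_ffls < 0) stop_fflnet("`n_planted_ffls` must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

feature_ids <- function(cfg) {
  list(
    gene = sprintf("gene%03d", seq_len(cfg$n_genes)),
    TF = sprintf("TF%03d", seq_len(cfg$n_tfs)),
    miRNA = sprintf("hsa-mir-%03d", seq_len(cfg$n_mirnas))
  )
}

# Assign planted fold changes. Planted loops claim the first DE slots with
# the fixed direction pattern (miRNA up, TF down, gene down); the remaining
# slots get random features with random signs.
plant_de <- function(cfg, ids) {
  all_feats <- unlist(ids, use.names = FALSE)
  n_de <- round(cfg$de_fraction * length(all_feats))
  n_ffls <- min(cfg$n_planted_ffls, cfg$n_tfs, cfg$n_mirnas, cfg$n_genes,
                n_de %/% 3)
  lo <- cfg$planted_log2fc_range[1]
  hi <- cfg$planted_log2fc_range[2]
  # the top band of the range is reserved for the emulated discovered loop,
  # which is planted as the strongest differential module
  hi_bg <- lo + 0.92 * (hi - lo)
  ffls <- tibble(tf = character(), mirna = character(), gene = character())
  de <- tibble(feature = character(), class = character(), log2fc = double())
  if (n_ffls > 0) {
    ffls <- tibble(
      tf = sample(ids$TF, n_ffls),
      mirna = sample(ids$miRNA, n_ffls),
      gene = sample(ids$gene, n_ffls)
    )
    # the first planted loop emulates the discovered one: its miRNA sits at
    # the top of the fold-change range (the most significant DEM) and its TF
    # and gene in the upper half
    mir_fc <- c(hi, runif(max(0, n_ffls - 1), lo, hi_bg))[seq_len(n_ffls)]
    tf_fc <- -c(hi, runif(max(0, n_ffls - 1), lo, hi_bg))[seq_len(n_ffls)]
    gene_fc <- -c(hi, runif(max(0, n_ffls - 1), lo, hi_bg))[seq_len(n_ffls)]
    de <- bind_rows(
      tibble(feature = ffls$mirna, class = "miRNA", log2fc = mir_fc),
      tibble(feature = ffls$tf, class = "TF", log2fc = tf_fc),
      tibble(feature = ffls$gene, class = "gene", log2fc = gene_fc)
    )
  }
  n_rest <- n_de - nrow(de)
  if (n_rest > 0) {
    pool <- setdiff(all_feats, de$feature)
    extra <- sample(pool, n_rest)
    cls <- ifelse(extra %in% ids$gene, "gene", ifelse(extra %in% ids$TF, "TF", "miRNA"))
    de <- bind_rows(de, tibble(
      feature = extra, class = cls,
      log2fc = sample(c(-1, 1), n_rest, replace = TRUE) * runif(n_rest, lo, hi_bg)
    ))
  }
  list(de = de, ffls = ffls)
}

simulate_expression <- function(cfg, ids, de, ffls) {
  all_feats <- unlist(ids, use.names = FALSE)
  nf <- length(all_feats)
  np <- cfg$n_pairs
  mu <- rnorm(nf, cfg$baseline_log_mean, cfg$baseline_log_sd)
  names(mu) <- all_feats
  # planted-loop members are solidly expressed (the emulated loop passed a
  # high-expression filter in the discovery setting)
  members <- unique(unlist(ffls, use.names = FALSE))
  if (length(members) > 0) {
    mu[members] <- cfg$baseline_log_mean + cfg$baseline_log_sd +
      abs(rnorm(length(members), 0, cfg$baseline_log_sd / 2))
  }
  lfc <- setNames(rep(0, nf), all_feats)
  lfc[de$feature] <- de$log2fc
  noise_a <- matrix(rnorm(nf * np, 0, cfg$noise_log_sd), nf, np)
  noise_t <- matrix(rnorm(nf * np, 0, cfg$noise_log_sd), nf, np)
  adj <- exp(mu + noise_a)
  tum <- 2^lfc * exp(mu + noise_t)
  wd <- max(2, nchar(as.character(np)))
  tum_ids <- sprintf(paste0("T%0", wd, "d"), seq_len(np))
  adj_ids <- sprintf(paste0("N%0", wd, "d"), seq_len(np))
  dimnames(adj) <- list(all_feats, adj_ids)
  dimnames(tum) <- list(all_feats, tum_ids)
  cls <- setNames(
    rep(c("gene", "TF", "miRNA"), c(cfg$n_genes, cfg$n_tfs, cfg$n_mirnas)),
    all_feats
  )
  pairing <- tibble(tumor = tum_ids, adjacent = adj_ids)
  list(
    tumor = expression_matrix(tum, cls, "tumor", pairing = pairing),
    adjacent = expression_matrix(adj, cls, "adjacent", pairing = pairing)
  )
}

simulate_catalog <- function(cfg, ids, ffls, de) {
  regs <- tibble(
    regulator = c(ids$TF, ids$miRNA),
    regulator_class = rep(c("TF", "miRNA"), c(cfg$n_tfs, cfg$n_mirnas))
  )
  # class mix of random targets: regulators act mostly on genes
  draw_targets <- function(reg, reg_class, n) {
    if (n == 0) return(NULL)
    classes <- if (reg_class == "TF") {
      sample(c("gene", "TF", "miRNA"), n, replace = TRUE, prob = c(0.7, 0.15, 0.15))
    } else {
      sample(c("gene", "TF"), n, replace = TRUE, prob = c(0.75, 0.25))
    }
    tgt <- vapply(classes, function(cl) sample(ids[[cl]], 1), character(1))
    ev_pool <- if (reg_class == "TF") c("ChIP-Seq", "experimental", "predicted")
               else c("TargetScan", "experimental", "predicted")
    tibble(
      regulator = reg, regulator_class = reg_class,
      target = tgt, target_class = classes,
      evidence = sample(ev_pool, n, replace = TRUE, prob = c(0.5, 0.2, 0.3)),
      source = "simulated"
    )
  }
  n_edges <- stats::rpois(nrow(regs), cfg$catalog_density)
  random_edges <- list_rbind(pmap(
    list(regs$regulator, regs$regulator_class, n_edges), draw_targets
  ))
  planted_edges <- NULL
  if (nrow(ffls) > 0) {
    planted_edges <- bind_rows(
      tibble(regulator = ffls$mirna, regulator_class = "miRNA", target = ffls$tf,
             target_class = "TF", evidence = "TargetScan", source = "planted"),
      tibble(regulator = ffls$mirna, regulator_class = "miRNA", target = ffls$gene,
             target_class = "gene", evidence = "TargetScan", source = "planted"),
      tibble(regulator = ffls$tf, regulator_class = "TF", target = ffls$gene,
             target_class = "gene", evidence = "ChIP-Seq", source = "planted"),
      hub_reinforcement_edges(ffls, de)
    )
  }
  edges <- bind_rows(planted_edges, random_edges) |>
    filter(.data$regulator != .data$target) |>
    distinct(.data$regulator, .data$target, .data$evidence, .keep_all = TRUE)
  if (nrow(ffls) > 0) {
    # any catalog edge between members of one planted triad carries reliable
    # evidence: the emulated loop sits in a well-supported neighborhood
    for (i in seq_len(nrow(ffls))) {
      mem <- c(ffls$tf[i], ffls$mirna[i], ffls$gene[i])
      intra <- edges$regulator %in% mem & edges$target %in% mem
      edges$evidence[intra] <- ifelse(edges$regulator_class[intra] == "TF",
                                      "ChIP-Seq", "TargetScan")
    }
    edges <- distinct(edges, .data$regulator, .data$target, .data$evidence,
                      .keep_all = TRUE)
  }
  interaction_catalog(edges)
}

# The discovered loop of the emulated study was made of hub nodes; wire each
# planted triad into the differential set so its members are central in the
# DE-restricted network, with reliable evidence labels.
hub_reinforcement_edges <- function(ffls, de) {
  rows <- list()
  for (i in seq_len(nrow(ffls))) {
    mem <- c(tf = ffls$tf[i], mirna = ffls$mirna[i], gene = ffls$gene[i])
    de_other <- filter(de, !.data$feature %in% mem)
    pick <- function(classes, n) {
      pool <- de_other$feature[de_other$class %in% classes]
      sample(pool, min(n, length(pool)))
    }
    cls <- setNames(de_other$class, de_other$feature)
    mir_targets <- pick(c("gene", "TF"), 5)
    # the TF co-targets the miRNA's gene targets (shared triangles give the
    # loop members the local clustering typical of hub modules)
    tf_targets <- union(pick("gene", 3), mir_targets[cls[mir_targets] == "gene"])
    gene_regs <- pick(c("TF", "miRNA"), 8)
    reg_tfs <- gene_regs[cls[gene_regs] == "TF"]
    rows[[i]] <- bind_rows(
      tibble(regulator = mem[["mirna"]], regulator_class = "miRNA",
             target = mir_targets, target_class = unname(cls[mir_targets]),
             evidence = "TargetScan", source = "planted-hub"),
      tibble(regulator = mem[["tf"]], regulator_class = "TF",
             target = tf_targets, target_class = unname(cls[tf_targets]),
             evidence = "ChIP-Seq", source = "planted-hub"),
      tibble(regulator = gene_regs, regulator_class = unname(cls[gene_regs]),
             target = mem[["gene"]], target_class = "gene",
             evidence = if_else(cls[gene_regs] == "TF", "ChIP-Seq", "TargetScan"),
             source = "planted-hub"),
      tibble(regulator = mem[["mirna"]], regulator_class = "miRNA",
             target = reg_tfs, target_class = "TF",
             evidence = "TargetScan", source = "planted-hub"),
      # interconnect the gene's regulators so its incident edges sit in
      # triangles, as in a dense hub module
      tidyr::expand_grid(regulator = reg_tfs,
                         target = gene_regs[cls[gene_regs] == "miRNA"]) |>
        mutate(regulator_class = "TF", target_class = "miRNA",
               evidence = "ChIP-Seq", source = "planted-hub")
    )
  }
  bind_rows(rows)
}

simulate_clinical <- function(cfg, tumor, ffls) {
  samples <- colnames(tumor$values)
  n <- length(samples)
  score <- rep(0, n)
  if (nrow(ffls) > 0) {
    f <- ffls[1, ]
    score <- zscore(tumor$values[f$mirna, ]) - zscore(tumor$values[f$tf, ]) -
      zscore(tumor$values[f$gene, ])
  }
  linpred <- cfg$hazard_beta * score
  event_time <- rexp(n, rate = cfg$baseline_hazard * exp(linpred))
  u <- runif(n)
  if (cfg$censor_fraction <= 0) {
    time <- event_time
    event <- rep(1L, n)
  } else if (cfg$censor_fraction >= 1) {
    time <- u * stats::quantile(event_time, 0.5)
    event <- rep(0L, n)
  } else {
    # pick the uniform-censoring upper bound that hits the target fraction
    frac <- function(cmax) mean(cmax * u < event_time) - cfg$censor_fraction
    upper <- max(event_time) * 2
    cmax <- if (frac(upper) > 0) upper else uniroot(frac, c(1e-6, upper))$root
    cens_time <- cmax * u
    event <- as.integer(event_time <= cens_time)
    time <- pmin(event_time, cens_time)
  }
  lost <- runif(n) < cfg$lost_fraction
  list(
    clinical = clinical_table(tibble(
      sample_id = samples, time = round(time, 3), event = event,
      lost_to_followup = lost
    )),
    hazard = tibble(sample = samples, score = as.double(score),
                    linpred = as.double(linpred))
  )
}

resolve_affected <- function(spec_arg, candidates) {
  if (is.character(spec_arg)) return(intersect(spec_arg, candidates))
  n <- as.integer(spec_arg)
  if (n <= 0) return(character())
  sample(candidates, min(n, length(candidates)))
}

simulate_covariates <- function(cfg, tumor) {
  feats <- names(tumor$feature_class)[tumor$feature_class %in% c("gene", "TF")]
  samples <- colnames(tumor$values)
  logexpr_z <- t(apply(log2(tumor$values[feats, , drop = FALSE] + 1), 1, zscore))
  meth_aff <- resolve_affected(cfg$meth_affected, feats)
  cnv_aff <- resolve_affected(cfg$cnv_affected, feats)
  meth <- matrix(rbeta(length(feats) * length(samples), 2, 5),
                 length(feats), length(samples), dimnames = list(feats, samples))
  # planted association: methylation tracks expression on the logistic scale
  for (f in meth_aff) {
    meth[f, ] <- stats::plogis(-1 + 1.5 * logexpr_z[f, ] + rnorm(length(samples), 0, 0.5))
  }
  cnv <- matrix(rnorm(length(feats) * length(samples), 0, 0.4),
                length(feats), length(samples), dimnames = list(feats, samples))
  for (f in cnv_aff) {
    cnv[f, ] <- 0.6 * logexpr_z[f, ] + rnorm(length(samples), 0, 0.3)
  }
  to_long <- function(m) {
    tibble(
      feature = rep(rownames(m), times = ncol(m)),
      sample = rep(colnames(m), each = nrow(m)),
      value = as.vector(m)
    )
  }
  list(methylation = to_long(meth), cnv = to_long(cnv),
       meth_affected = sort(meth_aff), cnv_affected = sort(cnv_aff))
}

#' Simulate a complete synthetic cohort with known ground truth
#'
#' Generates paired tumor/adjacent expression matrices, an interaction
#' catalog containing the planted feed-forward loops, a clinical survival
#' table whose hazard follows the first planted loop's activity score,
#' methylation and copy-number covariate tables, and the ground truth needed
#' to score every downstream stage.
#'
#' @param config A [sim_config()].
#' @return An `ffl_cohort` list with elements `tumor`, `adjacent`
#'   (`expr_matrix`), `catalog`, `clinical`, `methylation`, `cnv`, `truth`
#'   and `config`. `truth` holds `de_features` (feature, class, planted
#'   log2fc), `planted_ffls` (tf, mirna, gene), `hazard` (per-sample loop
#'   activity score and linear predictor) and the planted covariate-affected
#'   feature sets.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    ids <- feature_ids(config)
    planted <- plant_de(config, ids)
    expr <- simulate_expression(config, ids, planted$de, planted$ffls)
    catalog <- simulate_catalog(config, ids, planted$ffls, planted$de)
    clin <- simulate_clinical(config, expr$tumor, planted$ffls)
    covs <- simulate_covariates(config, expr$tumor)
    structure(list(
      tumor = expr$tumor, adjacent = expr$adjacent, catalog = catalog,
      clinical = clin$clinical, methylation = covs$methylation, cnv = covs$cnv,
      truth = list(
        de_features = planted$de, planted_ffls = planted$ffls,
        hazard = clin$hazard, meth_affected = covs$meth_affected,
        cnv_affected = covs$cnv_affected
      ),
      config = config
    ), class = "ffl_cohort")
  })
}

#' @export
print.ffl_cohort <- function(x, ...) {
  cat(sprintf(
    "<ffl_cohort> %d features x %d pairs; %d planted DE features, %d planted FFL(s)\n",
    nrow(x$tumor$values), ncol(x$tumor$values), nrow(x$truth$de_features),
    nrow(x$truth$planted_ffls)
  ))
  invisible(x)
}

#' Write a simulated cohort to a directory of TSV files plus a truth JSON
#'
#' Emits `expr_tumor.tsv`, `expr_adjacent.tsv`, `classes.tsv`, `catalog.tsv`,
#' `clinical.tsv`, `methylation.tsv`, `cnv.tsv` and `truth.json`. All tables
#' round-trip losslessly through [read_cohort()].
#'
#' @param cohort An `ffl_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(cohort$tumor, file.path(dir, "expr_tumor.tsv"))
  write_expression(cohort$adjacent, file.path(dir, "expr_adjacent.tsv"))
  write_class_map(cohort$tumor, file.path(dir, "classes.tsv"))
  write_catalog(cohort$catalog, file.path(dir, "catalog.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_covariate(cohort$methylation, file.path(dir, "methylation.tsv"))
  write_covariate(cohort$cnv, file.path(dir, "cnv.tsv"))
  truth <- cohort$truth
  jsonlite::write_json(list(
    de_features = truth$de_features,
    planted_ffls = truth$planted_ffls,
    hazard = truth$hazard,
    meth_affected = truth$meth_affected,
    cnv_affected = truth$cnv_affected,
    pairing = cohort$tumor$pairing
  ), file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Directory path.
#' @return An `ffl_cohort` (without the original `config`).
#' @export
read_cohort <- function(dir) {
  truth_raw <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  pairing <- as_tibble(truth_raw$pairing)
  cls_path <- file.path(dir, "classes.tsv")
  structure(list(
    tumor = read_expression(file.path(dir, "expr_tumor.tsv"), cls_path, "tumor",
                            pairing = pairing),
    adjacent = read_expression(file.path(dir, "expr_adjacent.tsv"), cls_path,
                               "adjacent", pairing = pairing),
    catalog = read_catalog(file.path(dir, "catalog.tsv")),
    clinical = read_clinical(file.path(dir, "clinical.tsv")),
    methylation = read_covariate(file.path(dir, "methylation.tsv")),
    cnv = read_covariate(file.path(dir, "cnv.tsv")),
    truth = list(
      de_features = as_tibble(truth_raw$de_features),
      planted_ffls = as_tibble(truth_raw$planted_ffls),
      hazard = as_tibble(truth_raw$hazard),
      meth_affected = unlist(truth_raw$meth_affected) %||% character(),
      cnv_affected = unlist(truth_raw$cnv_affected) %||% character()
    ),
    config = NULL
  ), class = "ffl_cohort")
}
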