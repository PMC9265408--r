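test_that("the discovered-loop network yields exactly one miRNA-FFL", {
  ffls <- enumerate_ffls(triad_network())
  expect_equal(nrow(ffls), 1)
  expect_identical(ffls$tf, "FOXO1")
  expect_identical(ffls$mirna, "hsa-miR-9-5p")
  expect_identical(ffls$gene, "CPEB3")
  expect_identical(ffls$ffl_type, "miRNA-FFL")
  expect_identical(unname(unlist(ffls[, c("mirna_dir", "tf_dir", "gene_dir")])),
                   c("up", "down", "down"))
})

test_that("co-targeting without a TF-miRNA edge is not a loop", {
  de <- tibble::tibble(feature = c("T1", "M1", "G1"),
                       class = c("TF", "miRNA", "gene"),
                       status = c("up", "up", "down"),
                       M = c(2, 2, -2), mean_tumor = 1, mean_adjacent = 1)
  cat0 <- interaction_catalog(tibble::tibble(
    regulator = c("T1", "M1"), regulator_class = c("TF", "miRNA"),
    target = "G1", target_class = "gene", evidence = "ChIP-Seq"
  ))
  expect_equal(nrow(enumerate_ffls(build_network(de, cat0))), 0)
})

test_that("loop subtype follows the TF-miRNA edge orientation", {
  base_edges <- function(extra_reg, extra_tgt, extra_cls) {
    interaction_catalog(tibble::tibble(
      regulator = c("T1", "M1", extra_reg),
      regulator_class = c("TF", "miRNA", extra_cls),
      target = c("G1", "G1", extra_tgt),
      target_class = c("gene", "gene", ifelse(extra_tgt == "M1", "miRNA", "TF")),
      evidence = "TargetScan"
    ))
  }
  de <- tibble::tibble(feature = c("T1", "M1", "G1"),
                       class = c("TF", "miRNA", "gene"),
                       status = "up", M = 2, mean_tumor = 1, mean_adjacent = 1)
  net_tf <- build_network(de, base_edges("T1", "M1", "TF"))
  expect_identical(enumerate_ffls(net_tf)$ffl_type, "TF-FFL")
  expect_identical(classify_ffl(net_tf, "T1", "M1"), "TF-FFL")

  net_mir <- build_network(de, base_edges("M1", "T1", "miRNA"))
  expect_identical(enumerate_ffls(net_mir)$ffl_type, "miRNA-FFL")

  both <- interaction_catalog(tibble::tibble(
    regulator = c("T1", "M1", "T1", "M1"),
    regulator_class = c("TF", "miRNA", "TF", "miRNA"),
    target = c("G1", "G1", "M1", "T1"),
    target_class = c("gene", "gene", "miRNA", "TF"),
    evidence = "TargetScan"
  ))
  net_both <- build_network(de, both)
  expect_identical(enumerate_ffls(net_both)$ffl_type, "composite-FFL")
  no_pair <- build_network(de, interaction_catalog(tibble::tibble(
    regulator = c("T1", "M1"), regulator_class = c("TF", "miRNA"),
    target = "G1", target_class = "gene", evidence = "TargetScan"
  )))
  expect_error(classify_ffl(no_pair, "T1", "M1"), "no TF-miRNA edge")
})

test_that("enumeration equals the exhaustive triple loop on random networks", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      rn <- random_regnet()
      got <- enumerate_ffls(rn)
      got_keys <- sort(paste(got$tf, got$mirna, got$gene, sep = "|"))
      expect_identical(got_keys, oracle_ffls(rn))
    }
  })
})

test_that("enumeration is invariant to node and edge order", {
  withr::with_seed(17, {
    rn <- random_regnet(p = 0.15)
    shuffled <- fflnet:::new_regnet(
      rn$nodes[sample(nrow(rn$nodes)), ],
      rn$edges[sample(nrow(rn$edges)), ]
    )
    expect_equal(enumerate_ffls(rn), enumerate_ffls(shuffled))
  })
})

test_that("association flags: null control, perfect association, degenerate", {
  co <- simulate_cohort(sim_config(n_genes = 60, n_tfs = 10, n_mirnas = 5,
                                   n_pairs = 25, de_fraction = 0, seed = 21))
  assoc <- methylation_cnv_association(co$tumor, co$methylation, co$cnv,
                                       n_perm = 299, seed = 5)
  # expression independent of the covariates: almost nothing flagged
  expect_gt(mean(!assoc$affected), 0.95)

  # CNV a monotone function of expression: rho = 1
  feats <- rownames(co$tumor$values)[1:5]
  cnv_mono <- tidyr::expand_grid(feature = feats,
                                 sample = colnames(co$tumor$values)) |>
    dplyr::mutate(value = sqrt(co$tumor$values[cbind(feature, sample)]))
  a2 <- methylation_cnv_association(co$tumor, cnv = cnv_mono,
                                    n_perm = 299, seed = 5)
  expect_true(all(a2$affected))
  expect_equal(unname(a2$rho), rep(1, 5))

  # constant expression: unaffected with a warning
  flat <- co$tumor
  flat$values[feats[1], ] <- 100
  expect_warning(
    a3 <- methylation_cnv_association(flat, cnv = cnv_mono, n_perm = 99, seed = 5),
    "constant"
  )
  expect_false(a3$affected[a3$feature == feats[1]])
  expect_true(is.na(a3$rho[a3$feature == feats[1]]))
})

test_that("association requires enough shared samples", {
  co <- simulate_cohort(sim_config(n_genes = 20, n_tfs = 3, n_mirnas = 3,
                                   n_pairs = 3, seed = 1))
  few <- dplyr::filter(co$methylation,
                       sample %in% unique(co$methylation$sample)[1:2])
  expect_error(methylation_cnv_association(co$tumor, methylation = few),
               "fewer than 5")
})

test_that("candidate cascade drops non-compliant evidence and affected genes", {
  p <- run_pipeline(sim_config(seed = 12))
  tr <- p$cohort$truth$planted_ffls
  kept <- dplyr::filter(p$ffls, keep)
  expect_identical(kept$mirna[1], tr$mirna[1])
  expect_equal(kept$rank[1], 1L)

  # degrade evidence of the planted loop: removed at the evidence step
  ffls2 <- p$ffls
  i <- which(ffls2$tf == tr$tf[1] & ffls2$mirna == tr$mirna[1] &
               ffls2$gene == tr$gene[1])
  ffls2$ev_tf_gene[i] <- "predicted"
  out2 <- filter_candidates(ffls2[, 1:11], p$de, p$hubs, p$assoc)
  j <- which(out2$tf == tr$tf[1] & out2$mirna == tr$mirna[1] &
               out2$gene == tr$gene[1])
  expect_false(out2$evidence_ok[j])
  expect_false(out2$keep[j])

  # plant a methylation-driven gene: removed at the association step
  co3 <- simulate_cohort(sim_config(seed = 12, meth_affected = tr$gene[1]))
  expect_identical(co3$truth$planted_ffls$gene[1], tr$gene[1])
  p3 <- run_pipeline(cohort = co3)
  k3 <- which(p3$ffls$tf == tr$tf[1] & p3$ffls$mirna == tr$mirna[1] &
                p3$ffls$gene == tr$gene[1])
  expect_false(p3$ffls$assoc_ok[k3])
  expect_false(p3$ffls$keep[k3])
})

test_that("relaxing any cutoff never removes a retained loop", {
  p <- run_pipeline(sim_config(seed = 14))
  strict <- candidate_filter_config(min_hub_expression = 50, min_abs_log2fc = 2)
  loose <- candidate_filter_config(min_hub_expression = 20, min_abs_log2fc = 1)
  key <- function(x) paste(x$tf, x$mirna, x$gene)[x$keep]
  kept_strict <- key(filter_candidates(p$ffls[, 1:11], p$de, p$hubs, p$assoc, strict))
  kept_loose <- key(filter_candidates(p$ffls[, 1:11], p$de, p$hubs, p$assoc, loose))
  expect_true(all(kept_strict %in% kept_loose))
})
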