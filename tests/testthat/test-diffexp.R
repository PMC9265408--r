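# Two tiny paired matrices used across the DE tests.
toy_pair <- function(tumor_vals, adjacent_vals, classes) {
  feats <- names(classes)
  n <- length(tumor_vals[[1]])
  t_mat <- do.call(rbind, tumor_vals)
  a_mat <- do.call(rbind, adjacent_vals)
  dimnames(t_mat) <- list(feats, sprintf("T%02d", seq_len(n)))
  dimnames(a_mat) <- list(feats, sprintf("N%02d", seq_len(n)))
  list(
    tumor = expression_matrix(t_mat, classes, "tumor"),
    adjacent = expression_matrix(a_mat, classes, "adjacent")
  )
}

test_that("low-expression filter uses strict class-specific maxima", {
  p <- toy_pair(
    tumor_vals = list(g_at_limit = c(20, 20), g_above = c(21, 1),
                      mi_one_high = c(0, 0), mi_low = c(10, 10)),
    adjacent_vals = list(g_at_limit = c(20, 18), g_above = c(2, 2),
                         mi_one_high = c(11, 0), mi_low = c(9, 10)),
    classes = c(g_at_limit = "gene", g_above = "gene",
                mi_one_high = "miRNA", mi_low = "miRNA")
  )
  kept <- filter_low_expression(p$tumor, p$adjacent)
  expect_setequal(kept, c("g_above", "mi_one_high"))

  zero <- toy_pair(list(a = c(0, 0)), list(a = c(0, 0)), c(a = "gene"))
  expect_length(filter_low_expression(zero$tumor, zero$adjacent), 0)
})

test_that("signal statistics M and D match direct computation", {
  p <- toy_pair(
    tumor_vals = list(same = c(10, 10), doubled = c(200, 200),
                      f3 = c(30, 50), f4 = c(5, 15)),
    adjacent_vals = list(same = c(10, 10), doubled = c(100, 100),
                         f3 = c(10, 10), f4 = c(40, 40)),
    classes = c(same = "gene", doubled = "gene", f3 = "gene", f4 = "gene")
  )
  sig <- compute_signal(p$tumor, p$adjacent, rownames(p$tumor$values), k = 0.5)
  expect_equal(sig$M[sig$feature == "same"], 0)
  expect_equal(sig$D[sig$feature == "same"], 0)
  expect_equal(sig$M[sig$feature == "doubled"], log2(200.5 / 100.5))
  # frozen hand computations: means (40, 10) and (10, 40)
  expect_equal(sig$M[sig$feature == "f3"], log2(40.5 / 10.5))
  expect_equal(sig$D[sig$feature == "f3"], 30)
  expect_equal(sig$M[sig$feature == "f4"], log2(10.5 / 40.5))
  expect_equal(sig$D[sig$feature == "f4"], 30)
})

test_that("noise distribution pools all within-condition pairs", {
  p <- toy_pair(
    tumor_vals = list(a = c(5, 5, 5, 5), b = c(1, 2, 3, 4)),
    adjacent_vals = list(a = c(5, 5, 5, 5), b = c(4, 3, 2, 1)),
    classes = c(a = "gene", b = "gene")
  )
  noise <- noise_distribution(p$tumor, p$adjacent, c("a", "b"), max_pairs = 100)
  # 2 features x (C(4,2) pairs x 2 conditions) points
  expect_equal(nrow(noise), 2 * 6 * 2)
  # the constant feature contributes exactly (0, 0) points
  expect_equal(sum(noise$abs_m == 0 & noise$d == 0), 12)

  ident <- toy_pair(list(x = c(7, 7)), list(x = c(7, 7)), c(x = "gene"))
  n0 <- noise_distribution(ident$tumor, ident$adjacent, "x")
  expect_true(all(n0$abs_m == 0) && all(n0$d == 0))

  single <- toy_pair(list(x = 7), list(x = 7), c(x = "gene"))
  expect_error(noise_distribution(single$tumor, single$adjacent, "x"), ">= 2")
})

test_that("pair subsampling is deterministic and order-invariant", {
  co <- simulate_cohort(sim_config(n_genes = 20, n_tfs = 4, n_mirnas = 4,
                                   n_pairs = 12, seed = 1))
  feats <- rownames(co$tumor$values)
  n1 <- noise_distribution(co$tumor, co$adjacent, feats, max_pairs = 10, seed = 3)
  n2 <- noise_distribution(co$tumor, co$adjacent, feats, max_pairs = 10, seed = 3)
  expect_identical(n1, n2)
  shuf <- co$tumor
  shuf$values <- shuf$values[, sample(ncol(shuf$values))]
  n3 <- noise_distribution(shuf, co$adjacent, feats, max_pairs = 10, seed = 3)
  expect_equal(sort(n3$d), sort(n1$d))
})

test_that("empirical DE probability counts strictly dominated noise points", {
  noise <- tibble::tibble(abs_m = c(0.1, 0.2, 0.3, 1.0, 2.0),
                          d = c(1, 2, 3, 10, 20))
  sig <- tibble::tibble(feature = c("dom", "zero", "mid"),
                        class = "gene",
                        M = c(5, 0, 0.5), D = c(100, 50, 5))
  out <- de_probability(sig, noise)
  expect_equal(out$prob, c(1, 0, 3 / 5))
  expect_error(de_probability(sig, noise[0, ]), "empty")
})

test_that("DE calls honor class fold-change cutoffs and strict prob", {
  de <- tibble::tibble(
    feature = c("tf1", "g1", "edge", "down"),
    class = c("TF", "gene", "gene", "miRNA"),
    M = c(log2(1.7), log2(1.7), 1.5, -2),
    prob = c(0.995, 0.995, 0.99, 0.995)
  )
  out <- call_de(de, de_thresholds())
  expect_identical(out$status, c("up", "not-DE", "not-DE", "down"))
  expect_error(call_de(dplyr::mutate(de, class = "lncRNA")), "unknown feature class")
  # log2-scale interpretation flag
  out2 <- call_de(dplyr::mutate(de, prob = 0.999),
                  de_thresholds(fc_cutoff_gene = 1, fc_cutoff_tf_mirna = 1,
                                fc_scale = "log2"))
  expect_identical(out2$status[2], "not-DE")  # |M| = 0.77 < 1
  expect_identical(out2$status[3], "up")      # |M| = 1.5 >= 1
})

test_that("prob is monotone in |M| and D against a fixed noise set", {
  withr::with_seed(42, {
    noise <- tibble::tibble(abs_m = abs(rnorm(500)), d = abs(rnorm(500, sd = 10)))
    base <- tibble::tibble(feature = "f", class = "gene", M = 0.5, D = 5)
    p0 <- de_probability(base, noise)$prob
    for (i in 1:20) {
      up <- tibble::tibble(feature = "f", class = "gene",
                           M = 0.5 + runif(1), D = 5 + runif(1, 0, 10))
      expect_gte(de_probability(up, noise)$prob, p0)
    }
  })
})

test_that("swapping condition labels flips M and preserves prob", {
  co <- simulate_cohort(sim_config(n_genes = 30, n_tfs = 5, n_mirnas = 5,
                                   n_pairs = 10, seed = 2))
  fwd <- diff_expression(co$tumor, co$adjacent)
  swapped_tumor <- co$adjacent
  swapped_tumor$condition <- "tumor"
  swapped_adj <- co$tumor
  swapped_adj$condition <- "adjacent"
  rev <- diff_expression(swapped_tumor, swapped_adj)
  expect_equal(rev$table$M, -fwd$table$M)
  expect_equal(rev$table$prob, fwd$table$prob)
})

test_that("tidy and glance summarize a DE fit", {
  co <- simulate_cohort(sim_config(n_genes = 30, n_tfs = 5, n_mirnas = 5,
                                   n_pairs = 6, seed = 2))
  de <- diff_expression(co$tumor, co$adjacent)
  expect_s3_class(tidy(de), "tbl_df")
  g <- glance(de)
  expect_equal(g$n_tested, nrow(tidy(de)))
  expect_equal(g$n_up, sum(tidy(de)$status == "up"))
  expect_s3_class(autoplot(de), "ggplot")
})
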