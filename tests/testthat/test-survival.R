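rec <- function(time, event) tibble::tibble(time = time, event = event)

test_that("product-limit estimator matches hand computation", {
  all_cens <- km_estimate(rec(c(2, 5, 9), c(0, 0, 0)))
  expect_true(all(all_cens$surv == 1))

  km <- km_estimate(rec(c(1, 2, 3), c(1, 0, 1)))
  expect_equal(km$surv[km$time == 1], 2 / 3)
  expect_equal(km$surv[km$time == 3], 0)

  # duplicating every record leaves the curve unchanged
  km2 <- km_estimate(rec(rep(c(1, 2, 3), 2), rep(c(1, 0, 1), 2)))
  expect_equal(km2$surv[km2$time %in% c(1, 3)], km$surv[km$time %in% c(1, 3)])

  expect_error(km_estimate(rec(numeric(), integer())), "no survival records")
  expect_error(km_estimate(rec(-1, 1)), ">= 0")
})

test_that("KM curves are monotone non-increasing on random inputs", {
  withr::with_seed(23, {
    for (rep in 1:10) {
      n <- sample(5:40, 1)
      km <- km_estimate(rec(rexp(n, 0.1), rbinom(n, 1, 0.6)))
      expect_true(all(diff(km$surv) <= 1e-12))
      expect_true(all(km$surv >= 0 & km$surv <= 1))
    }
  })
})

test_that("log-rank test matches the hand E/V oracle and its symmetries", {
  a <- rec(c(3, 6, 8, 12, 15), c(1, 1, 0, 1, 0))
  b <- rec(c(2, 4, 5, 9, 10), c(1, 1, 1, 1, 0))
  lr <- logrank_test(a, b)
  ora <- oracle_logrank(a, b)
  expect_equal(lr$chisq, ora$chisq, tolerance = 1e-10)
  expect_equal(lr$p, ora$p, tolerance = 1e-10)
  expect_equal(sum(lr$observed), sum(lr$expected), tolerance = 1e-10)

  same <- logrank_test(a, a)
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  sw <- logrank_test(b, a)
  expect_equal(sw$chisq, lr$chisq, tolerance = 1e-10)
  expect_equal(sw$p, lr$p, tolerance = 1e-10)

  expect_warning(none <- logrank_test(rec(c(1, 2), c(0, 0)), rec(3, 0)),
                 "no events")
  expect_equal(none$p, 1)
  expect_error(logrank_test(a, a[0, ]), "nonempty")
})

test_that("quartile grouping is rank-exact: 83 per arm at n = 332", {
  withr::with_seed(3, x <- stats::setNames(runif(332), sprintf("s%03d", 1:332)))
  grp <- quartile_groups(x)
  expect_length(grp$low, 83)
  expect_length(grp$high, 83)
  expect_lt(max(x[grp$low]), min(x[grp$high]))

  g8 <- quartile_groups(stats::setNames(1:8, letters[1:8]))
  expect_length(g8$low, 2)
  expect_length(g8$high, 2)
  expect_error(quartile_groups(stats::setNames(1:7, letters[1:7])), ">= 8")

  # invariant to sample order
  shuf <- x[sample(length(x))]
  expect_equal(quartile_groups(shuf), grp)
})

test_that("median combination grouping reproduces the best/worst contrast", {
  withr::with_seed(9, {
    n <- 400
    m <- rbind(mir = runif(n), tf = runif(n), gene = runif(n))
    colnames(m) <- sprintf("s%03d", 1:n)
    dirs <- c(mir = "low", tf = "high", gene = "high")
    grp <- combination_groups(m, dirs)
    med <- apply(m, 1, median)
    manual_best <- colnames(m)[m["mir", ] <= med["mir"] & m["tf", ] > med["tf"] &
                                 m["gene", ] > med["gene"]]
    expect_setequal(grp$best, manual_best)
    # independent genes: each arm holds about 1/8 of samples
    expect_lt(abs(length(grp$best) / n - 1 / 8), 3 * sqrt(7 / 64 / n))
    expect_lt(abs(length(grp$worst) / n - 1 / 8), 3 * sqrt(7 / 64 / n))

    # perfectly correlated genes with concordant directions cover ~everything
    m2 <- rbind(g1 = m[1, ], g2 = m[1, ])
    grp2 <- combination_groups(m2, c(g1 = "low", g2 = "low"))
    expect_equal(length(grp2$best) + length(grp2$worst), n)
  })
  expect_error(
    combination_groups(rbind(a = rep(1, 10), b = runif(10)),
                       c(a = "low", b = "high")),
    "'a' has constant expression"
  )
  expect_error(combination_groups(rbind(a = 1:10), c(a = "low")), ">= 2")
})

test_that("survival report: horizon truncation, lost-to-follow-up policy, arms", {
  co <- simulate_cohort(sim_config(n_genes = 15, n_tfs = 3, n_mirnas = 3,
                                   n_pairs = 60, hazard_beta = 1,
                                   de_fraction = 0.3,
                                   lost_fraction = 0.1, seed = 8))
  tr <- co$truth$planted_ffls
  rule <- grouping_rule("multi-median",
                        stats::setNames(c("low", "high", "high"),
                                        c(tr$mirna[1], tr$tf[1], tr$gene[1])))
  far <- survival_report(co$clinical, co$tumor, rule,
                         horizon_months = max(co$clinical$time) + 1)
  untrunc <- survival_report(co$clinical, co$tumor, rule, horizon_months = NULL)
  expect_equal(far$logrank$chisq, untrunc$logrank$chisq)
  expect_equal(tidy(far), tidy(untrunc))

  # drop policy removes lost subjects; censor policy keeps them
  rule_c <- grouping_rule("multi-median", rule$directions,
                          lost_to_followup_policy = "censor")
  n_drop <- sum(lengths(far$groups))
  n_cens <- sum(lengths(survival_report(co$clinical, co$tumor, rule_c)$groups))
  expect_gte(n_cens, n_drop)

  sq <- grouping_rule("single-quartile",
                      stats::setNames("low", tr$mirna[1]))
  rep_q <- survival_report(co$clinical, co$tumor, sq, horizon_months = 60)
  n_kept <- sum(!co$clinical$lost_to_followup)
  expect_length(rep_q$groups$favorable, floor(n_kept / 4))
  expect_length(rep_q$groups$unfavorable, floor(n_kept / 4))
  g <- glance(rep_q)
  expect_true(g$p >= 0 && g$p <= 1)
  expect_s3_class(autoplot(rep_q), "ggplot")
})

test_that("tumor volume follows the half length-width-squared rule", {
  expect_equal(tumor_volume(0, 0), 0)
  expect_equal(tumor_volume(5, 0), 0)
  expect_equal(tumor_volume(2, 2), 4)
  expect_equal(tumor_volume(10, 6), 180)
  expect_equal(tumor_volume(c(2, 10), c(2, 6)), c(4, 180))
  expect_warning(tumor_volume(3, 5), "longer axis")
  expect_error(tumor_volume(-1, 0), ">= 0")
})
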