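#' Kaplan-Meier product-limit estimate
#'
#' @param records A data frame with columns `time` and `event`
#'   (1 = death, 0 = censored); e.g. a [clinical_table()].
#' @return A `km_curve`: tibble with columns `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (one row per distinct observed time; events are
#'   processed before censorings at tied times, the product-limit
#'   convention).
#' @export
km_estimate <- function(records) {
  if (nrow(records) == 0) stop_fflnet("no survival records")
  if (any(records$time < 0)) stop_fflnet("survival times must be >= 0")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  out <- tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv
  )
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' @param group_a,group_b Data frames with `time` and `event` columns.
#' @return A `logrank_result`: list with `observed` and `expected` event
#'   counts per group, `variance`, `chisq` and `p` (chi-square, 1 df). If
#'   neither group has any event the test is degenerate: `chisq = 0`,
#'   `p = 1`, with a warning.
#' @export
logrank_test <- function(group_a, group_b) {
  if (nrow(group_a) == 0 || nrow(group_b) == 0) {
    stop_fflnet("both groups must be nonempty")
  }
  df <- bind_rows(
    mutate(as_tibble(group_a)[c("time", "event")], group = "A"),
    mutate(as_tibble(group_b)[c("time", "event")], group = "B")
  )
  if (sum(df$event) == 0) {
    rlang::warn("no events in either group; log-rank test is degenerate (p = 1)")
    return(structure(list(
      observed = c(A = 0, B = 0), expected = c(A = 0, B = 0),
      variance = 0, chisq = 0, p = 1
    ), class = "logrank_result"))
  }
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chisq <- unname(sd_fit$chisq)
  v <- if (is.matrix(sd_fit$var)) sd_fit$var[1, 1] else unname(sd_fit$var)
  structure(list(
    observed = setNames(as.vector(sd_fit$obs), c("A", "B")),
    expected = setNames(as.vector(sd_fit$exp), c("A", "B")),
    variance = v,
    chisq = chisq,
    p = stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  ), class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank> chisq = %.4g (1 df), p = %.4g; O/E A: %.0f/%.2f, B: %.0f/%.2f\n",
              x$chisq, x$p, x$observed["A"], x$expected["A"],
              x$observed["B"], x$expected["B"]))
  invisible(x)
}

#' @rdname logrank_test
#' @param x A `logrank_result`.
#' @param ... Unused.
#' @export
glance.logrank_result <- function(x, ...) {
  tibble(
    observed_a = x$observed[["A"]], expected_a = x$expected[["A"]],
    observed_b = x$observed[["B"]], expected_b = x$expected[["B"]],
    variance = x$variance, chisq = x$chisq, p = x$p
  )
}

#' Single-gene quartile grouping
#'
#' Ranks samples by the gene's expression and takes the `floor(n/4)`
#' smallest as the low group and the `floor(n/4)` largest as the high
#' group (rank-based, so group sizes are exact even with ties; tied values
#' are ordered by sample id for determinism). The middle half is excluded.
#'
#' @param expr Named numeric vector of one gene's expression across the
#'   cohort (names are sample ids), or a tumor `expr_matrix` plus `gene`.
#' @param gene Gene id (required when `expr` is an `expr_matrix`).
#' @return List with character vectors `low` and `high` of sample ids.
#' @export
quartile_groups <- function(expr, gene = NULL) {
  if (inherits(expr, "expr_matrix")) {
    if (is.null(gene)) stop_fflnet("`gene` is required with an expr_matrix")
    if (!gene %in% rownames(expr$values)) stop_fflnet(sprintf("unknown gene '%s'", gene))
    expr <- expr$values[gene, ]
  }
  n <- length(expr)
  if (n < 8) stop_fflnet("quartile grouping needs >= 8 samples")
  k <- floor(n / 4)
  ord <- names(expr)[order(expr, names(expr))]
  list(low = ord[seq_len(k)], high = ord[seq.int(n - k + 1, n)])
}

#' Multi-gene median combination grouping
#'
#' Splits each gene at its cohort median (values <= median are "low"), then
#' forms the best-prognosis group (samples at the low-risk level of every
#' gene) and the worst-prognosis group (samples at the opposite level of
#' every gene); all other samples are excluded.
#'
#' @param expr A tumor `expr_matrix` or a features-by-samples numeric
#'   matrix.
#' @param directions Named character vector mapping each gene to its
#'   low-risk expression level, `"low"` or `"high"` (e.g. a growth-promoting
#'   miRNA is `"low"`, a suppressor gene `"high"`).
#' @return List with character vectors `best` and `worst` of sample ids.
#' @export
combination_groups <- function(expr, directions) {
  m <- if (inherits(expr, "expr_matrix")) expr$values else expr
  genes <- names(directions)
  if (length(genes) < 2) stop_fflnet("combination grouping needs >= 2 genes")
  if (!all(directions %in% c("low", "high"))) {
    stop_fflnet("directions must be 'low' or 'high'")
  }
  missing <- setdiff(genes, rownames(m))
  if (length(missing) > 0) {
    stop_fflnet(sprintf("gene(s) not in expression matrix: %s",
                        paste(missing, collapse = ", ")))
  }
  samples <- colnames(m)
  level <- sapply(genes, function(g) {
    x <- m[g, ]
    if (max(x) == min(x)) {
      stop_fflnet(sprintf("gene '%s' has constant expression; cannot median-split", g))
    }
    ifelse(x <= stats::median(x), "low", "high")
  })
  best_mask <- rowSums(level == matrix(directions, nrow = length(samples),
                                       ncol = length(genes), byrow = TRUE)) == length(genes)
  worst_dir <- ifelse(directions == "low", "high", "low")
  worst_mask <- rowSums(level == matrix(worst_dir, nrow = length(samples),
                                        ncol = length(genes), byrow = TRUE)) == length(genes)
  list(best = samples[best_mask], worst = samples[worst_mask])
}

#' Grouping rule for survival stratification
#'
#' @param mode `"single-quartile"` (one gene, bottom vs top expression
#'   quartile) or `"multi-median"` (two or more genes, best- vs
#'   worst-prognosis median combinations).
#' @param directions Named character vector: per gene, the low-risk
#'   expression level (`"low"`/`"high"`). Single-quartile mode uses exactly
#'   one gene.
#' @param lost_to_followup_policy `"drop"` removes lost-to-follow-up
#'   subjects; `"censor"` keeps them as censored records.
#' @return A `grouping_rule` list.
#' @export
grouping_rule <- function(mode = c("single-quartile", "multi-median"), directions,
                          lost_to_followup_policy = c("drop", "censor")) {
  mode <- match.arg(mode)
  lost_to_followup_policy <- match.arg(lost_to_followup_policy)
  if (mode == "single-quartile" && length(directions) != 1) {
    stop_fflnet("single-quartile mode uses exactly one gene")
  }
  if (mode == "multi-median" && length(directions) < 2) {
    stop_fflnet("multi-median mode needs >= 2 genes")
  }
  structure(list(mode = mode, directions = directions,
                 lost_to_followup_policy = lost_to_followup_policy),
            class = "grouping_rule")
}

apply_lost_policy <- function(clinical, policy) {
  lost <- clinical$lost_to_followup %in% TRUE
  if (policy == "drop") {
    clinical[!lost, , drop = FALSE]
  } else {
    clinical$event[lost] <- 0L
    clinical
  }
}

truncate_followup <- function(clinical, horizon) {
  if (is.null(horizon) || !is.finite(horizon)) return(clinical)
  over <- clinical$time > horizon
  clinical$event[over] <- 0L
  clinical$time[over] <- horizon
  clinical
}

#' Survival stratification report for one grouping rule
#'
#' Applies the lost-to-follow-up policy, forms the two comparison groups
#' (expression quartiles or median combinations), truncates follow-up at
#' the horizon (later events become censored at the horizon), and runs the
#' Kaplan-Meier estimator and log-rank test.
#'
#' @param clinical A [clinical_table()].
#' @param expr A tumor `expr_matrix` covering the rule's genes.
#' @param rule A [grouping_rule()].
#' @param horizon_months Follow-up truncation horizon (e.g. 60); `NULL` for
#'   no truncation.
#' @return An `ffl_survival` object: list with `groups` (sample ids per
#'   arm), `curves` (tibble of per-arm KM curves), `logrank`
#'   (`logrank_result`), `rule` and `horizon_months`. `glance()` gives the
#'   one-row summary; `autoplot()` draws the KM curves.
#' @export
survival_report <- function(clinical, expr, rule, horizon_months = NULL) {
  clin <- apply_lost_policy(as_tibble(clinical), rule$lost_to_followup_policy)
  m <- if (inherits(expr, "expr_matrix")) expr$values else expr
  shared <- intersect(clin$sample_id, colnames(m))
  clin <- clin[clin$sample_id %in% shared, , drop = FALSE]
  m <- m[, shared, drop = FALSE]
  if (rule$mode == "single-quartile") {
    gene <- names(rule$directions)
    grp <- quartile_groups(m[gene, ])
    arms <- if (rule$directions == "low") {
      list(favorable = grp$low, unfavorable = grp$high)
    } else {
      list(favorable = grp$high, unfavorable = grp$low)
    }
  } else {
    grp <- combination_groups(m, rule$directions)
    arms <- list(favorable = grp$best, unfavorable = grp$worst)
  }
  arm_records <- lapply(arms, function(ids) {
    truncate_followup(clin[clin$sample_id %in% ids, , drop = FALSE], horizon_months)
  })
  if (any(vapply(arm_records, nrow, integer(1)) == 0)) {
    stop_fflnet("a comparison group has zero samples after filtering")
  }
  curves <- imap(arm_records, function(rec, nm) mutate(km_estimate(rec), arm = nm)) |>
    bind_rows()
  lr <- logrank_test(arm_records$favorable, arm_records$unfavorable)
  structure(list(groups = arms, curves = curves, logrank = lr, rule = rule,
                 horizon_months = horizon_months), class = "ffl_survival")
}

#' @export
print.ffl_survival <- function(x, ...) {
  cat(sprintf(
    "<ffl_survival> %s: favorable n=%d vs unfavorable n=%d; log-rank p = %.4g\n",
    x$rule$mode, length(x$groups$favorable), length(x$groups$unfavorable),
    x$logrank$p
  ))
  invisible(x)
}

#' @rdname survival_report
#' @param x An `ffl_survival`.
#' @param ... Unused.
#' @export
tidy.ffl_survival <- function(x, ...) x$curves

#' @rdname survival_report
#' @export
glance.ffl_survival <- function(x, ...) {
  tibble(
    mode = x$rule$mode,
    n_favorable = length(x$groups$favorable),
    n_unfavorable = length(x$groups$unfavorable),
    horizon_months = x$horizon_months %||% NA_real_,
    chisq = x$logrank$chisq,
    p = x$logrank$p
  )
}

#' Xenograft tumor volume from caliper measurements
#'
#' `V = L * W^2 / 2`, the standard ellipsoid approximation, with `L` the
#' longer axis.
#'
#' @param L Tumor length (mm); vectorized.
#' @param W Tumor width (mm).
#' @return Volume in cubic millimetres.
#' @export
tumor_volume <- function(L, W) {
  if (any(L < 0) || any(W < 0)) stop_fflnet("lengths must be >= 0")
  if (any(W > L)) {
    rlang::warn("W > L for some measurements; L is conventionally the longer axis")
  }
  L * W^2 / 2
}
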