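#' Differential-expression thresholds
#'
#' Class-specific cutoffs for calling differential expression between tumor
#' and matched-adjacent samples: a minimum expression filter (strict `>`,
#' maximum over all samples of both conditions), an empirical
#' signal-versus-noise probability cutoff (strict `>`), and linear
#' fold-change cutoffs (genes: 2; TFs and miRNAs, being amplifying
#' regulators: 1.6).
#'
#' @param min_expr_gene Minimum expression for genes and TFs (default 20
#'   RSEM).
#' @param min_expr_mirna Minimum expression for miRNAs (default 10 RSEM).
#' @param prob_cutoff DE probability cutoff (default 0.99, strict).
#' @param fc_cutoff_gene Linear fold-change cutoff for genes (default 2).
#' @param fc_cutoff_tf_mirna Linear fold-change cutoff for TFs and miRNAs
#'   (default 1.6).
#' @param k Pseudocount added inside every log ratio (default 0.5).
#' @param fc_scale `"linear"` interprets the fold-change cutoffs on the
#'   linear scale (`2^|M| >= cutoff`); `"log2"` interprets them as log2
#'   units (`|M| >= cutoff`).
#' @return A `de_thresholds` list.
#' @export
de_thresholds <- function(min_expr_gene = 20, min_expr_mirna = 10,
                          prob_cutoff = 0.99, fc_cutoff_gene = 2,
                          fc_cutoff_tf_mirna = 1.6, k = 0.5,
                          fc_scale = c("linear", "log2")) {
  fc_scale <- match.arg(fc_scale)
  if (prob_cutoff <= 0 || prob_cutoff >= 1) stop_fflnet("`prob_cutoff` must be in (0, 1)")
  if (fc_scale == "linear" && (fc_cutoff_gene <= 1 || fc_cutoff_tf_mirna <= 1)) {
    stop_fflnet("linear fold-change cutoffs must be > 1")
  }
  if (k <= 0) stop_fflnet("pseudocount `k` must be > 0")
  structure(list(
    min_expr_gene = min_expr_gene, min_expr_mirna = min_expr_mirna,
    prob_cutoff = prob_cutoff, fc_cutoff_gene = fc_cutoff_gene,
    fc_cutoff_tf_mirna = fc_cutoff_tf_mirna, k = k, fc_scale = fc_scale
  ), class = "de_thresholds")
}

check_matched_matrices <- function(tumor, adjacent) {
  stopifnot(inherits(tumor, "expr_matrix"), inherits(adjacent, "expr_matrix"))
  if (!identical(sort(rownames(tumor$values)), sort(rownames(adjacent$values)))) {
    stop_fflnet("tumor and adjacent matrices must share the same feature set")
  }
}

#' Filter features by minimum expression
#'
#' A feature is retained iff its maximum value over all samples of both
#' conditions strictly exceeds its class threshold (genes and TFs: 20
#' RSEM by default; miRNAs: 10).
#'
#' @param tumor,adjacent `expr_matrix` objects sharing a feature set.
#' @param thresholds A [de_thresholds()].
#' @return Character vector of retained feature ids (input row order).
#' @export
filter_low_expression <- function(tumor, adjacent, thresholds = de_thresholds()) {
  check_matched_matrices(tumor, adjacent)
  feats <- rownames(tumor$values)
  mx <- pmax(
    apply(tumor$values, 1, max),
    apply(adjacent$values[feats, , drop = FALSE], 1, max)
  )
  lim <- ifelse(tumor$feature_class[feats] == "miRNA",
                thresholds$min_expr_mirna, thresholds$min_expr_gene)
  feats[mx > lim]
}

#' Per-feature signal statistics M and D
#'
#' `M = log2((mean_tumor + k) / (mean_adjacent + k))` and
#' `D = |mean_tumor - mean_adjacent|`, with unweighted arithmetic means over
#' all samples of each condition.
#'
#' @inheritParams filter_low_expression
#' @param features Features to score (must have passed the filter).
#' @param k Pseudocount.
#' @return Tibble with columns `feature`, `class`, `mean_tumor`,
#'   `mean_adjacent`, `M`, `D`.
#' @export
compute_signal <- function(tumor, adjacent, features, k = 0.5) {
  check_matched_matrices(tumor, adjacent)
  mt <- rowMeans(tumor$values[features, , drop = FALSE])
  ma <- rowMeans(adjacent$values[features, , drop = FALSE])
  tibble(
    feature = features,
    class = unname(tumor$feature_class[features]),
    mean_tumor = unname(mt), mean_adjacent = unname(ma),
    M = unname(log2((mt + k) / (ma + k))),
    D = unname(abs(mt - ma))
  )
}

#' Pooled within-condition noise distribution
#'
#' For every unordered pair of samples within each condition computes the
#' per-feature statistics `|m*| = |log2((x_i + k)/(x_j + k))|` and
#' `d* = |x_i - x_j|`, pooling across features and pairs. If a condition has
#' more than `max_pairs` pairs, a uniform subsample without replacement is
#' taken (deterministic given `seed`; conditions with equal sample counts
#' select identical pair indices, so relabeling the conditions leaves the
#' pooled set unchanged).
#'
#' @inheritParams compute_signal
#' @param max_pairs Maximum sample pairs used per condition (default 30).
#' @param seed Seed for the pair subsample.
#' @return Tibble with columns `abs_m`, `d`.
#' @export
noise_distribution <- function(tumor, adjacent, features, k = 0.5,
                               max_pairs = 30, seed = 1L) {
  check_matched_matrices(tumor, adjacent)
  one_condition <- function(m) {
    n <- ncol(m)
    if (n < 2) stop_fflnet("noise distribution needs >= 2 samples per condition")
    m <- m[, order(colnames(m)), drop = FALSE]  # canonical: invariant to input sample order
    pairs <- utils::combn(n, 2)
    if (ncol(pairs) > max_pairs) {
      keep <- with_seed(seed, sample.int(ncol(pairs), max_pairs))
      pairs <- pairs[, keep, drop = FALSE]
    }
    xi <- m[, pairs[1, ], drop = FALSE]
    xj <- m[, pairs[2, ], drop = FALSE]
    tibble(
      abs_m = as.vector(abs(log2((xi + k) / (xj + k)))),
      d = as.vector(abs(xi - xj))
    )
  }
  bind_rows(
    one_condition(tumor$values[features, , drop = FALSE]),
    one_condition(adjacent$values[features, , drop = FALSE])
  )
}

#' Empirical DE probability from signal and noise
#'
#' `prob(feature)` is the fraction of pooled noise points strictly dominated
#' by the feature's signal: `|m*| < |M|` and `d* < D`.
#'
#' @param signal Tibble from [compute_signal()].
#' @param noise Tibble from [noise_distribution()].
#' @return `signal` with a `prob` column appended.
#' @export
de_probability <- function(signal, noise) {
  if (nrow(noise) == 0) stop_fflnet("noise distribution is empty")
  am <- noise$abs_m
  d <- noise$d
  n <- length(am)
  signal$prob <- vapply(seq_len(nrow(signal)), function(i) {
    sum(am < abs(signal$M[i]) & d < signal$D[i]) / n
  }, double(1))
  signal
}

#' Call differential-expression status
#'
#' A feature is DE iff `prob > prob_cutoff` (strict) and its fold change
#' passes the class cutoff (`2^|M| >= fc_cutoff` on the linear scale, or
#' `|M| >= fc_cutoff` under `fc_scale = "log2"`); the sign of `M` sets
#' up/down.
#'
#' @param de Tibble with columns `feature`, `class`, `M`, `prob`.
#' @param thresholds A [de_thresholds()].
#' @return `de` with a `status` column (`"up"`, `"down"`, `"not-DE"`).
#' @export
call_de <- function(de, thresholds = de_thresholds()) {
  unknown <- setdiff(unique(de$class), c("gene", "TF", "miRNA"))
  if (length(unknown) > 0) {
    stop_fflnet(sprintf("unknown feature class: %s", paste(unknown, collapse = ", ")))
  }
  fc_cut <- ifelse(de$class == "gene", thresholds$fc_cutoff_gene,
                   thresholds$fc_cutoff_tf_mirna)
  fc_ok <- if (thresholds$fc_scale == "linear") 2^abs(de$M) >= fc_cut
           else abs(de$M) >= fc_cut
  is_de <- de$prob > thresholds$prob_cutoff & fc_ok & de$M != 0
  de$status <- ifelse(!is_de, "not-DE", ifelse(de$M > 0, "up", "down"))
  de
}

#' Paired tumor-versus-adjacent differential expression
#'
#' Runs the full non-parametric DE pipeline: low-expression filtering,
#' signal statistics (M, D), pooled within-condition noise, empirical DE
#' probability, and class-specific status calls.
#'
#' @inheritParams filter_low_expression
#' @param max_pairs Maximum within-condition sample pairs for the noise
#'   distribution.
#' @param seed Seed for the noise-pair subsample.
#' @return An `ffl_de` object; `tidy()` returns the per-feature table
#'   (feature, class, means, M, D, prob, status), `glance()` the call
#'   counts, `autoplot()` an M-D signal/noise plot.
#' @export
diff_expression <- function(tumor, adjacent, thresholds = de_thresholds(),
                            max_pairs = 30, seed = 1L) {
  features <- filter_low_expression(tumor, adjacent, thresholds)
  if (length(features) == 0) {
    tab <- tibble(feature = character(), class = character(),
                  mean_tumor = double(), mean_adjacent = double(),
                  M = double(), D = double(), prob = double(), status = character())
    noise <- tibble(abs_m = double(), d = double())
  } else {
    sig <- compute_signal(tumor, adjacent, features, k = thresholds$k)
    noise <- noise_distribution(tumor, adjacent, features, k = thresholds$k,
                                max_pairs = max_pairs, seed = seed)
    tab <- call_de(de_probability(sig, noise), thresholds)
  }
  structure(list(table = tab, noise = noise, thresholds = thresholds,
                 n_filtered_out = nrow(tumor$values) - length(features)),
            class = "ffl_de")
}

#' @export
print.ffl_de <- function(x, ...) {
  cat(sprintf(
    "<ffl_de> %d features tested (%d filtered out): %d up, %d down\n",
    nrow(x$table), x$n_filtered_out,
    sum(x$table$status == "up"), sum(x$table$status == "down")
  ))
  invisible(x)
}

#' @rdname diff_expression
#' @param x An `ffl_de` object.
#' @param ... Unused.
#' @export
tidy.ffl_de <- function(x, ...) x$table

#' @rdname diff_expression
#' @export
glance.ffl_de <- function(x, ...) {
  tibble(
    n_tested = nrow(x$table),
    n_filtered_out = x$n_filtered_out,
    n_up = sum(x$table$status == "up"),
    n_down = sum(x$table$status == "down"),
    n_noise_points = nrow(x$noise),
    prob_cutoff = x$thresholds$prob_cutoff
  )
}
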