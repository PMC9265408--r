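#' Expression matrix container
#'
#' A features-by-samples table of RSEM-normalized expression values with a
#' feature class (`gene`, `TF` or `miRNA`) attached to every row and a
#' condition label (`tumor` or `adjacent`) attached to the whole matrix.
#' Values must be non-negative and finite; feature and sample ids must be
#' unique.
#'
#' @param values Numeric matrix, features in rows (rownames are feature ids),
#'   samples in columns (colnames are sample ids).
#' @param feature_class Named character vector mapping every feature id to
#'   one of `"gene"`, `"TF"`, `"miRNA"`.
#' @param condition `"tumor"` or `"adjacent"`.
#' @param pairing Optional tibble with columns `tumor`, `adjacent` recording
#'   which tumor sample is matched to which adjacent sample.
#'
#' @return An `expr_matrix` object.
#' @export
expression_matrix <- function(values, feature_class, condition = c("tumor", "adjacent"),
                              pairing = NULL) {
  condition <- match.arg(condition)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_fflnet("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_fflnet("`values` must carry feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop_fflnet(sprintf(
      "duplicated feature id(s): %s",
      paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", ")
    ), class = "fflnet_duplicate_id")
  }
  if (anyDuplicated(colnames(values))) {
    stop_fflnet("duplicated sample id(s)", class = "fflnet_duplicate_id")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)[1, ]
    stop_fflnet(sprintf(
      "expression values must be finite and >= 0; offending cell at feature '%s', sample '%s'",
      rownames(values)[bad[1]], colnames(values)[bad[2]]
    ), class = "fflnet_bad_value")
  }
  missing_class <- setdiff(rownames(values), names(feature_class))
  if (length(missing_class) > 0) {
    stop_fflnet(sprintf(
      "no feature class for: %s", paste(head(missing_class, 5), collapse = ", ")
    ), class = "fflnet_missing_class")
  }
  cls <- feature_class[rownames(values)]
  if (!all(cls %in% c("gene", "TF", "miRNA"))) {
    stop_fflnet("feature classes must be one of 'gene', 'TF', 'miRNA'")
  }
  structure(
    list(values = values, feature_class = cls, condition = condition, pairing = pairing),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d features x %d samples (%s)\n  classes: %s\n",
    nrow(x$values), ncol(x$values), x$condition,
    paste(sprintf("%s=%d", names(table(x$feature_class)), table(x$feature_class)), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Tidy an expression matrix into long format
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `feature`, `class`, `sample`, `condition`,
#'   `value`, one row per cell.
#' @export
tidy.expr_matrix <- function(x, ...) {
  tibble(
    feature = rep(rownames(x$values), times = ncol(x$values)),
    class = rep(unname(x$feature_class), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    condition = x$condition,
    value = as.vector(x$values)
  )
}

allowed_evidence_levels <- c("ChIP-Seq", "TargetScan", "experimental", "predicted")

#' Construct and validate an interaction catalog
#'
#' Typed directed regulator-to-target edges with evidence labels. Self-edges,
#' duplicate (regulator, target, evidence) rows and miRNA-to-miRNA edges are
#' rejected.
#'
#' @param edges A data frame with columns `regulator`, `regulator_class`
#'   (`TF`/`miRNA`), `target`, `target_class` (`gene`/`TF`/`miRNA`),
#'   `evidence` (one of `ChIP-Seq`, `TargetScan`, `experimental`,
#'   `predicted`) and optional free-text `source`.
#' @return A validated tibble with class `interaction_catalog`.
#' @export
interaction_catalog <- function(edges) {
  edges <- as_tibble(edges)
  required <- c("regulator", "regulator_class", "target", "target_class", "evidence")
  missing <- setdiff(required, names(edges))
  if (length(missing) > 0) {
    stop_fflnet(sprintf("catalog is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!"source" %in% names(edges)) edges$source <- NA_character_
  if (!all(edges$regulator_class %in% c("TF", "miRNA"))) {
    stop_fflnet("regulator_class must be 'TF' or 'miRNA'")
  }
  if (!all(edges$target_class %in% c("gene", "TF", "miRNA"))) {
    stop_fflnet("target_class must be 'gene', 'TF' or 'miRNA'")
  }
  bad_ev <- setdiff(unique(edges$evidence), allowed_evidence_levels)
  if (length(bad_ev) > 0) {
    stop_fflnet(sprintf(
      "unknown evidence label(s) %s; allowed: %s",
      paste(sQuote(bad_ev), collapse = ", "),
      paste(allowed_evidence_levels, collapse = ", ")
    ), class = "fflnet_bad_evidence")
  }
  if (any(edges$regulator == edges$target)) {
    stop_fflnet("self-edges are not allowed in the catalog", class = "fflnet_self_edge")
  }
  if (anyDuplicated(edges[c("regulator", "target", "evidence")])) {
    stop_fflnet("duplicate (regulator, target, evidence) rows", class = "fflnet_duplicate_edge")
  }
  if (any(edges$regulator_class == "miRNA" & edges$target_class == "miRNA")) {
    stop_fflnet("miRNAs may not target miRNAs", class = "fflnet_bad_edge")
  }
  class(edges) <- c("interaction_catalog", class(tibble()))
  edges
}

#' Construct and validate a clinical survival table
#'
#' @param records A data frame with columns `sample_id`, `time` (months,
#'   finite, >= 0), `event` (1 = death, 0 = censored) and optional logical
#'   `lost_to_followup`.
#' @return A validated tibble with class `clinical_table`.
#' @export
clinical_table <- function(records) {
  records <- as_tibble(records)
  required <- c("sample_id", "time", "event")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop_fflnet(sprintf("clinical table missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!"lost_to_followup" %in% names(records)) records$lost_to_followup <- FALSE
  records$lost_to_followup <- as.logical(records$lost_to_followup)
  if (anyDuplicated(records$sample_id)) {
    stop_fflnet("duplicated sample_id in clinical table", class = "fflnet_duplicate_id")
  }
  if (any(!is.finite(records$time)) || any(records$time < 0)) {
    stop_fflnet("survival times must be finite and >= 0", class = "fflnet_bad_value")
  }
  if (!all(records$event %in% c(0, 1))) {
    stop_fflnet("event must be 0 (censored) or 1 (death)", class = "fflnet_bad_value")
  }
  class(records) <- c("clinical_table", class(tibble()))
  records
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose header row holds sample ids and whose
#' first column holds feature ids, plus a two-column class map
#' (`feature`, `class`) assigning `gene`/`TF`/`miRNA` to every feature.
#' Empty or non-numeric cells are an error (missing expression values are not
#' silently coerced).
#'
#' @param path Path to the expression TSV.
#' @param class_map Path to a class-map TSV, or a data frame with columns
#'   `feature` and `class`.
#' @param condition `"tumor"` or `"adjacent"`.
#' @param pairing Optional pairing tibble (see [expression_matrix()]).
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, class_map, condition = c("tumor", "adjacent"),
                            pairing = NULL) {
  condition <- match.arg(condition)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) stop_fflnet(sprintf("'%s': expected feature id column plus >= 1 sample", path))
  feats <- raw[[1]]
  mat <- as.matrix(raw[-1])
  num <- suppressWarnings(apply(mat, 2, as.numeric))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(mat), dimnames = dimnames(mat))
  bad <- which(is.na(num) | is.na(mat) | mat == "", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_fflnet(sprintf(
      "'%s': malformed numeric cell at feature '%s', sample '%s'",
      path, feats[bad[1, 1]], colnames(mat)[bad[1, 2]]
    ), class = "fflnet_bad_value")
  }
  rownames(num) <- feats
  if (is.character(class_map)) {
    class_map <- readr::read_tsv(class_map, col_types = "cc", progress = FALSE)
  }
  cls <- setNames(class_map$class, class_map$feature)
  expression_matrix(num, cls, condition = condition, pairing = pairing)
}

#' Write an expression matrix to TSV (rows sorted by feature id)
#'
#' @param x An `expr_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  ord <- order(rownames(x$values))
  df <- tibble(feature = rownames(x$values)[ord])
  df <- bind_cols(df, as_tibble(x$values[ord, , drop = FALSE]))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Write the feature class map to TSV
#' @param x An `expr_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_class_map <- function(x, path) {
  df <- tibble(feature = names(x$feature_class), class = unname(x$feature_class)) |>
    arrange(.data$feature)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read an interaction catalog from TSV
#'
#' @param path TSV with columns `regulator`, `regulator_class`, `target`,
#'   `target_class`, `evidence`, optional `source`.
#' @return An `interaction_catalog` tibble.
#' @export
read_catalog <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  interaction_catalog(df)
}

#' Write an interaction catalog to TSV (sorted rows)
#' @param catalog An `interaction_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  df <- as_tibble(catalog) |>
    arrange(.data$regulator, .data$target, .data$evidence)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a clinical survival table from TSV
#'
#' @param path TSV with columns `sample_id`, `time`, `event`, optional
#'   `lost_to_followup`. Lost-to-follow-up rows are retained here; dropping
#'   or censoring them is a survival-analysis policy.
#' @return A `clinical_table` tibble.
#' @export
read_clinical <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    time = readr::col_double(),
    event = readr::col_integer(),
    .default = readr::col_logical()
  ), progress = FALSE)
  clinical_table(df)
}

#' Write a clinical table to TSV (sorted by sample id)
#' @param clinical A `clinical_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_tsv(arrange(as_tibble(clinical), .data$sample_id), path, progress = FALSE)
  invisible(path)
}

#' Read a per-feature covariate table (methylation beta or CNV) from TSV
#' @param path TSV with first column `feature`, remaining columns samples.
#' @return A tibble (long format: feature, sample, value).
#' @export
read_covariate <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    feature = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (ncol(df) == 1) {
    return(tibble(feature = character(), sample = character(), value = double()))
  }
  tidyr::pivot_longer(df, -"feature", names_to = "sample", values_to = "value")
}

#' Write a per-feature covariate table to TSV
#' @param cov Long tibble (feature, sample, value) or wide data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_covariate <- function(cov, path) {
  if (all(c("feature", "sample", "value") %in% names(cov)) && nrow(cov) > 0) {
    cov <- tidyr::pivot_wider(cov, names_from = "sample", values_from = "value")
  } else if (nrow(cov) == 0) {
    cov <- tibble(feature = character())
  }
  readr::write_tsv(arrange(as_tibble(cov), .data$feature), path, progress = FALSE)
  invisible(path)
}

#' Export a regulatory network to SIF, GraphML or edge TSV
#'
#' SIF lines use the relation tokens `tf-target` / `mirna-target`. GraphML
#' carries node class, DE direction and edge evidence attributes. Edge TSV is
#' a lossless tabular dump that round-trips through [read_network_tsv()].
#'
#' @param network A `regnet` object (see [build_network()]).
#' @param path Output file path.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  edges <- arrange(network$edges, .data$regulator, .data$target)
  nodes <- arrange(network$nodes, .data$node)
  if (format == "sif") {
    if (nrow(edges) == 0) stop_fflnet("cannot write SIF for an empty network")
    lines <- sprintf("%s\t%s\t%s", edges$regulator, edges$edge_type, edges$target)
    writeLines(lines, path)
  } else if (format == "tsv") {
    readr::write_tsv(edges, path, progress = FALSE)
  } else {
    doc <- xml2::xml_new_root("graphml",
      xmlns = "http://graphml.graphdrawing.org/xmlns")
    for (k in list(c("class", "node", "d_class"), c("direction", "node", "d_dir"),
                   c("edge_type", "edge", "d_type"), c("evidence", "edge", "d_ev"))) {
      xml2::xml_add_child(doc, "key", id = k[3], `for` = k[2],
                          attr.name = k[1], attr.type = "string")
    }
    g <- xml2::xml_add_child(doc, "graph", id = "regnet", edgedefault = "directed")
    for (i in seq_len(nrow(nodes))) {
      n <- xml2::xml_add_child(g, "node", id = nodes$node[i])
      xml2::xml_add_child(n, "data", key = "d_class", nodes$class[i])
      xml2::xml_add_child(n, "data", key = "d_dir", nodes$direction[i])
    }
    for (i in seq_len(nrow(edges))) {
      e <- xml2::xml_add_child(g, "edge", source = edges$regulator[i],
                               target = edges$target[i])
      xml2::xml_add_child(e, "data", key = "d_type", edges$edge_type[i])
      xml2::xml_add_child(e, "data", key = "d_ev", edges$evidence[i])
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' Read a network edge TSV written by [export_network()]
#' @param path Edge TSV path.
#' @return A tibble of edges.
#' @export
read_network_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}
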