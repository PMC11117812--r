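#' All-pairs miRNA-mRNA Pearson correlation
#'
#' Normalizes each matrix by its own median-of-ratios size factors,
#' transforms to `log2(normalized + 1)` and computes the product-moment
#' correlation for every (miRNA, gene) pair over the samples in scope, with
#' the two-sided p-value from the t transform `t = r * sqrt((n-2)/(1-r^2))`
#' on `n - 2` degrees of freedom. Zero-variance features yield records with
#' `r = NA` (flagged, excluded downstream by [filter_negative()]).
#'
#' The paper-style screen computes these correlations for the differentially
#' expressed miRNAs against all genes; pass the DE miRNA IDs as
#' `mirna_features` to restrict the candidate universe.
#'
#' @param mirna_counts,mrna_counts Count tibbles sharing sample columns.
#' @param meta Sample metadata (required when `scope` is a group label).
#' @param scope `"pooled"` (all shared samples) or a group label present in
#'   `meta$group`.
#' @param mirna_features,gene_features Optional feature subsets.
#' @param normalization `"size_factors"` (default), `"libsize"` or `"none"`.
#' @param transform `"log2p1"` (log2 of normalized count + 1, the default) or
#'   `"none"` (correlate normalized counts directly).
#' @return A tibble with columns `mirna_id, gene_id, n, r, pvalue, scope`.
#' @export
correlate_pairs <- function(mirna_counts, mrna_counts, meta = NULL,
                            scope = "pooled",
                            mirna_features = NULL, gene_features = NULL,
                            normalization = c("size_factors", "libsize", "none"),
                            transform = c("log2p1", "none")) {
  normalization <- match.arg(normalization)
  transform <- match.arg(transform)
  validate_counts(mirna_counts, "mirna_counts")
  validate_counts(mrna_counts, "mrna_counts")
  shared <- intersect(names(mirna_counts)[-1], names(mrna_counts)[-1])
  if (scope != "pooled") {
    if (is.null(meta)) abort("`meta` is required for a group scope.")
    validate_meta(meta)
    shared <- intersect(shared, meta$sample_id[meta$group == scope])
  }
  if (length(shared) < 3) abort(sprintf("scope '%s' has %d shared samples; >= 3 required.",
                                        scope, length(shared)))

  prep <- function(counts, features) {
    m <- counts_to_matrix(counts)
    norm <- switch(normalization,
      size_factors = sweep(m, 2, size_factors(counts), "/"),
      libsize = sweep(m, 2, colSums(m) / mean(colSums(m)), "/"),
      none = m
    )
    norm <- norm[, shared, drop = FALSE]
    if (!is.null(features)) {
      missing <- setdiff(features, rownames(norm))
      if (length(missing) > 0) abort(sprintf("features absent from matrix: %s",
                                             paste(head(missing, 5), collapse = ", ")))
      norm <- norm[features, , drop = FALSE]
    }
    if (transform == "log2p1") log2(norm + 1) else norm
  }
  A <- prep(mirna_counts, mirna_features)
  B <- prep(mrna_counts, gene_features)

  n <- length(shared)
  sdA <- apply(A, 1, sd); sdB <- apply(B, 1, sd)
  r <- suppressWarnings(cor(t(A), t(B)))
  r[sdA < 1e-12, ] <- NA_real_
  r[, sdB < 1e-12] <- NA_real_

  out <- tibble::tibble(
    mirna_id = rep(rownames(A), times = ncol(r)),
    gene_id = rep(colnames(r), each = nrow(r)),
    n = n,
    r = as.vector(r)
  )
  tstat <- out$r * sqrt((n - 2) / pmax(1 - out$r^2, .Machine$double.eps))
  out$pvalue <- pmax(2 * pt(-abs(tstat), df = n - 2), .Machine$double.xmin)
  out$pvalue[is.na(out$r)] <- NA_real_
  out$scope <- scope
  out
}

#' Keep strongly negative, significant correlations
#'
#' Applies the negative-correlation screen with strict inequalities: a record
#' survives only if `r < r_max` and `pvalue < alpha`. A correlation sitting
#' exactly at the threshold (e.g. r = -0.70) is excluded. Records with
#' undefined `r` (zero-variance features) are dropped.
#'
#' @param records Correlation tibble from [correlate_pairs()].
#' @param r_max Upper bound on r (exclusive); a positive value defeats the
#'   purpose of the screen and triggers a warning.
#' @param alpha p-value bound (exclusive).
#' @return The retained subset.
#' @export
filter_negative <- function(records, r_max = -0.7, alpha = 0.05) {
  if (r_max > 0) warn("`r_max` is positive: the screen will retain positive correlations.")
  keep <- !is.na(records$r) & records$r < r_max & records$pvalue < alpha
  records[keep, , drop = FALSE]
}

#' Intersect correlation records with miRNA-target evidence
#'
#' Joins each correlation record against the evidence table on the miRNA
#' (mature ID or accession, case-insensitive) and the gene symbol
#' (case-insensitive), and emits an interaction edge when the pair is backed
#' by a validated row (if `accept_validated`) or by at least
#' `min_predicted_dbs` distinct prediction databases. Pairs without evidence
#' produce no edge. The result does not depend on evidence row order.
#'
#' @param records Correlation tibble (typically already passed through
#'   [filter_negative()]).
#' @param evidence Evidence tibble in the [read_evidence()] schema.
#' @param min_predicted_dbs Minimum number of distinct prediction databases.
#' @param accept_validated Whether a single validated row suffices.
#' @return An edge tibble with columns `mirna_id, gene_id, n, r, pvalue,
#'   validated, n_predicted_dbs, evidence` (list column of matching evidence
#'   rows, ordered by database then type).
#' @export
merge_evidence <- function(records, evidence, min_predicted_dbs = 1,
                           accept_validated = TRUE) {
  evidence <- validate_evidence(evidence)
  if (nrow(records) == 0) {
    return(tibble::tibble(mirna_id = character(0), gene_id = character(0),
                          n = integer(0), r = numeric(0), pvalue = numeric(0),
                          validated = logical(0), n_predicted_dbs = integer(0),
                          evidence = list()))
  }
  ev <- dplyr::mutate(evidence,
                      .mid = tolower(.data$mirna_id),
                      .mac = tolower(.data$mirna_acc),
                      .sym = toupper(.data$target_symbol))
  ev <- dplyr::arrange(ev, .data$database, .data$type, .data$target_symbol)
  rec <- dplyr::mutate(records,
                       .mkey = tolower(.data$mirna_id),
                       .gkey = toupper(.data$gene_id))
  purrr::map_dfr(seq_len(nrow(rec)), function(i) {
    hits <- ev[(ev$.mid == rec$.mkey[i] | ev$.mac == rec$.mkey[i]) &
                 ev$.sym == rec$.gkey[i], , drop = FALSE]
    if (nrow(hits) == 0) return(NULL)
    validated <- any(hits$type == "validated")
    npred <- dplyr::n_distinct(hits$database[hits$type == "predicted"])
    if (!((validated && accept_validated) || npred >= min_predicted_dbs)) return(NULL)
    tibble::tibble(
      mirna_id = rec$mirna_id[i], gene_id = rec$gene_id[i],
      n = rec$n[i] %||% NA_integer_, r = rec$r[i] %||% NA_real_,
      pvalue = rec$pvalue[i] %||% NA_real_,
      validated = validated, n_predicted_dbs = npred,
      evidence = list(dplyr::select(hits, -dplyr::starts_with(".")))
    )
  })
}

#' Assemble the bipartite miRNA-gene interaction network
#'
#' Collapses duplicate (miRNA, gene) edges (merging their evidence), builds a
#' bipartite igraph with node direction attributes taken from the sign of the
#' DE log2 fold change, and reports a size summary. Edges referencing
#' features absent from the DE tables get direction `"unknown"` with a
#' warning.
#'
#' @param edges Edge tibble from [merge_evidence()].
#' @param de_mrna,de_mirna Optional `mirlink_de` tibbles used to annotate
#'   node directions (`"up"` / `"down"`, first contrast level vs second).
#' @return A list of class `mirlink_network` with elements `graph` (igraph),
#'   `nodes`, `edges` (tibbles) and `summary` (one-row tibble with
#'   `n_mirnas`, `n_genes`, `n_edges`).
#' @export
build_network <- function(edges, de_mrna = NULL, de_mirna = NULL) {
  if (nrow(edges) == 0) {
    g <- igraph::make_empty_graph(directed = FALSE)
    out <- list(graph = g,
                nodes = tibble::tibble(name = character(0), kind = character(0),
                                       direction = character(0)),
                edges = edges,
                summary = tibble::tibble(n_mirnas = 0L, n_genes = 0L, n_edges = 0L))
    class(out) <- "mirlink_network"
    return(out)
  }
  merged <- edges |>
    dplyr::group_by(.data$mirna_id, .data$gene_id) |>
    dplyr::summarise(
      n = .data$n[1], r = .data$r[1], pvalue = .data$pvalue[1],
      validated = any(.data$validated),
      evidence = list(dplyr::bind_rows(.data$evidence) |> dplyr::distinct()),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_predicted_dbs = purrr::map_int(
      .data$evidence, ~ dplyr::n_distinct(.x$database[.x$type == "predicted"])
    ))

  direction_of <- function(ids, de) {
    if (is.null(de)) return(rep("unknown", length(ids)))
    idx <- match(ids, de$feature_id)
    dir <- ifelse(is.na(idx), "unknown",
                  ifelse(de$log2fc[idx] > 0, "up",
                         ifelse(de$log2fc[idx] < 0, "down", "unknown")))
    dir
  }
  mirnas <- unique(merged$mirna_id)
  genes <- unique(merged$gene_id)
  mdir <- direction_of(mirnas, de_mirna)
  gdir <- direction_of(genes, de_mrna)
  if ((!is.null(de_mirna) && any(mdir == "unknown")) ||
      (!is.null(de_mrna) && any(gdir == "unknown"))) {
    warn("some network nodes are absent from the DE tables; direction set to 'unknown'.")
  }
  nodes <- tibble::tibble(
    name = c(mirnas, genes),
    kind = c(rep("mirna", length(mirnas)), rep("gene", length(genes))),
    direction = c(mdir, gdir)
  )
  edge_attr <- merged |>
    dplyr::mutate(evidence_dbs = purrr::map_chr(
      .data$evidence, ~ paste(sort(unique(.x$database)), collapse = ";")
    ))
  g <- igraph::graph_from_data_frame(
    dplyr::select(edge_attr, from = "mirna_id", to = "gene_id",
                  "r", "pvalue", "validated", "n_predicted_dbs", "evidence_dbs"),
    directed = FALSE,
    vertices = as.data.frame(dplyr::mutate(nodes, type = .data$kind == "gene"))
  )
  out <- list(
    graph = g, nodes = nodes, edges = merged,
    summary = tibble::tibble(n_mirnas = length(mirnas), n_genes = length(genes),
                             n_edges = nrow(merged))
  )
  class(out) <- "mirlink_network"
  out
}

#' @export
print.mirlink_network <- function(x, ...) {
  cat(sprintf("mirlink bipartite network: %d miRNAs, %d genes, %d edges\n",
              x$summary$n_mirnas, x$summary$n_genes, x$summary$n_edges))
  invisible(x)
}
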