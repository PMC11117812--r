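#' Pipeline configuration
#'
#' Bundles the thresholds and options of the full analysis: differential
#' expression of both matrices, ranking + gene-set enrichment, the
#' correlation screen restricted to DE miRNAs, evidence intersection and
#' network assembly.
#'
#' @param lfc_min Absolute log2-fold-change threshold (exclusive).
#' @param alpha DE significance threshold (exclusive), applied to `padj`
#'   when `use_adjusted`.
#' @param use_adjusted Gate DE on BH-adjusted p-values (the headline screen)
#'   or raw p-values.
#' @param r_max Correlation threshold (exclusive; records with `r < r_max`
#'   survive). A positive value triggers a warning at run time.
#' @param cor_alpha Correlation p-value threshold (exclusive, raw — the
#'   screen applies no multiplicity correction, though a BH column is added
#'   for transparency).
#' @param min_predicted_dbs Distinct prediction databases required when no
#'   validated evidence exists.
#' @param accept_validated Whether one validated row suffices.
#' @param scope Correlation scope: `"pooled"` or a group label.
#' @param n_perm,min_size,max_size GSEA options (enrichment runs only when
#'   gene sets are supplied).
#' @param seed Integer seed covering every stochastic stage.
#' @return A list of class `mirlink_pipeline_config`.
#' @export
pipeline_config <- function(lfc_min = 0.5, alpha = 0.05, use_adjusted = TRUE,
                            r_max = -0.7, cor_alpha = 0.05,
                            min_predicted_dbs = 1, accept_validated = TRUE,
                            scope = "pooled", n_perm = 1000,
                            min_size = 5, max_size = 500, seed = 1L) {
  if (lfc_min < 0) abort("`lfc_min` must be >= 0.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (cor_alpha <= 0 || cor_alpha >= 1) abort("`cor_alpha` must lie in (0, 1).")
  structure(list(
    lfc_min = lfc_min, alpha = alpha, use_adjusted = use_adjusted,
    r_max = r_max, cor_alpha = cor_alpha,
    min_predicted_dbs = min_predicted_dbs, accept_validated = accept_validated,
    scope = scope, n_perm = n_perm, min_size = min_size, max_size = max_size,
    seed = as.integer(seed)
  ), class = "mirlink_pipeline_config")
}

#' Run the full paired miRNA-mRNA analysis
#'
#' Stage order: DE on the mRNA matrix, DE on the miRNA matrix, effect/
#' significance filtering, ranking and (optionally) pre-ranked GSEA,
#' all-pairs correlation of the DE miRNAs against all genes, the negative-
#' correlation filter, evidence intersection, and bipartite network assembly.
#' No stage mutates its inputs; when `out_dir` is given every intermediate is
#' also written as a TSV/GraphML artifact re-readable by the package's
#' readers, and the manifest records a content digest per artifact so that
#' identical configuration + inputs yield identical manifests.
#'
#' @param mrna,mirna Count tibbles over shared samples.
#' @param meta Sample metadata (`sample_id`, `group`).
#' @param evidence Evidence tibble ([read_evidence()] schema).
#' @param gene_sets Optional named list of gene sets for enrichment.
#' @param config A [pipeline_config()].
#' @param contrast Two group labels, first vs second; defaults to the order
#'   of appearance in `meta`.
#' @param out_dir Optional output directory.
#' @return A list of class `mirlink_run` with elements `de_mrna, de_mirna,
#'   de_mrna_sig, de_mirna_sig, ranking, gsea (or NULL), correlations,
#'   correlations_neg, edges, network, manifest`.
#' @export
run_pipeline <- function(mrna, mirna, meta, evidence, gene_sets = NULL,
                         config = pipeline_config(), contrast = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "mirlink_pipeline_config"))
  if (config$r_max > 0) {
    warn("`r_max` is positive: the negative-correlation screen is effectively disabled.")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  de_mrna <- stage("de_mrna", de_test(mrna, meta, contrast = contrast))
  de_mirna <- stage("de_mirna", de_test(mirna, meta, contrast = contrast))
  de_mrna_sig <- stage("filter_de_mrna",
                       filter_de(de_mrna, config$lfc_min, config$alpha, config$use_adjusted))
  de_mirna_sig <- stage("filter_de_mirna",
                        filter_de(de_mirna, config$lfc_min, config$alpha, config$use_adjusted))
  ranking <- stage("rank", rank_genes(de_mrna, metric = "signed_lfc"))
  gsea <- NULL
  if (!is.null(gene_sets)) {
    gsea <- stage("gsea", gsea_preranked(ranking, gene_sets, n_perm = config$n_perm,
                                         seed = child_seed(config$seed, 11L),
                                         min_size = config$min_size,
                                         max_size = config$max_size))
  }
  correlations <- if (nrow(de_mirna_sig) > 0) {
    stage("correlate", correlate_pairs(mirna, mrna, meta = meta, scope = config$scope,
                                       mirna_features = de_mirna_sig$feature_id))
  } else {
    tibble::tibble(mirna_id = character(0), gene_id = character(0),
                   n = integer(0), r = numeric(0), pvalue = numeric(0),
                   scope = character(0))
  }
  correlations$padj <- p.adjust(correlations$pvalue, method = "BH")
  correlations_neg <- stage("filter_negative",
                            filter_negative(correlations, config$r_max, config$cor_alpha))
  edges <- stage("merge_evidence",
                 merge_evidence(correlations_neg, evidence,
                                min_predicted_dbs = config$min_predicted_dbs,
                                accept_validated = config$accept_validated))
  network <- stage("network", build_network(edges, de_mrna = de_mrna, de_mirna = de_mirna))

  result <- list(
    de_mrna = de_mrna, de_mirna = de_mirna,
    de_mrna_sig = de_mrna_sig, de_mirna_sig = de_mirna_sig,
    ranking = ranking, gsea = gsea,
    correlations = correlations, correlations_neg = correlations_neg,
    edges = edges, network = network
  )

  manifest <- tibble::tibble(
    stage = c("config", "de_mrna", "de_mirna", "de_mrna_sig", "de_mirna_sig",
              "ranking", "gsea", "correlations", "correlations_neg", "edges",
              "network"),
    digest = vapply(list(unclass(config), de_mrna, de_mirna, de_mrna_sig,
                         de_mirna_sig, ranking,
                         if (is.null(gsea)) "none" else dplyr::select(gsea, -"leading_edge"),
                         correlations, correlations_neg,
                         dplyr::select(edges, -dplyr::any_of("evidence")),
                         network$summary),
                    rlang::hash, "")
  )
  result$manifest <- manifest

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_de(de_mrna, file.path(out_dir, "de_mrna.tsv"))
    write_de(de_mirna, file.path(out_dir, "de_mirna.tsv"))
    write_correlations(correlations, file.path(out_dir, "correlations.tsv"))
    write_correlations(correlations_neg, file.path(out_dir, "correlations_negative.tsv"))
    write_network(network, file.path(out_dir, "network.graphml"), "graphml")
    write_network(network, file.path(out_dir, "network_edges.tsv"), "edge_tsv")
    readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"), progress = FALSE)
  }
  class(result) <- "mirlink_run"
  result
}

#' @export
print.mirlink_run <- function(x, ...) {
  cat("mirlink pipeline run\n")
  cat(sprintf("  DE mRNAs: %d significant of %d\n", nrow(x$de_mrna_sig), nrow(x$de_mrna)))
  cat(sprintf("  DE miRNAs: %d significant of %d\n", nrow(x$de_mirna_sig), nrow(x$de_mirna)))
  cat(sprintf("  negative correlations: %d of %d tested pairs\n",
              nrow(x$correlations_neg), nrow(x$correlations)))
  cat(sprintf("  network: %d miRNAs, %d genes, %d edges\n",
              x$network$summary$n_mirnas, x$network$summary$n_genes,
              x$network$summary$n_edges))
  invisible(x)
}
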