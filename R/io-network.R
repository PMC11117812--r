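#' Write an interaction network to disk
#'
#' Supported formats: `"graphml"` (via igraph; node `kind`/`direction` and
#' edge `r`/`pvalue`/`validated`/`n_predicted_dbs`/`evidence_dbs` attributes
#' are preserved), `"edge_tsv"` (flat edge list with node directions joined
#' in) and `"json"` (nodes + edges arrays).
#'
#' @param network A `mirlink_network` from [build_network()].
#' @param path Output path.
#' @param format One of `"graphml"`, `"edge_tsv"`, `"json"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "edge_tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "mirlink_network"))
  flat_edges <- network$edges |>
    dplyr::mutate(evidence_dbs = purrr::map_chr(
      .data$evidence, ~ paste(sort(unique(.x$database)), collapse = ";")
    )) |>
    dplyr::select(-"evidence") |>
    dplyr::left_join(setNames(network$nodes[, c("name", "direction")],
                              c("mirna_id", "mirna_direction")), by = "mirna_id") |>
    dplyr::left_join(setNames(network$nodes[, c("name", "direction")],
                              c("gene_id", "gene_direction")), by = "gene_id")
  switch(format,
    graphml = igraph::write_graph(network$graph, path, format = "graphml"),
    edge_tsv = readr::write_tsv(flat_edges, path, progress = FALSE),
    json = jsonlite::write_json(
      list(nodes = network$nodes, edges = flat_edges, summary = network$summary),
      path, dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
  )
  invisible(path)
}

#' Read a GraphML network written by [write_network()]
#'
#' @param path Path to a GraphML file.
#' @return An igraph object.
#' @export
read_network_graphml <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  igraph::read_graph(path, format = "graphml")
}
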