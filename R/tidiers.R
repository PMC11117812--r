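#' Tidy a differential-expression result
#'
#' @param x A `mirlink_de` tibble.
#' @param ... Unused.
#' @return A plain tibble, one row per feature.
#' @method tidy mirlink_de
#' @export
tidy.mirlink_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mirlink_de")
  out
}

#' One-row summary of a differential-expression result
#'
#' @param x A `mirlink_de` tibble.
#' @param lfc_min,alpha Thresholds used for the significant-feature count.
#' @param ... Unused.
#' @return A one-row tibble: `n_features, n_tested, n_sig, n_up, n_down`.
#' @method glance mirlink_de
#' @export
glance.mirlink_de <- function(x, lfc_min = 0.5, alpha = 0.05, ...) {
  sig <- filter_de(x, lfc_min = lfc_min, alpha = alpha)
  tibble::tibble(
    n_features = nrow(x),
    n_tested = sum(!is.na(x$padj)),
    n_sig = nrow(sig),
    n_up = sum(sig$direction == "up"),
    n_down = sum(sig$direction == "down")
  )
}

#' Tidy a gene-set enrichment result
#'
#' @param x A `mirlink_gsea` tibble.
#' @param ... Unused.
#' @return A plain tibble with the leading edge collapsed to a
#'   comma-separated string.
#' @method tidy mirlink_gsea
#' @export
tidy.mirlink_gsea <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mirlink_gsea")
  dplyr::mutate(out, leading_edge = purrr::map_chr(.data$leading_edge,
                                                   paste, collapse = ","))
}

#' One-row summary of a gene-set enrichment result
#'
#' @param x A `mirlink_gsea` tibble.
#' @param alpha Adjusted-p threshold for the significant-set count.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance mirlink_gsea
#' @export
glance.mirlink_gsea <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_sets = nrow(x),
    n_sig = sum(x$padj < alpha, na.rm = TRUE),
    n_pos = sum(x$es > 0),
    n_neg = sum(x$es < 0),
    n_perm = attr(x, "n_perm") %||% NA_integer_
  )
}

#' Tidy an interaction network
#'
#' @param x A `mirlink_network`.
#' @param ... Unused.
#' @return The edge tibble with evidence databases collapsed to a string.
#' @method tidy mirlink_network
#' @export
tidy.mirlink_network <- function(x, ...) {
  dplyr::mutate(x$edges, evidence_dbs = purrr::map_chr(
    .data$evidence, ~ paste(sort(unique(.x$database)), collapse = ";")
  )) |> dplyr::select(-"evidence")
}

#' One-row summary of an interaction network
#'
#' @param x A `mirlink_network`.
#' @param ... Unused.
#' @return The `summary` tibble (`n_mirnas, n_genes, n_edges`).
#' @method glance mirlink_network
#' @export
glance.mirlink_network <- function(x, ...) x$summary
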