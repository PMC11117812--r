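#' Volcano plot of a differential-expression result
#'
#' @param object A `mirlink_de` tibble.
#' @param lfc_min,alpha Thresholds drawn as guide lines and used to colour
#'   significant features.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mirlink_de
#' @export
autoplot.mirlink_de <- function(object, lfc_min = 0.5, alpha = 0.05, ...) {
  dat <- dplyr::filter(object, !is.na(.data$pvalue)) |>
    dplyr::mutate(sig = !is.na(.data$padj) & .data$padj < alpha &
                    abs(.data$log2fc) > lfc_min)
  ggplot2::ggplot(dat, ggplot2::aes(.data$log2fc, -log10(.data$pvalue),
                                    colour = .data$sig)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-lfc_min, lfc_min), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p-value") +
    ggplot2::theme_minimal()
}

#' NES bar plot of a gene-set enrichment result
#'
#' @param object A `mirlink_gsea` tibble.
#' @param alpha Adjusted-p threshold used for colouring.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mirlink_gsea
#' @export
autoplot.mirlink_gsea <- function(object, alpha = 0.05, ...) {
  dat <- dplyr::mutate(object, set = stats::reorder(.data$set, .data$nes),
                       sig = .data$padj < alpha)
  ggplot2::ggplot(dat, ggplot2::aes(.data$nes, .data$set, fill = .data$sig)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "steelblue"),
                               name = sprintf("padj < %.2g", alpha)) +
    ggplot2::labs(x = "Normalized enrichment score", y = NULL) +
    ggplot2::theme_minimal()
}

#' Running-score plot for one gene set
#'
#' @param gsea A `mirlink_gsea` result.
#' @param set Name of a set present in the result.
#' @return A ggplot object showing the running enrichment score with hit
#'   positions marked in the rug.
#' @export
plot_gsea_running <- function(gsea, set) {
  profiles <- attr(gsea, "profiles")
  if (is.null(profiles[[set]])) abort(sprintf("no running profile for set '%s'.", set))
  prof <- profiles[[set]]
  ggplot2::ggplot(prof, ggplot2::aes(.data$position, .data$running)) +
    ggplot2::geom_line(colour = "forestgreen") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_rug(data = dplyr::filter(prof, .data$hit), sides = "b",
                      length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(title = set, x = "Rank", y = "Running enrichment score") +
    ggplot2::theme_minimal()
}

#' Bipartite layout plot of an interaction network
#'
#' miRNA nodes on the left, gene nodes on the right; node colour encodes the
#' direction of differential expression.
#'
#' @param object A `mirlink_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mirlink_network
#' @export
autoplot.mirlink_network <- function(object, ...) {
  nodes <- object$nodes |>
    dplyr::group_by(.data$kind) |>
    dplyr::mutate(x = ifelse(.data$kind == "mirna", 0, 1),
                  y = seq(0, 1, length.out = max(dplyr::n(), 2))[seq_len(dplyr::n())]) |>
    dplyr::ungroup()
  edges <- object$edges |>
    dplyr::left_join(dplyr::select(nodes, name, x0 = "x", y0 = "y"),
                     by = c(mirna_id = "name")) |>
    dplyr::left_join(dplyr::select(nodes, name, x1 = "x", y1 = "y"),
                     by = c(gene_id = "name"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1),
                          colour = "grey70", linewidth = 0.4) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y, colour = .data$direction,
                                     shape = .data$kind), size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$name,
                                    hjust = ifelse(.data$kind == "mirna", 1.2, -0.2)),
                       size = 2.8) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "steelblue",
                                            unknown = "grey50")) +
    ggplot2::xlim(-0.5, 1.5) +
    ggplot2::theme_void()
}
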