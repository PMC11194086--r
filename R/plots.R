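#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_tile
#'   geom_hline geom_vline geom_errorbar labs theme_minimal
#'   scale_fill_gradient2 coord_flip geom_histogram
#' @export
ggplot2::autoplot

#' Volcano plot of a differential-expression result
#'
#' @param object A `de_result` from [test_de()] (or a `diffbind_result`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.de_result <- function(object, ...) {
  df <- object[object$tested, , drop = FALSE]
  ggplot(df, aes(x = .data$log2FC, y = -log10(pmax(.data$p_adj, 1e-300)),
                 colour = .data$significant)) +
    geom_point(size = 0.6, alpha = 0.7) +
    geom_hline(yintercept = -log10(attr(object, "thresholds")[["padj_max"]]),
               linetype = 2, linewidth = 0.3) +
    labs(x = "log2 fold change (high - neg)", y = "-log10 adjusted p",
         colour = "significant") +
    theme_minimal()
}

#' @rdname autoplot.de_result
#' @export
autoplot.diffbind_result <- function(object, ...) {
  df <- object[object$tested, , drop = FALSE]
  ggplot(df, aes(x = .data$log2FC, y = -log10(pmax(.data$p_adj, 1e-300)),
                 colour = .data$class)) +
    geom_point(size = 0.6, alpha = 0.7) +
    labs(x = "log2 fold change", y = "-log10 adjusted p", colour = NULL) +
    theme_minimal()
}

#' Bar plot of normalised enrichment scores
#'
#' @param object A `gsea_result` from [gsea_preranked()].
#' @param ... Unused.
#' @export
autoplot.gsea_result <- function(object, ...) {
  df <- object[!object$skipped & !is.na(object$NES), , drop = FALSE]
  df$set <- stats::reorder(df$set, df$NES)
  ggplot(df, aes(x = .data$set, y = .data$NES, fill = .data$q < 0.1)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "normalized enrichment score (NES)",
         fill = "q < 0.1") +
    theme_minimal()
}

#' Heatmap of pairwise signature-score correlations
#'
#' @param object A `signature_cor` from [correlate_signatures()].
#' @param ... Unused.
#' @export
autoplot.signature_cor <- function(object, ...) {
  df <- tidy.signature_cor(object)
  df2 <- dplyr::bind_rows(
    df,
    dplyr::rename(df, signature1 = "signature2", signature2 = "signature1"),
    tibble::tibble(signature1 = rownames(object$r),
                   signature2 = rownames(object$r), r = 1,
                   p = 0, p_adj = 0))
  ggplot(df2, aes(x = .data$signature1, y = .data$signature2,
                  fill = .data$r)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "Pearson R") +
    theme_minimal()
}

#' Distribution of per-cell values with classification thresholds
#'
#' @param object A `cell_classes` from [classify_cells_by_value()].
#' @param ... Unused.
#' @export
autoplot.cell_classes <- function(object, ...) {
  th <- attr(object, "thresholds")
  ggplot(object, aes(x = .data$value, fill = .data$class)) +
    geom_histogram(bins = 50) +
    geom_vline(xintercept = unname(th), linetype = 2, linewidth = 0.3) +
    labs(x = "per-cell value", y = "cells", fill = NULL) +
    theme_minimal()
}

#' Error-bar plot of bootstrap log2FC confidence intervals
#'
#' @param ci Tibble from [bootstrap_log2fc()].
#' @param genes Optional subset of genes to display.
#' @return A ggplot.
#' @export
plot_bootstrap_ci <- function(ci, genes = NULL) {
  if (!is.null(genes)) ci <- ci[ci$gene %in% genes, , drop = FALSE]
  ci$gene <- stats::reorder(ci$gene, ci$log2FC)
  ggplot(ci, aes(x = .data$gene, y = .data$log2FC)) +
    geom_col(fill = "grey70") +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                  width = 0.3) +
    coord_flip() +
    labs(x = NULL, y = "log2 fold change (95% bootstrap CI)") +
    theme_minimal()
}
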