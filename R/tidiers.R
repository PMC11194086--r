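#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a hurdle fit into one row per gene
#'
#' @param x A [fit_hurdle()] result.
#' @param ... Unused.
#' @return The per-gene coefficient tibble.
#' @export
tidy.hurdle_fit <- function(x, ...) x$genes

#' One-row summary of a hurdle fit
#'
#' @param x A [fit_hurdle()] result.
#' @param ... Unused.
#' @export
glance.hurdle_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$genes),
    n_skipped = sum(x$genes$skipped),
    n_converged = sum(x$genes$converged),
    n_high = length(x$cells_high),
    n_neg = length(x$cells_neg),
    use_cdr = x$use_cdr
  )
}

#' Tidy a recovered-expression object into per-gene summaries
#'
#' @param x A [recover_expression()] result.
#' @param ... Unused.
#' @export
tidy.recovered_expression <- function(x, ...) {
  tibble::tibble(
    gene = rownames(x$lambda),
    dispersion = x$dispersion,
    reliability = unname(x$reliability),
    mean_lambda = rowMeans(x$lambda),
    mean_posterior_var = rowMeans(x$posterior_var)
  )
}

#' @export
glance.recovered_expression <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$lambda), n_cells = ncol(x$lambda),
    n_components = x$n_components, ridge = x$ridge,
    median_dispersion = median(x$dispersion),
    median_reliability = median(x$reliability)
  )
}

#' Tidy a signature correlation matrix into long pair rows
#'
#' @param x A [correlate_signatures()] result.
#' @param ... Unused.
#' @export
tidy.signature_cor <- function(x, ...) {
  nm <- rownames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    signature1 = nm[idx[, 1]], signature2 = nm[idx[, 2]],
    r = x$r[idx], p = x$p[idx], p_adj = x$p_adj[idx]
  )
}

#' @export
glance.signature_cor <- function(x, ...) {
  tibble::tibble(n_signatures = nrow(x$r), n_cells = x$n_cells)
}

#' Tidy a boundary enrichment test
#'
#' @param x A [boundary_upregulation_test()] result.
#' @param ... Unused.
#' @export
tidy.boundary_enrichment <- function(x, ...) {
  tibble::tibble(p = x$p, overlap = x$overlap,
                 n_foreground = x$n_foreground,
                 n_upregulated = x$n_upregulated,
                 n_universe = x$n_universe)
}
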