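#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the number of detected genes (raw count >= 1),
#' total UMI, mitochondrial ratio, and the complexity score
#' `log10(n_genes_detected) / log10(total_umi)`. Complexity is undefined
#' (NA) when `total_umi <= 1`; such cells fail any downstream filter.
#'
#' @param counts Gene-by-cell count matrix (base or sparse) with gene and
#'   cell names, or a `cell_population`.
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes.
#' @return Tibble: cell, n_genes_detected, total_umi, mito_ratio,
#'   complexity.
#' @export
#' @examples
#' m <- matrix(c(3, 0, 7, 1, 1, 1), nrow = 3,
#'             dimnames = list(c("A", "B", "C"), c("c1", "c2")))
#' compute_cell_qc(m)
compute_cell_qc <- function(counts, mito_prefix = "MT-") {
  if (inherits(counts, "cell_population")) counts <- counts$counts
  counts <- as_count_matrix(counts)
  assert_that(ncol(counts) > 0, "empty count matrix")
  n_genes <- unname(Matrix::colSums(counts > 0))
  total <- unname(Matrix::colSums(counts))
  mito_idx <- startsWith(rownames(counts), mito_prefix)
  mito <- if (any(mito_idx)) unname(Matrix::colSums(counts[mito_idx, , drop = FALSE])) else rep(0, ncol(counts))
  tibble::tibble(
    cell = colnames(counts),
    n_genes_detected = as.integer(n_genes),
    total_umi = total,
    mito_ratio = ifelse(total > 0, mito / total, NA_real_),
    complexity = ifelse(total > 1 & n_genes > 0,
                        log10(n_genes) / log10(total), NA_real_)
  )
}

## filter thresholds per profile: detected-gene range, min UMI, max mito,
## min complexity. "compendium" mirrors the integrated multi-platform
## compendium; "tenx" the droplet dataset.
qc_profiles <- list(
  compendium = list(genes_min = 1000, genes_max = 9000, umi_min = 500,
                    mito_max = 0.20, complexity_min = 0.80),
  tenx = list(genes_min = 200, genes_max = Inf, umi_min = 200,
              mito_max = 0.10, complexity_min = 0.80)
)

#' Filter cells by QC thresholds
#'
#' Applies one of two named threshold profiles. `"compendium"`: 1000-9000
#' detected genes, UMI >= 500, mitochondrial ratio < 0.20, complexity
#' > 0.80. `"tenx"`: >= 200 genes, UMI >= 200, mitochondrial ratio
#' < 0.10, complexity > 0.80. Cell order is preserved; a filter report is
#' attached as attribute `"qc_report"`.
#'
#' @param counts Gene-by-cell count matrix.
#' @param metrics Tibble from [compute_cell_qc()] (computed if missing).
#' @param profile `"compendium"` or `"tenx"`.
#' @return The filtered count matrix.
#' @export
filter_cells <- function(counts, metrics = NULL,
                         profile = c("compendium", "tenx")) {
  profile <- match.arg(profile)
  if (inherits(counts, "cell_population")) counts <- counts$counts
  counts <- as_count_matrix(counts)
  metrics <- metrics %||% compute_cell_qc(counts)
  assert_that(identical(metrics$cell, colnames(counts)),
              "metrics do not match the count matrix cells")
  th <- qc_profiles[[profile]]
  keep <- metrics$n_genes_detected >= th$genes_min &
    metrics$n_genes_detected <= th$genes_max &
    metrics$total_umi >= th$umi_min &
    metrics$mito_ratio < th$mito_max &
    metrics$complexity > th$complexity_min
  keep[is.na(keep)] <- FALSE
  out <- counts[, keep, drop = FALSE]
  attr(out, "qc_report") <- tibble::tibble(
    profile = profile, n_in = ncol(counts), n_kept = sum(keep))
  out
}

#' The Ex expression transform: log2((CPM/10) + 1)
#'
#' CPM is counts per million within each cell, so Ex is invariant to
#' scaling all counts of a cell and zero wherever the count is zero.
#'
#' @param counts Gene-by-cell count matrix; every cell total must be > 0.
#' @return Dense gene-by-cell matrix of Ex values.
#' @export
transform_ex <- function(counts) {
  if (inherits(counts, "cell_population")) counts <- counts$counts
  counts <- as_count_matrix(counts)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    rlang::abort("cells with zero total counts present; filter cells first")
  }
  cpm <- sweep(counts, 2L, 1e6 / totals, `*`)
  log2(cpm / 10 + 1)
}

#' Filter genes by expression prevalence
#'
#' Keeps a gene iff its Ex exceeds `min_ex` (strictly) in at least
#' `min_frac` of cells (fraction compared with >=).
#'
#' @param ex Ex matrix from [transform_ex()].
#' @param min_ex Expression threshold (default 3.5).
#' @param min_frac Minimum fraction of cells (default 0.02).
#' @return The row-filtered Ex matrix.
#' @export
filter_genes <- function(ex, min_ex = 3.5, min_frac = 0.02) {
  assert_that(min_frac >= 0 && min_frac <= 1, "min_frac must be in [0,1]")
  frac <- rowMeans(ex > min_ex)
  keep <- frac >= min_frac
  if (!any(keep)) rlang::warn("no genes pass the expression filter")
  ex[keep, , drop = FALSE]
}

#' Per-gene z-scaling of an expression matrix
#'
#' Centers and scales each gene across cells using the sample standard
#' deviation (ddof = 1) and clips the result to `+/- clip`. Genes with
#' zero variance map to all-zero rows.
#'
#' @param ex Gene-by-cell expression matrix.
#' @param clip Clipping bound for scaled values (default 10).
#' @return Scaled matrix Es of the same shape.
#' @export
scale_genes <- function(ex, clip = 10) {
  assert_that(ncol(ex) >= 2, "need at least two cells to scale")
  mu <- rowMeans(ex)
  s <- apply(ex, 1L, sd)
  es <- (ex - mu) / ifelse(s > 0, s, 1)
  es[s == 0, ] <- 0
  pmin(pmax(es, -clip), clip)
}
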