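#' Build a marker-anchored top-N gene signature
#'
#' Takes the top `N` genes of a [rank_genes_by_marker()] ranking (marker
#' excluded, order preserved). The anchor usage mirrors signature
#' construction around a senescence marker: top 100, 250 or 500 genes
#' most correlated with the marker.
#'
#' @param ranking A `marker_ranking` tibble.
#' @param N Signature size (must not exceed the ranking length).
#' @param name Signature name (default `"marker_top<N>"`).
#' @return Object of class `gene_signature`: list with `name`, `genes`
#'   (ordered), `source`, `N`.
#' @export
build_marker_signature <- function(ranking, N, name = NULL) {
  assert_that(N >= 1 && N <= nrow(ranking),
              "N must be between 1 and the number of ranked genes")
  structure(list(
    name = name %||% paste0("marker_top", N),
    genes = ranking$gene[seq_len(N)],
    source = "marker_topN",
    N = as.integer(N)
  ), class = "gene_signature")
}

#' Wrap an external gene set as a signature
#'
#' @param genes Character vector of gene ids.
#' @param name Signature name.
#' @return A `gene_signature`.
#' @export
gene_signature <- function(genes, name) {
  genes <- unique(as.character(genes))
  assert_that(length(genes) > 0, "empty gene set")
  structure(list(name = name, genes = genes, source = "external",
                 N = length(genes)), class = "gene_signature")
}

#' Match an expression-balanced control gene set to a signature
#'
#' Standard module-score control matching: all genes are cut into
#' `n_bins` equal-frequency bins of mean expression; for each signature
#' gene, `n_ctrl` control genes are sampled without replacement from its
#' bin (signature genes excluded). The union over signature genes is the
#' control set, so its mean-expression distribution matches the
#' signature's.
#'
#' @param signature A `gene_signature`.
#' @param ex_means Named numeric vector of per-gene mean Ex over cells.
#' @param n_bins Number of expression bins (default 25).
#' @param n_ctrl Controls sampled per signature gene (default 100).
#' @param seed RNG seed.
#' @return Object of class `control_gene_set`: `genes`, `bins` (per
#'   signature gene), `n_bins`, `n_ctrl`, `seed`.
#' @export
match_control_genes <- function(signature, ex_means, n_bins = 25L,
                                n_ctrl = 100L, seed = 1L) {
  assert_that(all(signature$genes %in% names(ex_means)),
              "ex_means must cover all signature genes")
  bin <- dplyr::ntile(ex_means, n_bins)
  names(bin) <- names(ex_means)
  pool <- setdiff(names(ex_means), signature$genes)
  short_bins <- character()
  ctrl <- with_seed(seed, {
    unique(unlist(lapply(signature$genes, function(g) {
      cand <- pool[bin[pool] == bin[[g]]]
      if (length(cand) < n_ctrl) {
        short_bins <<- c(short_bins, g)
        cand
      } else {
        sample(cand, n_ctrl)
      }
    })))
  })
  if (length(short_bins)) {
    rlang::warn(sprintf(
      "bins of %d signature gene(s) held fewer than n_ctrl = %d candidates; whole bin used (first: %s)",
      length(short_bins), n_ctrl, short_bins[1]))
  }
  structure(list(genes = ctrl, bins = bin[signature$genes],
                 n_bins = as.integer(n_bins), n_ctrl = as.integer(n_ctrl),
                 seed = as.integer(seed), signature = signature$name),
            class = "control_gene_set")
}

#' Per-cell module score against a matched control set
#'
#' `SC = mean(Es over signature genes) - mean(Es over control genes)`,
#' computed per cell on the scaled matrix. Scoring against controls with
#' matched expression removes the cell-complexity confound; `C = G`
#' yields exactly zero.
#'
#' @param es Scaled expression matrix from [scale_genes()].
#' @param signature A `gene_signature` (or character vector).
#' @param controls A `control_gene_set` (or character vector).
#' @return Tibble: cell, score, signature.
#' @export
score_modules <- function(es, signature, controls) {
  g <- if (inherits(signature, "gene_signature")) signature$genes else signature
  c_ <- if (inherits(controls, "control_gene_set")) controls$genes else controls
  assert_that(length(g) > 0 && length(c_) > 0, "empty signature or control set")
  assert_that(all(g %in% rownames(es)) && all(c_ %in% rownames(es)),
              "all signature and control genes must be present in the matrix")
  assert_that(!is.null(colnames(es)), "matrix must carry cell names")
  sc <- colMeans(es[g, , drop = FALSE]) - colMeans(es[c_, , drop = FALSE])
  tibble::tibble(
    cell = colnames(es),
    score = unname(sc),
    signature = if (inherits(signature, "gene_signature")) signature$name else "signature"
  )
}

#' Pairwise Pearson correlation of signature scores across cells
#'
#' @param scores Named list of score tibbles from [score_modules()] (or a
#'   wide tibble cell x signatures).
#' @return Object of class `signature_cor`: `r` (k x k matrix), `p`
#'   (two-sided t-test), `p_adj` (BH over distinct pairs), `n_cells`.
#' @export
correlate_signatures <- function(scores) {
  if (is.data.frame(scores)) {
    wide <- scores
  } else {
    assert_that(length(scores) >= 2, "need at least two signatures")
    nm <- names(scores) %||% vapply(scores, function(s) s$signature[1], "")
    wide <- purrr::reduce(purrr::map2(scores, nm, function(s, n) {
      stats::setNames(s[c("cell", "score")], c("cell", n))
    }), dplyr::inner_join, by = "cell")
  }
  m <- as.matrix(wide[setdiff(names(wide), "cell")])
  assert_that(ncol(m) >= 2, "need at least two signatures")
  k <- ncol(m); n <- nrow(m)
  r <- matrix(1, k, k, dimnames = list(colnames(m), colnames(m)))
  p <- matrix(NA_real_, k, k, dimnames = dimnames(r))
  diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (sd(m[, i]) == 0 || sd(m[, j]) == 0) {
      r[i, j] <- r[j, i] <- NA_real_
      next
    }
    ct <- cor.test(m[, i], m[, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  padj <- p
  ut <- upper.tri(p)
  padj[ut] <- p.adjust(p[ut], "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  structure(list(r = r, p = p, p_adj = padj, n_cells = n),
            class = "signature_cor")
}

#' Classify cells by empirical percentiles of a per-cell value
#'
#' Thresholds are the empirical quantiles (linear interpolation between
#' order statistics, R type 7). A cell is `high` iff its value is
#' strictly above the upper quantile, `neg` iff strictly below the lower
#' quantile, `mid` otherwise (ties at a threshold fall to `mid`).
#' Transcript classification uses 70/30; image-intensity classification
#' uses 80/20.
#'
#' @param values Data frame with a `cell` column and a value column, or a
#'   (named) numeric vector.
#' @param upper_pct,lower_pct Upper/lower percentile cut points in (0,100).
#' @param value_col Column holding the value when `values` is a data
#'   frame (default: first non-cell numeric column).
#' @return Tibble: cell, value, class (factor high/mid/neg), plus
#'   attributes `thresholds`.
#' @export
#' @examples
#' classify_cells_by_value(setNames(1:10, paste0("c", 1:10)), 80, 20)
classify_cells_by_value <- function(values, upper_pct = 70, lower_pct = 30,
                                    value_col = NULL) {
  assert_that(lower_pct < upper_pct, "lower_pct must be below upper_pct")
  if (is.data.frame(values)) {
    value_col <- value_col %||%
      setdiff(names(values)[vapply(values, is.numeric, TRUE)], "cell")[1]
    v <- values[[value_col]]
    cells <- if ("cell" %in% names(values)) values$cell else
      as.character(seq_along(v))
  } else {
    v <- as.numeric(values)
    cells <- names(values) %||% as.character(seq_along(v))
  }
  assert_that(length(v) >= 10, "need at least 10 cells to classify")
  if (length(unique(v)) == 1L) {
    rlang::warn("all values identical; every cell classed mid")
  }
  qs <- quantile(v, c(lower_pct, upper_pct) / 100, type = 7, names = FALSE)
  cls <- ifelse(v > qs[2], "high", ifelse(v < qs[1], "neg", "mid"))
  out <- tibble::tibble(
    cell = cells, value = v,
    class = factor(cls, levels = c("high", "mid", "neg"))
  )
  attr(out, "thresholds") <- c(lower = qs[1], upper = qs[2])
  attr(out, "percentiles") <- c(lower = lower_pct, upper = upper_pct)
  class(out) <- c("cell_classes", class(out))
  out
}
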