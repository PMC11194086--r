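## weighted-KS enrichment score for one set against a ranked list.
## hit_idx are positions of set members in the ranked order; weights are
## |metric|^p at those positions (p = 0 -> equal weights).
gsea_es <- function(n, hit_idx, metric_abs_p) {
  nh <- length(hit_idx)
  if (nh == 0 || nh == n) return(NA_real_)
  w <- metric_abs_p[hit_idx]
  if (all(w == 0)) w <- rep(1, nh)
  step_hit <- numeric(n)
  step_hit[hit_idx] <- w / sum(w)
  step_miss <- rep(1 / (n - nh), n)
  step_miss[hit_idx] <- 0
  running <- cumsum(step_hit - step_miss)
  ## earliest position of the max |deviation|; round so exact ties are not
  ## broken by accumulated float noise
  running[which.max(round(abs(running), 9))]
}

#' Preranked gene-set enrichment analysis
#'
#' The standard weighted Kolmogorov-Smirnov preranked procedure: ES is
#' the signed maximum deviation of the weighted hit CDF minus the miss
#' CDF walked down the ranked list; the null is built from random
#' gene-label sets of matching size; NES divides ES by the mean absolute
#' null ES of matching sign; nominal p is the same-sign permutation tail;
#' FDR q pools normalised null scores across sets.
#'
#' @param ranked Tibble with `gene` and a numeric metric column (e.g.
#'   `r_adj` from [rank_genes_by_marker()]), or a named numeric vector.
#'   Sorted descending internally; metric ties break by gene name.
#' @param sets Named list of gene-id vectors (see [read_gmt()]).
#' @param weight_p Metric weighting exponent (0 = classic KS, 1 =
#'   default).
#' @param n_perm Permutations per set size.
#' @param seed RNG seed.
#' @param min_size Minimum overlap with the ranked list; smaller sets are
#'   skipped with a flag.
#' @return Tibble of class `gsea_result`: set, size, ES, NES, p, q,
#'   leading_edge (list column), skipped.
#' @export
gsea_preranked <- function(ranked, sets, weight_p = 1, n_perm = 1000L,
                           seed = 1L, min_size = 5L) {
  if (is.data.frame(ranked)) {
    mcol <- setdiff(names(ranked)[vapply(ranked, is.numeric, TRUE)],
                    c("rank"))[1]
    metric <- setNames(ranked[[mcol]], ranked$gene)
  } else {
    metric <- ranked
  }
  assert_that(!anyDuplicated(names(metric)), "duplicate genes in ranked list")
  ord <- order(-metric, names(metric))
  metric <- metric[ord]
  genes <- names(metric)
  n <- length(genes)
  wabs <- abs(metric)^weight_p

  sizes <- vapply(sets, function(s) length(intersect(s, genes)), 0L)
  use <- sizes >= min_size & sizes < n
  ## shared null ES per distinct set size
  null_by_size <- with_seed(seed, {
    lapply(setNames(nm = as.character(unique(sizes[use]))), function(sz) {
      k <- as.integer(sz)
      vapply(seq_len(n_perm), function(i) {
        gsea_es(n, sample.int(n, k), wabs)
      }, numeric(1))
    })
  })

  rows <- purrr::map_dfr(names(sets), function(nm) {
    hit_idx <- which(genes %in% sets[[nm]])
    k <- length(hit_idx)
    if (!(k >= min_size && k < n)) {
      return(tibble::tibble(set = nm, size = k, ES = NA_real_, NES = NA_real_,
                            p = NA_real_, q = NA_real_,
                            leading_edge = list(character()), skipped = TRUE))
    }
    es <- gsea_es(n, hit_idx, wabs)
    null <- null_by_size[[as.character(k)]]
    same <- if (es >= 0) null[null >= 0] else null[null < 0]
    mean_abs <- mean(abs(same))
    nes <- if (length(same) && mean_abs > 0) es / mean_abs else NA_real_
    p <- if (length(same)) (sum(abs(same) >= abs(es)) + 1) / (length(same) + 1) else NA_real_
    ## leading edge: set members up to the ES extremum
    step_hit <- numeric(n); w <- wabs[hit_idx]
    if (all(w == 0)) w <- rep(1, k)
    step_hit[hit_idx] <- w / sum(w)
    step_miss <- rep(1 / (n - k), n); step_miss[hit_idx] <- 0
    running <- cumsum(step_hit - step_miss)
    peak <- which.max(abs(running))
    le <- if (es >= 0) genes[intersect(hit_idx, seq_len(peak))] else
      genes[intersect(hit_idx, peak:n)]
    tibble::tibble(set = nm, size = k, ES = es, NES = nes, p = p, q = NA_real_,
                   leading_edge = list(le), skipped = FALSE)
  })

  ## FDR by pooled normalised null scores
  tested <- !rows$skipped & !is.na(rows$NES)
  if (any(tested)) {
    null_nes <- unlist(lapply(names(null_by_size), function(sz) {
      null <- null_by_size[[sz]]
      posm <- mean(abs(null[null >= 0])); negm <- mean(abs(null[null < 0]))
      c(null[null >= 0] / ifelse(posm > 0, posm, 1),
        null[null < 0] / ifelse(negm > 0, negm, 1))
    }))
    obs <- rows$NES[tested]
    q <- vapply(obs, function(x) {
      if (x >= 0) {
        num <- mean(null_nes[null_nes >= 0] >= x)
        den <- mean(obs[obs >= 0] >= x)
      } else {
        num <- mean(null_nes[null_nes < 0] <= x)
        den <- mean(obs[obs < 0] <= x)
      }
      min(1, num / max(den, 1e-12))
    }, numeric(1))
    rows$q[tested] <- q
  }
  attr(rows, "n_perm") <- n_perm
  attr(rows, "seed") <- seed
  class(rows) <- c("gsea_result", class(rows))
  rows
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a gene list and
#' each set, within a stated universe: `p = P(X >= k)` with `X ~
#' Hypergeom(K, N - K, n)`. BH adjustment across sets.
#'
#' @param hits Character vector of foreground genes (must lie in the
#'   universe).
#' @param sets Named list of gene sets.
#' @param universe Character vector of all tested genes.
#' @return Tibble of class `ora_result`: set, overlap, set_size,
#'   list_size, universe_size, p, q.
#' @export
ora_hypergeometric <- function(hits, sets, universe) {
  universe <- unique(universe)
  assert_that(length(universe) > 0, "empty universe")
  hits <- unique(hits)
  assert_that(all(hits %in% universe), "hits must be a subset of the universe")
  n <- length(hits); N <- length(universe)
  rows <- purrr::map_dfr(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(set, hits))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(set = nm, overlap = k, set_size = K, list_size = n,
                   universe_size = N, p = p)
  })
  rows$q <- p.adjust(rows$p, "BH")
  class(rows) <- c("ora_result", class(rows))
  rows
}
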