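## Independent brute-force oracles used to cross-check the implementation.
## These deliberately avoid the package's code paths (and IRanges).

## Benjamini-Hochberg step-up, straight from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

## weighted-KS enrichment score by explicit CDF walk
oracle_es <- function(ranked_genes, metric, set, p = 1) {
  n <- length(ranked_genes)
  hit <- ranked_genes %in% set
  nh <- sum(hit)
  if (nh == 0 || nh == n) return(NA_real_)
  w <- abs(metric)^p
  w[!hit] <- 0
  if (sum(w) == 0) w[hit] <- 1
  phit <- 0; pmiss <- 0; best <- 0
  for (i in seq_len(n)) {
    if (hit[i]) phit <- phit + w[i] / sum(w) else pmiss <- pmiss + 1 / (n - nh)
    if (abs(phit - pmiss) - abs(best) > 1e-9) best <- phit - pmiss
  }
  unname(best)
}

## hypergeometric upper tail from binomial coefficients
oracle_hyper_upper <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

## quadratic interval overlap (0-based half-open)
oracle_overlaps_any <- function(q, s) {
  vapply(seq_len(nrow(q)), function(i) {
    any(s$chrom == q$chrom[i] & s$start < q$end[i] & s$end > q$start[i])
  }, logical(1))
}

## O(n*m) nearest-TSS search with the package's documented tie-break
oracle_nearest <- function(elements, tss) {
  mid <- floor((elements$start + elements$end) / 2)
  out <- character(nrow(elements))
  for (i in seq_len(nrow(elements))) {
    best_g <- NA_character_; best_d <- Inf; best_pos <- Inf
    for (j in seq_len(nrow(tss))) {
      if (tss$chrom[j] != elements$chrom[i]) next
      d <- abs(tss$tss[j] - mid[i])
      if (tss$tss[j] >= elements$start[i] && tss$tss[j] < elements$end[i]) d <- 0
      if (d < best_d ||
          (d == best_d && tss$tss[j] < best_pos) ||
          (d == best_d && tss$tss[j] == best_pos && tss$gene[j] < best_g)) {
        best_g <- tss$gene[j]; best_d <- d; best_pos <- tss$tss[j]
      }
    }
    out[i] <- best_g
  }
  out
}

## O(n*m) CTCF categorisation straight from the precedence rules
oracle_categorize <- function(sites, prom_windows, enhancers, tads,
                              range = 200000) {
  mid <- floor((sites$start + sites$end) / 2)
  emid <- floor((enhancers$start + enhancers$end) / 2)
  pmid <- floor((prom_windows$start + prom_windows$end) / 2)
  out <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    in_prom <- any(prom_windows$chrom == sites$chrom[i] &
                     prom_windows$start < sites$end[i] &
                     prom_windows$end > sites$start[i])
    if (in_prom) { out[i] <- "promoter"; next }
    ec <- enhancers$chrom == sites$chrom[i] & abs(emid - mid[i]) <= range
    pc <- prom_windows$chrom == sites$chrom[i] & abs(pmid - mid[i]) <= range
    le <- any(ec & emid < mid[i]); re <- any(ec & emid > mid[i])
    lp <- any(pc & pmid < mid[i]); rp <- any(pc & pmid > mid[i])
    if ((le && rp) || (re && lp)) {
      out[i] <- "enhancer_promoter_intervening"; next
    }
    in_tad <- nrow(tads) > 0 && any(tads$chrom == sites$chrom[i] &
                                      tads$start < sites$end[i] &
                                      tads$end > sites$start[i])
    out[i] <- if (in_tad) "tad_boundary" else "other"
  }
  out
}

## random interval fixture on one chromosome
random_intervals <- function(n, chrom = "chrT", size = 1e6, max_w = 5000) {
  start <- sample.int(size - max_w, n, replace = TRUE)
  tibble::tibble(chrom = chrom, start = start,
                 end = start + sample.int(max_w, n, replace = TRUE))
}
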