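#' Build a position weight matrix from a count (frequency) matrix
#'
#' Adds a pseudocount, normalises each column to probabilities and
#' stores the log-odds against the background.
#'
#' @param counts 4-by-width numeric matrix with rownames A/C/G/T (as
#'   from [read_jaspar_pfm()]).
#' @param pseudocount Added to every cell before normalising (default 1).
#' @param background Background base probabilities (A,C,G,T), default
#'   uniform.
#' @return Object of class `pwm`: `prob`, `log_odds` (natural log),
#'   `background`, `width`.
#' @export
pwm_from_counts <- function(counts, pseudocount = 1,
                            background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  counts <- as.matrix(counts)
  assert_that(nrow(counts) == 4, "PFM must have 4 rows (A,C,G,T)")
  assert_that(ncol(counts) >= 1, "PFM width must be >= 1")
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  prob <- sweep(counts + pseudocount, 2L, colSums(counts + pseudocount), `/`)
  background <- background / sum(background)
  lo <- log(prob / background)
  structure(list(prob = prob, log_odds = lo, background = background,
                 width = ncol(prob)), class = "pwm")
}

#' Exact null distribution of PWM window scores under the background
#'
#' Dynamic programming over positions: the distribution of the total
#' log-odds score of a random background window. For widths whose score
#' space is small (4^width <= 2^16) the DP aggregates exact score sums
#' (scores aggregated once at the end, rounded at 1e-9); wider motifs use an
#' integer score lattice of the given granularity.
#'
#' @param pwm A [pwm_from_counts()] object.
#' @param granularity Lattice resolution for wide motifs (default 1e-3).
#' @return Tibble: score, prob (ascending in score; probs sum to 1).
#' @export
pwm_null_distribution <- function(pwm, granularity = 1e-3) {
  lo <- pwm$log_odds
  bg <- pwm$background
  w <- pwm$width
  if (4^w <= 65536) {
    ## expand every word's score without intermediate rounding (so sums
    ## match a direct enumeration bit-for-bit), aggregate once at the end
    score <- 0; prob <- 1
    for (j in seq_len(w)) {
      score <- as.vector(outer(score, lo[, j], `+`))
      prob <- as.vector(outer(prob, bg, `*`))
    }
    agg <- rowsum(prob, round(score, 9))
    key <- as.numeric(rownames(agg))
    ord <- order(key)
    tibble::tibble(score = key[ord], prob = as.vector(agg)[ord])
  } else {
    loi <- round(lo / granularity)
    offset <- sum(apply(loi, 2L, min))
    span <- sum(apply(loi, 2L, max) - apply(loi, 2L, min))
    d <- numeric(span + 1); d[1] <- 1
    for (j in seq_len(w)) {
      nd <- numeric(span + 1)
      mj <- min(loi[, j])
      for (b in 1:4) {
        sh <- loi[b, j] - mj
        nd[(1 + sh):(span + 1)] <- nd[(1 + sh):(span + 1)] +
          bg[b] * d[1:(span + 1 - sh)]
      }
      d <- nd
    }
    nz <- which(d > 0)
    tibble::tibble(score = (nz - 1 + offset) * granularity, prob = d[nz])
  }
}

#' Score threshold for a target p-value
#'
#' The smallest achievable window score `t` with `P(S >= t) <=
#' pvalue_max` under the background null; `Inf` when no score is rare
#' enough. Monotone non-increasing in `pvalue_max`.
#'
#' @param pwm A `pwm` object.
#' @param pvalue_max Per-window p-value bound (default 1e-4).
#' @param null Optional precomputed [pwm_null_distribution()].
#' @return Numeric threshold.
#' @export
pwm_score_threshold <- function(pwm, pvalue_max = 1e-4, null = NULL) {
  null <- null %||% pwm_null_distribution(pwm)
  tail <- rev(cumsum(rev(null$prob)))  # P(S >= score_i)
  ## eps well below the pmf granularity guards float ties at the cutoff
  ok <- which(tail <= pvalue_max + 1e-9)
  if (!length(ok)) return(Inf)
  null$score[min(ok)]
}

## integer-encode a DNA string; N and other ambiguity codes -> 5
encode_dna <- function(seq) {
  x <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  x[is.na(x)] <- 5L
  x
}

revcomp_codes <- function(codes) {
  comp <- c(4L, 3L, 2L, 1L, 5L)
  rev(comp[codes])
}

## best window score of an encoded sequence on one strand
best_window <- function(codes, lo5) {
  w <- ncol(lo5)
  n <- length(codes)
  if (n < w) return(c(score = -Inf, pos = NA_real_))
  best <- -Inf; pos <- NA_real_
  for (i in seq_len(n - w + 1L)) {
    s <- sum(lo5[cbind(codes[i:(i + w - 1L)], seq_len(w))])
    if (s > best) { best <- s; pos <- i }
  }
  c(score = best, pos = pos)
}

#' Scan sequences for PWM motif matches
#'
#' Scores every window on both strands with the log-odds matrix
#' (ambiguous bases contribute 0, i.e. score as background), takes the
#' per-sequence best window, converts it to a p-value from the exact
#' background null, and flags the site as passing when any window meets
#' the threshold for `pvalue_max`. A BH q-value over the scanned sites'
#' best-window p-values is also reported (`q`), so a per-site q cutoff
#' can mirror adjusted-p motif filtering.
#'
#' @param sequences Named character vector of DNA sequences, a
#'   `DNAStringSet`, or a FASTA file path.
#' @param pwm A `pwm` object.
#' @param pvalue_max Per-window p-value bound (default 1e-4).
#' @return Tibble of class `pwm_scan`: site, length, best_score, strand,
#'   p, q, passed, too_short.
#' @export
scan_pwm <- function(sequences, pwm, pvalue_max = 1e-4) {
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
  }
  if (inherits(sequences, "XStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  assert_that(length(sequences) > 0, "no sequences to scan")
  nm <- names(sequences) %||% sprintf("seq%04d", seq_along(sequences))
  lo5 <- rbind(pwm$log_odds, N = 0)
  null <- pwm_null_distribution(pwm)
  thr <- pwm_score_threshold(pwm, pvalue_max, null = null)
  tail_p <- function(s) {
    if (!is.finite(s)) return(1)
    sum(null$prob[null$score >= s - 1e-9])
  }
  rows <- purrr::map_dfr(seq_along(sequences), function(i) {
    codes <- encode_dna(sequences[[i]])
    if (length(codes) < pwm$width) {
      return(tibble::tibble(site = nm[i], length = length(codes),
                            best_score = NA_real_, strand = NA_character_,
                            p = NA_real_, passed = FALSE, too_short = TRUE))
    }
    fwd <- best_window(codes, lo5)
    rev_ <- best_window(revcomp_codes(codes), lo5)
    if (fwd[["score"]] >= rev_[["score"]]) {
      best <- fwd[["score"]]; strand <- "+"
    } else {
      best <- rev_[["score"]]; strand <- "-"
    }
    ## 1e-8 absorbs the 1e-9 key rounding of the null distribution
    tibble::tibble(site = nm[i], length = length(codes), best_score = best,
                   strand = strand, p = min(tail_p(best), 1),
                   passed = is.finite(thr) && best >= thr - 1e-8,
                   too_short = FALSE)
  })
  rows$q <- NA_real_
  ok <- !rows$too_short
  rows$q[ok] <- p.adjust(rows$p[ok], "BH")
  attr(rows, "threshold") <- thr
  class(rows) <- c("pwm_scan", class(rows))
  rows
}
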