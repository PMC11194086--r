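## internal helpers shared across modules

#' @keywords internal
#' @noRd
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) rlang::abort(msg)
  invisible(TRUE)
}

## counts can arrive as a base matrix or a Matrix sparse matrix; interval
## tables as data.frame or tibble. Normalise once at entry.
as_count_matrix <- function(counts) {
  if (inherits(counts, "sparseMatrix")) counts <- as.matrix(counts)
  counts <- as.matrix(counts)
  assert_that(all(counts >= 0), "count matrix contains negative entries")
  assert_that(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              "count matrix must carry gene rownames and cell colnames")
  assert_that(!anyDuplicated(rownames(counts)) && !anyDuplicated(colnames(counts)),
              "gene and cell names must be unique")
  counts
}

check_intervals <- function(x, what = "intervals") {
  assert_that(all(c("chrom", "start", "end") %in% names(x)),
              paste0(what, " must have chrom/start/end columns (0-based half-open)"))
  assert_that(all(x$start < x$end), paste0(what, ": start must be < end"))
  assert_that(all(x$start >= 0), paste0(what, ": start must be >= 0"))
  invisible(x)
}

## 0-based half-open tibble -> IRanges-compatible GRanges (1-based closed)
intervals_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

## deterministic local RNG scope
with_seed <- function(seed, code) withr::with_seed(seed, code)
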