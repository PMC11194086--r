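#' Call active promoters from three activation marks
#'
#' A TSS is active iff each of the H3K27ac, ATAC and H3K4me3 peak sets
#' overlaps its window `[tss - window, tss + window)` by at least one
#' base (0-based half-open, so a peak starting exactly at `tss + window`
#' does not count).
#'
#' @param tss Tibble: gene, chrom, tss, strand.
#' @param peaks Named list with interval tibbles `H3K27ac`, `ATAC`,
#'   `H3K4me3` (chrom/start/end).
#' @param window Half-width of the promoter window in bp (default 2000).
#' @param chrom_sizes Optional named vector; TSSs beyond their chromosome
#'   are rejected with a diagnostic message.
#' @return Tibble: gene, chrom, tss, strand, window start/end, per-mark
#'   logical columns, active.
#' @export
call_active_promoters <- function(tss, peaks, window = 2000,
                                  chrom_sizes = NULL) {
  assert_that(all(c("H3K27ac", "ATAC", "H3K4me3") %in% names(peaks)),
              "peaks must include H3K27ac, ATAC and H3K4me3")
  tss <- tibble::as_tibble(tss)
  if (!is.null(chrom_sizes)) {
    bad <- tss$tss < 0 | tss$tss >= chrom_sizes[tss$chrom]
    if (any(bad)) {
      rlang::warn(sprintf("%d TSS rows beyond chromosome bounds rejected (%s)",
                          sum(bad), paste(head(tss$gene[bad], 3), collapse = ", ")))
      tss <- tss[!bad, , drop = FALSE]
    }
  }
  win <- tibble::tibble(chrom = tss$chrom,
                        start = pmax(tss$tss - window, 0),
                        end = tss$tss + window)
  win_gr <- intervals_to_gr(win)
  has <- lapply(peaks[c("H3K27ac", "ATAC", "H3K4me3")], function(p) {
    check_intervals(p, "peaks")
    IRanges::overlapsAny(win_gr, intervals_to_gr(p))
  })
  out <- dplyr::mutate(tss,
                       window_start = win$start, window_end = win$end,
                       H3K27ac = has$H3K27ac, ATAC = has$ATAC,
                       H3K4me3 = has$H3K4me3,
                       active = has$H3K27ac & has$ATAC & has$H3K4me3)
  class(out) <- c("promoter_calls", class(out))
  out
}

#' Call enhancers from overlapping H3K27ac and H3K4me1 peaks
#'
#' An enhancer is an H3K27ac peak that overlaps at least one H3K4me1
#' peak and no promoter window; its coordinates are the H3K27ac peak
#' (intersection available via `coords = "intersection"`).
#'
#' @param h3k27ac,h3k4me1 Interval tibbles (chrom/start/end).
#' @param promoter_windows Interval tibble of promoter windows (e.g.
#'   active promoters from [call_active_promoters()], using
#'   window_start/window_end), or NULL for none.
#' @param coords `"h3k27ac"` (default) or `"intersection"` (clip to the
#'   overlapped H3K4me1 span).
#' @return Tibble of enhancer intervals (chrom, start, end, name).
#' @export
call_enhancers <- function(h3k27ac, h3k4me1, promoter_windows = NULL,
                           coords = c("h3k27ac", "intersection")) {
  coords <- match.arg(coords)
  check_intervals(h3k27ac, "H3K27ac peaks")
  check_intervals(h3k4me1, "H3K4me1 peaks")
  gr27 <- intervals_to_gr(h3k27ac)
  gr41 <- intervals_to_gr(h3k4me1)
  keep <- IRanges::overlapsAny(gr27, gr41)
  if (!is.null(promoter_windows) && nrow(promoter_windows)) {
    pw <- check_intervals(promoter_windows, "promoter windows")
    keep <- keep & !IRanges::overlapsAny(gr27, intervals_to_gr(pw))
  }
  out <- h3k27ac[keep, , drop = FALSE]
  if (coords == "intersection" && nrow(out)) {
    gro <- intervals_to_gr(out)
    hits <- GenomicRanges::findOverlaps(gro, gr41)
    ## clip each enhancer to the union span of its overlapping K4me1 peaks
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (q in unique(qh)) {
      j <- sh[qh == q]
      out$start[q] <- max(out$start[q], min(h3k4me1$start[j]))
      out$end[q] <- min(out$end[q], max(h3k4me1$end[j]))
    }
  }
  dplyr::arrange(out, chrom, start)
}

#' Link elements to the nearest gene TSS
#'
#' Distance is measured from the element midpoint (integer floor) to
#' each TSS; the nearest wins, ties broken by smaller TSS coordinate
#' then lexicographic gene name. Distance is reported signed in the
#' gene's direction of transcription: positive when the element lies
#' downstream of the TSS, negative upstream; an element containing its
#' nearest TSS has distance 0.
#'
#' @param elements Interval tibble (chrom/start/end).
#' @param tss TSS tibble (gene/chrom/tss/strand).
#' @param max_range Optional maximum absolute distance; beyond it the
#'   link is `NA` ("none within range").
#' @return `elements` with nearest_gene, distance, midpoint columns.
#' @export
link_nearest_gene <- function(elements, tss, max_range = NULL) {
  assert_that(nrow(tss) > 0, "empty TSS table")
  check_intervals(elements, "elements")
  mid <- floor((elements$start + elements$end) / 2)
  tss_ord <- dplyr::arrange(tss, chrom, tss, gene)
  nearest_gene <- rep(NA_character_, nrow(elements))
  distance <- rep(NA_real_, nrow(elements))
  for (i in seq_len(nrow(elements))) {
    cand <- tss_ord[tss_ord$chrom == elements$chrom[i], , drop = FALSE]
    if (!nrow(cand)) next
    d <- abs(cand$tss - mid[i])
    ## contained TSS => distance 0
    inside <- cand$tss >= elements$start[i] & cand$tss < elements$end[i]
    d[inside] <- 0
    j <- which(d == min(d))[1]  # cand pre-sorted: coordinate then name
    if (!is.null(max_range) && min(d) > max_range) next
    nearest_gene[i] <- cand$gene[j]
    raw <- mid[i] - cand$tss[j]
    distance[i] <- if (d[j] == 0) 0 else if (cand$strand[j] == "-") -raw else raw
  }
  dplyr::mutate(elements, midpoint = mid, nearest_gene = nearest_gene,
                distance = distance)
}

#' Categorise CTCF sites by regulatory context
#'
#' Precedence: (1) `promoter` if the site overlaps any active-promoter
#' window; else (2) `enhancer_promoter_intervening` if an enhancer lies
#' on one side of the site and an active-promoter window on the other,
#' both within `range` bp of the site midpoint; else (3) `tad_boundary`
#' if the site overlaps a boundary interval; else (4) `other`. Sites
#' matching both (2) and (3) keep the first as primary category and
#' carry both flags. The linked gene is the overlapped promoter's gene
#' for category 1, the intervening promoter's gene for category 2, and
#' the nearest TSS otherwise.
#'
#' @param sites CTCF site interval tibble (chrom/start/end, optional
#'   name).
#' @param promoters Active-promoter tibble from
#'   [call_active_promoters()] (rows with `active = TRUE` are used), or
#'   an interval tibble with gene/window_start/window_end.
#' @param enhancers Enhancer interval tibble.
#' @param tss TSS tibble (for nearest-gene links of categories 3 and 4).
#' @param tads TAD-boundary interval tibble.
#' @param range Maximum distance for the intervening rule (default
#'   200000).
#' @return Tibble of class `ctcf_catalog`: site intervals with name,
#'   category, flag_intervening, flag_boundary, linked_gene.
#' @export
categorize_ctcf_sites <- function(sites, promoters, enhancers, tss, tads,
                                  range = 200000) {
  check_intervals(sites, "CTCF sites")
  if (inherits(promoters, "promoter_calls") || "active" %in% names(promoters)) {
    promoters <- promoters[promoters$active, , drop = FALSE]
  }
  pw <- tibble::tibble(chrom = promoters$chrom,
                       start = promoters$window_start %||% promoters$start,
                       end = promoters$window_end %||% promoters$end,
                       gene = promoters$gene)
  mid <- floor((sites$start + sites$end) / 2)
  n <- nrow(sites)
  category <- character(n)
  flag_int <- logical(n); flag_bnd <- logical(n)
  linked <- rep(NA_character_, n)

  gr_sites <- intervals_to_gr(sites)
  ov_prom <- GenomicRanges::findOverlaps(gr_sites, intervals_to_gr(pw))
  ov_tad <- if (nrow(tads)) IRanges::overlapsAny(gr_sites, intervals_to_gr(tads)) else rep(FALSE, n)

  prom_hit <- rep(NA_integer_, n)
  if (length(ov_prom)) {
    first <- !duplicated(S4Vectors::queryHits(ov_prom))
    prom_hit[S4Vectors::queryHits(ov_prom)[first]] <- S4Vectors::subjectHits(ov_prom)[first]
  }
  emid <- if (nrow(enhancers)) floor((enhancers$start + enhancers$end) / 2) else numeric(0)
  pmid <- floor((pw$start + pw$end) / 2)

  for (i in seq_len(n)) {
    ## intervening flag: enhancer one side, promoter window the other
    ec <- which(enhancers$chrom == sites$chrom[i] & abs(emid - mid[i]) <= range)
    pc <- which(pw$chrom == sites$chrom[i] & abs(pmid - mid[i]) <= range)
    left_e <- any(emid[ec] < mid[i]); right_e <- any(emid[ec] > mid[i])
    left_p <- any(pmid[pc] < mid[i]); right_p <- any(pmid[pc] > mid[i])
    flag_int[i] <- (left_e && right_p) || (right_e && left_p)
    flag_bnd[i] <- ov_tad[i]
    if (!is.na(prom_hit[i])) {
      category[i] <- "promoter"
      linked[i] <- pw$gene[prom_hit[i]]
    } else if (flag_int[i]) {
      category[i] <- "enhancer_promoter_intervening"
      ## link to the nearest opposite-side promoter
      opp <- if (left_e && right_p) pc[pmid[pc] > mid[i]] else pc[pmid[pc] < mid[i]]
      if (left_e && right_p && right_e && left_p) opp <- pc
      j <- opp[which.min(abs(pmid[opp] - mid[i]))]
      linked[i] <- pw$gene[j]
    } else if (flag_bnd[i]) {
      category[i] <- "tad_boundary"
    } else {
      category[i] <- "other"
    }
  }
  ## nearest-gene links for boundary/other sites
  rest <- is.na(linked)
  if (any(rest) && nrow(tss)) {
    lk <- link_nearest_gene(sites[rest, , drop = FALSE], tss)
    linked[rest] <- lk$nearest_gene
  }
  site_names <- if ("name" %in% names(sites)) sites$name else
    sprintf("site%05d", seq_len(n))
  out <- dplyr::mutate(sites,
                       name = site_names,
                       midpoint = mid,
                       category = factor(category,
                                         levels = c("promoter",
                                                    "enhancer_promoter_intervening",
                                                    "tad_boundary", "other")),
                       flag_intervening = flag_int,
                       flag_boundary = flag_bnd,
                       linked_gene = linked)
  class(out) <- c("ctcf_catalog", class(out))
  out
}

#' Test boundary CTCF loss for coupling to gene upregulation
#'
#' Upper-tail hypergeometric test of the overlap between genes linked to
#' TAD-boundary CTCF sites with decreased binding (the foreground) and
#' upregulated genes, within the tested gene universe.
#'
#' @param catalog A [categorize_ctcf_sites()] result carrying per-site
#'   binding calls: either a `binding_class` column
#'   (increased/decreased/unchanged) or joinable via `binding` below.
#' @param de Differential-expression tibble with `gene` and a logical
#'   `upregulated` column (or a `de_result`, where upregulated =
#'   significant & direction == "up").
#' @param binding Optional tibble (region, class) from
#'   [differential_region_test()] to join on site name.
#' @return List of class `boundary_enrichment`: p, overlap k, foreground
#'   size, upregulated count, universe size.
#' @export
boundary_upregulation_test <- function(catalog, de, binding = NULL) {
  if (!is.null(binding)) {
    catalog$binding_class <- binding$class[match(catalog$name, binding$region)]
  }
  assert_that("binding_class" %in% names(catalog),
              "catalog needs a binding_class column (or supply `binding`)")
  if (inherits(de, "de_result")) {
    de <- tibble::tibble(gene = de$gene,
                         upregulated = de$significant & de$direction == "up")
  }
  fg <- unique(stats::na.omit(catalog$linked_gene[
    catalog$category == "tad_boundary" & catalog$binding_class == "decreased"]))
  assert_that(length(fg) > 0, "empty foreground: no boundary sites with decreased binding")
  universe <- unique(de$gene)
  fg <- intersect(fg, universe)
  up <- unique(de$gene[de$upregulated])
  k <- length(intersect(fg, up))
  p <- phyper(k - 1, length(up), length(universe) - length(up), length(fg),
              lower.tail = FALSE)
  structure(list(p = p, overlap = k, n_foreground = length(fg),
                 n_upregulated = length(up), n_universe = length(universe)),
            class = "boundary_enrichment")
}

#' @export
print.boundary_enrichment <- function(x, ...) {
  cat(sprintf(
    "<boundary_enrichment> %d/%d boundary-loss genes upregulated (%d up of %d); hypergeometric p = %.3g\n",
    x$overlap, x$n_foreground, x$n_upregulated, x$n_universe, x$p))
  invisible(x)
}

#' Correlate paired per-feature change values
#'
#' Pearson correlation with a two-sided t-test, e.g. CTCF binding change
#' against promoter H3K27ac change on the same features.
#'
#' @param data Data frame holding the two columns, or NULL to pass
#'   vectors.
#' @param x,y Column names (with `data`) or numeric vectors.
#' @return Tibble: r, p, n, undefined (flag for zero-variance input).
#' @export
correlate_change <- function(data = NULL, x, y) {
  if (!is.null(data)) { x <- data[[x]]; y <- data[[y]] }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  assert_that(length(x) >= 3, "need at least 3 paired finite values")
  if (sd(x) == 0 || sd(y) == 0) {
    rlang::warn("zero variance; correlation undefined")
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = length(x),
                          undefined = TRUE))
  }
  ct <- cor.test(x, y)
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 undefined = FALSE)
}
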