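tb <- function(...) tibble::tibble(...)

test_that("active promoters require all three marks inside the half-open window", {
  tss <- tb(gene = c("gA", "gB", "gC"), chrom = "chr1",
            tss = c(10000, 50000, 90000), strand = "+")
  peaks <- list(
    H3K27ac = tb(chrom = "chr1", start = c(9500, 48000, 91000),
                 end = c(9600, 48100, 91100)),
    ATAC = tb(chrom = "chr1", start = c(10100, 52000, 88100),
              end = c(10200, 52100, 88200)),
    H3K4me3 = tb(chrom = "chr1", start = c(8200, 49900, 89000),
                 end = c(8300, 50050, 89100)))
  pr <- call_active_promoters(tss, peaks)
  expect_true(pr$active[pr$gene == "gA"])
  ## gB: ATAC peak starts exactly at tss + 2000 -> half-open, no overlap
  expect_false(pr$active[pr$gene == "gB"])
  expect_false(pr$ATAC[pr$gene == "gB"])
  expect_true(pr$H3K27ac[pr$gene == "gB"])
  expect_true(pr$active[pr$gene == "gC"])
  ## out-of-bounds TSS rejected with diagnostic
  expect_warning(
    pr2 <- call_active_promoters(tb(gene = "gX", chrom = "chr1",
                                    tss = 2e6, strand = "+"),
                                 peaks, chrom_sizes = c(chr1 = 1e6)),
    "beyond")
  expect_equal(nrow(pr2), 0L)
})

test_that("promoter calls are invariant to peak order and peak splitting", {
  tss <- tb(gene = "gA", chrom = "chr1", tss = 10000, strand = "+")
  peaks <- list(
    H3K27ac = tb(chrom = "chr1", start = c(9500, 300), end = c(9700, 400)),
    ATAC = tb(chrom = "chr1", start = 9900, end = 10100),
    H3K4me3 = tb(chrom = "chr1", start = 11000, end = 11500))
  p1 <- call_active_promoters(tss, peaks)
  peaks2 <- peaks
  peaks2$H3K27ac <- peaks$H3K27ac[c(2, 1), ]
  ## split the ATAC peak into abutting pieces covering the same bases
  peaks2$ATAC <- tb(chrom = "chr1", start = c(9900, 10000),
                    end = c(10000, 10100))
  p2 <- call_active_promoters(tss, peaks2)
  expect_equal(p1$active, p2$active)
})

test_that("enhancer rule: overlapping K27ac/K4me1 outside promoter windows", {
  k27 <- tb(chrom = "chr1", start = c(100, 5000, 9000),
            end = c(200, 5200, 9100), name = c("e1", "e2", "e3"))
  k41 <- tb(chrom = "chr1", start = c(150, 5100), end = c(250, 5300))
  pw <- tb(chrom = "chr1", start = 4900, end = 5400)
  enh <- call_enhancers(k27, k41, pw)
  ## e1 overlaps K4me1 and no promoter; e2 overlaps a promoter window;
  ## e3 has no K4me1 support
  expect_equal(enh$name, "e1")
  expect_equal(enh$start, 100)
  expect_equal(enh$end, 200)
  enh_i <- call_enhancers(k27, k41, pw, coords = "intersection")
  expect_equal(enh_i$start, 150)
  expect_equal(enh_i$end, 200)
  ## noiseless planted landscape: rule recovers truth exactly
  land <- generate_regulatory_landscape(landscape_config(seed = 7))
  prom <- call_active_promoters(land$tss, land$peaks)
  pws <- tb(chrom = prom$chrom[prom$active],
            start = prom$window_start[prom$active],
            end = prom$window_end[prom$active])
  got <- call_enhancers(land$peaks$H3K27ac, land$peaks$H3K4me1, pws)
  expect_identical(paste(got$chrom, got$start, got$end),
                   paste(land$enhancer_truth$chrom,
                         land$enhancer_truth$start,
                         land$enhancer_truth$end))
})

test_that("nearest-gene linking matches the quadratic oracle and tie rules", {
  ## tie: midpoint 500 equidistant from TSS 400 and 600
  el <- tb(chrom = "chr1", start = 450, end = 550)
  tss <- tb(gene = c("far", "right", "left"), chrom = "chr1",
            tss = c(5000, 600, 400), strand = c("+", "+", "-"))
  lk <- link_nearest_gene(el, tss)
  expect_equal(lk$nearest_gene, "left")  # smaller coordinate wins the tie
  ## element containing a TSS -> distance 0
  el2 <- tb(chrom = "chr1", start = 590, end = 650)
  expect_equal(link_nearest_gene(el2, tss)$distance, 0)
  ## chromosome without TSS -> none
  el3 <- tb(chrom = "chrZ", start = 0, end = 10)
  expect_true(is.na(link_nearest_gene(el3, tss)$nearest_gene))
  ## random fixtures vs oracle
  withr::with_seed(31, {
    for (i in 1:5) {
      els <- random_intervals(40)
      ts <- tb(gene = sprintf("t%03d", 1:30), chrom = "chrT",
               tss = sample.int(1e6, 30), strand = "+")
      expect_identical(link_nearest_gene(els, ts)$nearest_gene,
                       oracle_nearest(els, ts))
    }
  })
  ## max_range produces explicit missing links
  lk4 <- link_nearest_gene(el, tss, max_range = 50)
  expect_true(is.na(lk4$nearest_gene))
})

test_that("CTCF categorisation follows the precedence rules", {
  prom <- tb(gene = "gP", chrom = "chr1", tss = 300000, strand = "+",
             window_start = 298000, window_end = 302000, active = TRUE)
  enh <- tb(chrom = "chr1", start = 219000, end = 220000)
  tss <- tb(gene = "gP", chrom = "chr1", tss = 300000, strand = "+")
  tads <- tb(chrom = "chr1", start = 0, end = 10)
  ## site inside the promoter window -> promoter regardless of surroundings
  s1 <- tb(chrom = "chr1", start = 299000, end = 299400, name = "s1")
  ## enhancer at -50 kb, promoter at +30 kb -> intervening
  s2 <- tb(chrom = "chr1", start = 269800, end = 270200, name = "s2")
  ## enhancer and promoter both on the same side -> not intervening
  s3 <- tb(chrom = "chr1", start = 100000, end = 100400, name = "s3")
  cat_ <- categorize_ctcf_sites(dplyr::bind_rows(s1, s2, s3), prom, enh, tss,
                                tads)
  expect_equal(as.character(cat_$category),
               c("promoter", "enhancer_promoter_intervening", "other"))
  expect_equal(cat_$linked_gene[1:2], c("gP", "gP"))
  ## beyond the 200 kb range the intervening rule lapses
  s4 <- tb(chrom = "chr1", start = 550000, end = 550400, name = "s4")
  cat4 <- categorize_ctcf_sites(s4, prom, enh, tss, tads)
  expect_equal(as.character(cat4$category), "other")
  ## boundary flag retained when intervening wins
  tads2 <- tb(chrom = "chr1", start = 269000, end = 271000)
  cat5 <- categorize_ctcf_sites(s2, prom, enh, tss, tads2)
  expect_equal(as.character(cat5$category), "enhancer_promoter_intervening")
  expect_true(cat5$flag_boundary)
})

test_that("planted landscape is recovered with perfect recall and precision", {
  land <- generate_regulatory_landscape(landscape_config(seed = 13))
  prom <- call_active_promoters(land$tss, land$peaks,
                                chrom_sizes = land$chrom_sizes)
  truth <- land$promoter_truth
  expect_identical(prom$active[match(truth$gene, prom$gene)], truth$active)
  enh <- call_enhancers(land$peaks$H3K27ac, land$peaks$H3K4me1,
                        tb(chrom = prom$chrom[prom$active],
                           start = prom$window_start[prom$active],
                           end = prom$window_end[prom$active]))
  cat_ <- categorize_ctcf_sites(land$ctcf_sites, prom, enh, land$tss,
                                land$tad_boundaries)
  got <- as.character(cat_$category[match(land$ctcf_truth$site, cat_$name)])
  expect_identical(got, land$ctcf_truth$category)
  ## linked genes agree where truth defines them
  has_link <- !is.na(land$ctcf_truth$linked_gene) &
    land$ctcf_truth$category != "other"
  expect_identical(cat_$linked_gene[match(land$ctcf_truth$site[has_link],
                                          cat_$name)],
                   land$ctcf_truth$linked_gene[has_link])
})

test_that("size factors follow median-of-ratios with geometric-mean centring", {
  counts <- rbind(c(10, 20), c(20, 40))
  sf <- size_factors(counts)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)
  expect_equal(prod(sf), 1, tolerance = 1e-12)
  ## property: product is 1 on random matrices
  withr::with_seed(17, {
    for (i in 1:5) {
      m <- matrix(rpois(200, 40) + 1, ncol = 4)
      expect_equal(prod(size_factors(m)), 1, tolerance = 1e-9)
    }
  })
})

test_that("differential region classes honour both thresholds", {
  lfc <- c(rep(2, 30), rep(-2, 30), rep(0, 140))
  rc <- simulate_region_counts(200, lfc = lfc, depth = 80, n_rep = 3,
                               seed = 19)
  db <- differential_region_test(rc$counts, rc$condition)
  expect_true(all(db$p_adj >= db$p, na.rm = TRUE))
  expect_true(all(db$class[db$p_adj >= 0.05 | abs(db$log2FC) <= log2(1.5)] ==
                    "unchanged", na.rm = TRUE))
  expect_gt(mean(db$class[1:30] == "increased"), 0.8)
  expect_gt(mean(db$class[31:60] == "decreased"), 0.8)
  ## all-zero regions are untested and unchanged
  m <- rc$counts; m[1, ] <- 0
  db0 <- differential_region_test(m, rc$condition)
  expect_false(db0$tested[1])
  expect_equal(as.character(db0$class[1]), "unchanged")
})

test_that("size-factor cross-check against the reference implementation", {
  skip_if_not_installed("DESeq2")
  withr::with_seed(23, {
    m <- matrix(rnbinom(600, mu = 50, size = 10) + 1, ncol = 6)
    sf_ref <- DESeq2::estimateSizeFactorsForMatrix(m)
    sf_ref <- sf_ref / exp(mean(log(sf_ref)))
    expect_equal(unname(size_factors(m)), unname(sf_ref), tolerance = 1e-8)
  })
})

test_that("boundary upregulation test is exact in the extreme case", {
  catalog <- tb(chrom = "chr1", start = c(0, 100), end = c(50, 150),
                name = c("a", "b"),
                category = factor(rep("tad_boundary", 2),
                                  levels = c("promoter",
                                             "enhancer_promoter_intervening",
                                             "tad_boundary", "other")),
                linked_gene = c("g1", "g2"),
                binding_class = "decreased")
  de <- tb(gene = paste0("g", 1:20), upregulated = c(TRUE, TRUE, rep(FALSE, 18)))
  bt <- boundary_upregulation_test(catalog, de)
  ## foreground (2) entirely upregulated, K = 2 of N = 20:
  ## p = C(2,2)C(18,0)/C(20,2)
  expect_equal(bt$p, 1 / choose(20, 2), tolerance = 1e-12)
  expect_error(
    boundary_upregulation_test(dplyr::mutate(catalog,
                                             binding_class = "increased"), de),
    "empty foreground")
})

test_that("change correlation handles exact and degenerate cases", {
  x <- rnorm(20)
  expect_equal(correlate_change(x = x, y = x)$r, 1)
  expect_equal(correlate_change(x = x, y = -x)$r, -1)
  expect_warning(res <- correlate_change(x = x, y = rep(1, 20)), "zero variance")
  expect_true(res$undefined)
  expect_error(correlate_change(x = 1:2, y = 1:2), "at least 3")
  df <- tb(a = x, b = x + rnorm(20, sd = 0.1))
  expect_gt(correlate_change(df, "a", "b")$r, 0.9)
})
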