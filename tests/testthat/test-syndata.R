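test_that("same config reproduces byte-identical populations", {
  cfg <- sim_config(seed = 9, n_cells = 150, n_genes = 200,
                    module_sizes = c(maturation = 30L),
                    module_loadings = c(maturation = 1), keep_mu = FALSE)
  p1 <- generate_cell_population(cfg)
  p2 <- generate_cell_population(cfg)
  expect_identical(as.matrix(p1$counts), as.matrix(p2$counts))
  expect_identical(p1$cell_meta, p2$cell_meta)
})

test_that("config validation rejects impossible module allocations", {
  expect_error(sim_config(n_genes = 100, module_sizes = c(m = 200L),
                          module_loadings = c(m = 1)), "exceed")
  expect_error(sim_config(frac_senescent = 1.2), "frac_senescent")
  expect_error(sim_config(module_sizes = c(a = 10L),
                          module_loadings = c(b = 1)), "share names")
})

test_that("population structure invariants hold", {
  pop <- generate_cell_population(sim_config(seed = 2, n_cells = 300,
                                             n_genes = 300))
  expect_equal(unname(pop$cell_meta$library_size),
               unname(Matrix::colSums(pop$counts)))
  expect_equal(sum(pop$gene_meta$is_marker), 1L)
  mods <- pop$gene_meta$module[!is.na(pop$gene_meta$module)]
  expect_equal(unname(table(mods)[names(sim_config()$module_sizes)]),
               unname(sim_config()$module_sizes),
               ignore_attr = TRUE)
})

test_that("marker detection tracks the planted senescent fraction at full capture", {
  pop <- generate_cell_population(sim_config(seed = 4, n_cells = 2000,
                                             n_genes = 2000,
                                             frac_senescent = 0.15,
                                             marker_capture = 1,
                                             keep_mu = FALSE))
  detected <- mean(pop$counts["CDKN2A", ] > 0)
  expect_lt(abs(detected - 0.15), 0.03)
})

test_that("zero loadings give gene-marker correlations centred at zero", {
  pop <- generate_cell_population(sim_config(
    seed = 6, n_cells = 1000, n_genes = 300,
    module_loadings = c(maturation = 0, isg = 0, sasp = 0), keep_mu = FALSE))
  m <- as.matrix(pop$counts)
  r <- suppressWarnings(cor(t(m[-1, ]), m["CDKN2A", ]))
  expect_lt(mean(abs(r), na.rm = TRUE), 3 / sqrt(1000))
})

test_that("stronger module loadings raise the median gene-marker correlation", {
  meds <- vapply(c(0.3, 0.8, 1.5), function(l) {
    pop <- generate_cell_population(sim_config(
      seed = 8, n_cells = 800, n_genes = 300,
      module_sizes = c(maturation = 40L),
      module_loadings = c(maturation = l), keep_mu = FALSE))
    m <- as.matrix(pop$counts)
    mod <- pop$gene_meta$gene[!is.na(pop$gene_meta$module)]
    median(suppressWarnings(cor(t(m[mod, ]), m["CDKN2A", ])), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("intensity table plants a two-fold foci rate and is reproducible", {
  it <- generate_intensity_table(n_cells = 4000, foci_rate = 0.5,
                                 foci_ratio = 2, seed = 3)
  m1 <- mean(it$foci_count[it$senescent == 1])
  m0 <- mean(it$foci_count[it$senescent == 0])
  expect_lt(abs(m1 / m0 - 2), 0.35)
  expect_identical(it, generate_intensity_table(n_cells = 4000,
                                                foci_rate = 0.5,
                                                foci_ratio = 2, seed = 3))
  expect_true(all(it$foci_count >= 0))
  expect_true(all(it$p16 > 0))
  ## no intensity shift => top-20% classification recovers senescence at chance
  it0 <- generate_intensity_table(n_cells = 4000, seed = 5,
                                  channels = list(p16 = c(meanlog = 4,
                                                          sdlog = 0.5,
                                                          shift = 0)))
  cls <- classify_cells_by_value(setNames(it0$p16, it0$cell), 80, 20)
  hi <- cls$cell[cls$class == "high"]
  frac_sen <- mean(it0$senescent[match(hi, it0$cell)])
  expect_lt(abs(frac_sen - mean(it0$senescent)), 0.05)
})

test_that("landscape geometry matches its planted truth", {
  land <- generate_regulatory_landscape(landscape_config(seed = 2))
  cs <- land$chrom_sizes[[1]]
  for (mark in names(land$peaks)) {
    p <- land$peaks[[mark]]
    expect_true(all(p$start >= 0 & p$end <= cs), info = mark)
    expect_true(all(p$start < p$end), info = mark)
    expect_true(!is.unsorted(p$start))
  }
  ## every planted-active TSS has all three marks within +/- 2 kb
  act <- land$promoter_truth$gene[land$promoter_truth$active]
  tss_act <- land$tss[land$tss$gene %in% act, ]
  win <- tibble::tibble(chrom = tss_act$chrom, start = tss_act$tss - 2000,
                        end = tss_act$tss + 2000)
  for (mark in c("H3K27ac", "ATAC", "H3K4me3")) {
    expect_true(all(oracle_overlaps_any(win, land$peaks[[mark]])), info = mark)
  }
  ## planted boundary CTCF sites overlap a TAD boundary interval
  bnd <- land$ctcf_truth$site[land$ctcf_truth$category == "tad_boundary"]
  sites <- land$ctcf_sites[land$ctcf_sites$name %in% bnd, ]
  expect_true(all(oracle_overlaps_any(sites, land$tad_boundaries)))
  ## coupling: ~90% of boundary-loss linked genes upregulated
  loss_genes <- land$ctcf_truth$linked_gene[
    land$ctcf_truth$category == "tad_boundary" & land$ctcf_truth$planted_lfc < 0]
  up <- land$gene_truth$upregulated[match(loss_genes, land$gene_truth$gene)]
  expect_gt(mean(up), 0.9 - 3 * sqrt(0.9 * 0.1 / length(up)))
  expect_lt(mean(up), 0.9 + 3 * sqrt(0.9 * 0.1 / length(up)))
})

test_that("infeasible packing is rejected with a diagnostic", {
  expect_error(landscape_config(chrom_size = 2e6), "infeasible packing")
})

test_that("fixtures round-trip and the manifest tracks content", {
  pop <- generate_cell_population(sim_config(
    seed = 12, n_cells = 60, n_genes = 80,
    module_sizes = c(maturation = 12L), module_loadings = c(maturation = 1),
    keep_mu = FALSE))
  land <- generate_regulatory_landscape(landscape_config(
    seed = 12, n_tss = 10, n_enhancers = 5, n_intervening = 4, n_boundary = 5,
    n_other = 3, n_ctcf_promoter = 3))
  it <- generate_intensity_table(n_cells = 50, seed = 12)
  dir1 <- withr::local_tempdir()
  mf <- write_fixtures(pop, land, it, dir1)
  expect_true(all(file.exists(file.path(dir1, mf$file))))
  back <- Matrix::readMM(file.path(dir1, "counts.mtx"))
  expect_equal(as.matrix(back), unname(as.matrix(pop$counts)))
  bed <- read_bed(file.path(dir1, "peaks_CTCF.bed"))
  expect_true(!is.unsorted(bed$start))
  ## checksum changes iff content changes
  dir2 <- withr::local_tempdir()
  mf2 <- write_fixtures(pop, land, it, dir2)
  expect_identical(mf$md5, mf2$md5)
  pop$counts[1, 1] <- pop$counts[1, 1] + 1
  dir3 <- withr::local_tempdir()
  mf3 <- write_fixtures(pop, land, it, dir3)
  expect_false(identical(mf$md5[mf$file == "counts.mtx"],
                         mf3$md5[mf3$file == "counts.mtx"]))
})
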