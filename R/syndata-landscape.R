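#' Configuration for a synthetic regulatory landscape
#'
#' The toy genome is a single 10 Mb chromosome partitioned into five
#' well-separated districts (promoter, enhancer, enhancer-promoter
#' intervening, TAD-boundary, isolated), with >= 200 kb of empty sequence
#' between districts so that the CTCF categorisation rules, which look
#' 200 kb to either side, see exactly the planted configuration and
#' nothing else. All coordinates are 0-based half-open.
#'
#' @param seed Integer RNG seed.
#' @param chrom,chrom_size Chromosome name and length (bp).
#' @param n_tss Number of gene TSSs in the promoter district.
#' @param frac_active Fraction of those promoters planted active (all
#'   three activation marks within +/-2 kb of the TSS).
#' @param n_enhancers Stand-alone enhancers (overlapping H3K27ac/H3K4me1
#'   pairs outside every promoter window).
#' @param n_intervening CTCF sites planted between an enhancer and an
#'   active promoter, both within 200 kb.
#' @param n_boundary CTCF sites planted inside TAD-boundary intervals,
#'   each with a linked gene TSS 6 kb away (promoter kept inactive).
#' @param n_other Isolated CTCF sites (no promoter, enhancer or boundary
#'   within range).
#' @param n_ctcf_promoter CTCF sites planted inside active-promoter windows.
#' @param boundary_lfc Planted log2 change of CTCF binding at boundary
#'   sites (negative = loss).
#' @param coupling_prob Probability that the gene linked to a
#'   boundary-loss site is planted upregulated.
#' @param background_up_rate Baseline upregulation probability for all
#'   other genes.
#' @param n_rep,region_depth,region_dispersion Replicates per condition,
#'   mean region depth and NB dispersion for the planted region counts.
#' @param n_background_regions Unchanged background regions appended to
#'   the region-count matrix (rows `bg_*`). Median-of-ratios
#'   normalisation assumes most regions are unchanged; a realistic
#'   peak-union matrix is dominated by such rows.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(seed = 1L,
                             chrom = "chrSim",
                             chrom_size = 1e7,
                             n_tss = 120L,
                             frac_active = 0.7,
                             n_enhancers = 80L,
                             n_intervening = 50L,
                             n_boundary = 100L,
                             n_other = 40L,
                             n_ctcf_promoter = 40L,
                             boundary_lfc = -1.585,
                             coupling_prob = 0.9,
                             background_up_rate = 0.1,
                             n_rep = 3L,
                             region_depth = 50,
                             region_dispersion = 0.05,
                             n_background_regions = 800L) {
  assert_that(chrom_size > 1e4, "chromosome must exceed 10 kb")
  assert_that(coupling_prob >= 0 && coupling_prob <= 1,
              "coupling_prob must be in [0,1]")
  cfg <- list(seed = as.integer(seed), chrom = chrom, chrom_size = chrom_size,
              n_tss = as.integer(n_tss), frac_active = frac_active,
              n_enhancers = as.integer(n_enhancers),
              n_intervening = as.integer(n_intervening),
              n_boundary = as.integer(n_boundary),
              n_other = as.integer(n_other),
              n_ctcf_promoter = as.integer(n_ctcf_promoter),
              boundary_lfc = boundary_lfc, coupling_prob = coupling_prob,
              background_up_rate = background_up_rate,
              n_rep = as.integer(n_rep), region_depth = region_depth,
              region_dispersion = region_dispersion,
              n_background_regions = as.integer(n_background_regions))
  ## feasibility: districts are sized below from these counts
  need <- 12000 * n_tss + 15000 * n_enhancers + 45000 * n_intervening +
    15000 * n_boundary + 15000 * n_other + 5 * 250000
  if (need > chrom_size) {
    rlang::abort(sprintf(
      "infeasible packing: elements need ~%.1f Mb but chromosome is %.1f Mb",
      need / 1e6, chrom_size / 1e6))
  }
  structure(cfg, class = "landscape_config")
}

#' Generate a toy regulatory landscape with planted element classes
#'
#' Builds peak sets (H3K27ac, H3K4me1, H3K4me3, ATAC, CTCF), a TSS table,
#' TAD boundaries, a region-by-sample count matrix with planted binding
#' changes at CTCF sites, and truth tables sufficient to score every
#' downstream interval operation. See [landscape_config()] for the
#' geometry guarantees.
#'
#' @param config A [landscape_config()].
#' @return List of class `regulatory_landscape`: `chrom_sizes`,
#'   `tss` (tibble gene/chrom/tss/strand), `peaks` (named list of interval
#'   tibbles per mark), `tad_boundaries`, `ctcf_sites`,
#'   `region_counts` (matrix site x sample), `condition` (factor),
#'   `ctcf_truth` (site, category, planted_lfc, linked_gene),
#'   `promoter_truth`, `enhancer_truth`, `gene_truth` (gene, upregulated).
#' @export
generate_regulatory_landscape <- function(config) {
  assert_that(inherits(config, "landscape_config"), "config must be a landscape_config")
  with_seed(config$seed, {
    ch <- config$chrom
    gap <- 250000  # inter-district isolation > 200 kb categorisation range

    tss <- list(); peaks <- list(H3K27ac = list(), H3K4me1 = list(),
                                 H3K4me3 = list(), ATAC = list(), CTCF = list())
    tads <- list(); ctcf_truth <- list()
    pos <- gap
    gene_i <- 0L
    new_gene <- function() { gene_i <<- gene_i + 1L; sprintf("SG%04d", gene_i) }
    add_peak <- function(mark, start, end, name) {
      peaks[[mark]][[length(peaks[[mark]]) + 1L]] <<-
        tibble::tibble(chrom = ch, start = start, end = end, name = name)
    }

    ## --- promoter district: TSSs every 12 kb; frac_active get all marks
    active_flag <- rep(FALSE, config$n_tss)
    if (config$n_tss > 0) {
      active_flag[sample.int(config$n_tss, round(config$frac_active * config$n_tss))] <- TRUE
    }
    promoter_truth <- vector("list", config$n_tss)
    ctcf_prom_slots <- sort(sample(which(active_flag),
                                   min(config$n_ctcf_promoter, sum(active_flag))))
    for (i in seq_len(config$n_tss)) {
      t0 <- pos + 6000
      g <- new_gene()
      strand <- if (i %% 2 == 0) "+" else "-"
      tss[[length(tss) + 1L]] <- tibble::tibble(gene = g, chrom = ch,
                                                tss = t0, strand = strand)
      if (active_flag[i]) {
        add_peak("H3K27ac", t0 - 600, t0 + 400, paste0(g, "_pk27"))
        add_peak("ATAC", t0 - 300, t0 + 300, paste0(g, "_pkat"))
        add_peak("H3K4me3", t0 - 500, t0 + 700, paste0(g, "_pk43"))
      } else {
        ## inactive: at most two of the three marks
        keep <- sample(c("H3K27ac", "ATAC", "H3K4me3"), sample(0:2, 1))
        if ("H3K27ac" %in% keep) add_peak("H3K27ac", t0 - 600, t0 + 400, paste0(g, "_pk27"))
        if ("ATAC" %in% keep) add_peak("ATAC", t0 - 300, t0 + 300, paste0(g, "_pkat"))
        if ("H3K4me3" %in% keep) add_peak("H3K4me3", t0 - 500, t0 + 700, paste0(g, "_pk43"))
      }
      if (i %in% ctcf_prom_slots) {
        sid <- sprintf("ctcf_prom_%03d", match(i, ctcf_prom_slots))
        add_peak("CTCF", t0 + 800, t0 + 1200, sid)
        ctcf_truth[[length(ctcf_truth) + 1L]] <- tibble::tibble(
          site = sid, category = "promoter", planted_lfc = 0, linked_gene = g)
      }
      promoter_truth[[i]] <- tibble::tibble(gene = g, active = active_flag[i])
      pos <- pos + 12000
    }
    pos <- pos + gap

    ## --- enhancer district: overlapping K27ac/K4me1 pairs, no promoters near
    enhancer_truth <- vector("list", config$n_enhancers)
    for (i in seq_len(config$n_enhancers)) {
      e0 <- pos + 5000
      add_peak("H3K27ac", e0, e0 + 800, sprintf("enh_%03d_27", i))
      add_peak("H3K4me1", e0 + 200, e0 + 1000, sprintf("enh_%03d_41", i))
      enhancer_truth[[i]] <- tibble::tibble(chrom = ch, start = e0, end = e0 + 800)
      pos <- pos + 15000
    }
    pos <- pos + gap

    ## --- intervening district: enhancer .. CTCF .. active promoter triplets
    for (i in seq_len(config$n_intervening)) {
      e0 <- pos + 2000
      add_peak("H3K27ac", e0, e0 + 800, sprintf("ienh_%03d_27", i))
      add_peak("H3K4me1", e0 + 200, e0 + 1000, sprintf("ienh_%03d_41", i))
      enhancer_truth[[length(enhancer_truth) + 1L]] <-
        tibble::tibble(chrom = ch, start = e0, end = e0 + 800)
      sid <- sprintf("ctcf_intv_%03d", i)
      add_peak("CTCF", pos + 20000, pos + 20400, sid)
      t0 <- pos + 40000
      g <- new_gene()
      tss[[length(tss) + 1L]] <- tibble::tibble(gene = g, chrom = ch,
                                                tss = t0, strand = "+")
      add_peak("H3K27ac", t0 - 600, t0 + 400, paste0(g, "_pk27"))
      add_peak("ATAC", t0 - 300, t0 + 300, paste0(g, "_pkat"))
      add_peak("H3K4me3", t0 - 500, t0 + 700, paste0(g, "_pk43"))
      promoter_truth[[length(promoter_truth) + 1L]] <-
        tibble::tibble(gene = g, active = TRUE)
      ctcf_truth[[length(ctcf_truth) + 1L]] <- tibble::tibble(
        site = sid, category = "enhancer_promoter_intervening",
        planted_lfc = 0, linked_gene = g)
      pos <- pos + 45000
    }
    pos <- pos + gap

    ## --- boundary district: TAD boundary + CTCF inside + linked inactive TSS
    for (i in seq_len(config$n_boundary)) {
      b0 <- pos + 4000
      tads[[length(tads) + 1L]] <- tibble::tibble(chrom = ch, start = b0,
                                                  end = b0 + 2000,
                                                  name = sprintf("tad_b_%03d", i))
      sid <- sprintf("ctcf_bnd_%03d", i)
      add_peak("CTCF", b0 + 800, b0 + 1200, sid)
      g <- new_gene()
      tss[[length(tss) + 1L]] <- tibble::tibble(gene = g, chrom = ch,
                                                tss = b0 + 7000, strand = "+")
      ## only one mark: promoter stays inactive, site stays in boundary class
      add_peak("H3K4me3", b0 + 6500, b0 + 7500, paste0(g, "_pk43"))
      promoter_truth[[length(promoter_truth) + 1L]] <-
        tibble::tibble(gene = g, active = FALSE)
      ctcf_truth[[length(ctcf_truth) + 1L]] <- tibble::tibble(
        site = sid, category = "tad_boundary",
        planted_lfc = config$boundary_lfc, linked_gene = g)
      pos <- pos + 15000
    }
    pos <- pos + gap

    ## --- isolated district: lone CTCF sites
    for (i in seq_len(config$n_other)) {
      sid <- sprintf("ctcf_other_%03d", i)
      add_peak("CTCF", pos + 5000, pos + 5400, sid)
      ctcf_truth[[length(ctcf_truth) + 1L]] <- tibble::tibble(
        site = sid, category = "other", planted_lfc = 0,
        linked_gene = NA_character_)
      pos <- pos + 15000
    }
    if (pos + gap > config$chrom_size) {
      rlang::abort("infeasible packing: ran past chromosome end")
    }

    tss <- dplyr::bind_rows(tss)
    peaks <- lapply(peaks, function(p) dplyr::arrange(dplyr::bind_rows(p), chrom, start))
    tads <- dplyr::bind_rows(tads)
    ctcf_truth <- dplyr::bind_rows(ctcf_truth)
    promoter_truth <- dplyr::bind_rows(promoter_truth)
    enhancer_truth <- dplyr::bind_rows(enhancer_truth) |>
      dplyr::arrange(chrom, start)

    ## region counts over CTCF sites with planted binding changes, plus
    ## unchanged background regions so the size-factor reference is
    ## anchored on null rows
    ctcf_sites <- peaks$CTCF
    lfc <- ctcf_truth$planted_lfc[match(ctcf_sites$name, ctcf_truth$site)]
    rc <- simulate_region_counts(
      n_regions = nrow(ctcf_sites) + config$n_background_regions,
      lfc = c(lfc, rep(0, config$n_background_regions)),
      depth = config$region_depth,
      dispersion = config$region_dispersion, n_rep = config$n_rep,
      seed = config$seed + 1L)
    rownames(rc$counts) <- c(ctcf_sites$name,
                             sprintf("bg_%04d",
                                     seq_len(config$n_background_regions)))

    ## gene truth: boundary-loss linked genes upregulated with coupling_prob
    loss_genes <- ctcf_truth$linked_gene[
      ctcf_truth$category == "tad_boundary" & ctcf_truth$planted_lfc < 0]
    up <- runif(nrow(tss)) < config$background_up_rate
    names(up) <- tss$gene
    up[loss_genes] <- runif(length(loss_genes)) < config$coupling_prob
    gene_truth <- tibble::tibble(gene = tss$gene, upregulated = unname(up[tss$gene]))

    structure(list(
      chrom_sizes = setNames(config$chrom_size, ch),
      tss = tss, peaks = peaks, tad_boundaries = tads,
      ctcf_sites = ctcf_sites,
      region_counts = rc$counts, condition = rc$condition,
      ctcf_truth = ctcf_truth, promoter_truth = promoter_truth,
      enhancer_truth = enhancer_truth, gene_truth = gene_truth,
      config = config
    ), class = "regulatory_landscape")
  })
}

#' Simulate a region-by-sample count matrix with planted fold changes
#'
#' Two conditions with `n_rep` samples each; counts are NB with mean
#' `depth * 2^(lfc * condition)` (condition 2 carries the change).
#'
#' @param n_regions Number of regions.
#' @param lfc Planted log2 fold change, length 1 or `n_regions`.
#' @param depth Mean count in condition 1.
#' @param dispersion NB dispersion.
#' @param n_rep Samples per condition.
#' @param seed RNG seed.
#' @param depth_factors Optional per-sample depth multipliers (length
#'   `2 * n_rep`); used to plant known size factors.
#' @return List with `counts` (matrix), `condition` (factor) and
#'   `lfc` (planted values).
#' @export
simulate_region_counts <- function(n_regions, lfc = 0, depth = 50,
                                   dispersion = 0.05, n_rep = 3L, seed = 1L,
                                   depth_factors = NULL) {
  assert_that(depth > 0 && dispersion > 0, "depth and dispersion must be > 0")
  lfc <- rep_len(lfc, n_regions)
  n_samp <- 2L * n_rep
  depth_factors <- depth_factors %||% rep(1, n_samp)
  assert_that(length(depth_factors) == n_samp,
              "depth_factors must have one entry per sample")
  condition <- factor(rep(c("ctrl", "sen"), each = n_rep))
  with_seed(seed, {
    ## columns: ctrl reps then sen reps, scaled by sample depth factors
    mu <- cbind(matrix(depth, n_regions, n_rep),
                matrix(depth * 2^lfc, n_regions, n_rep))
    mu <- sweep(mu, 2L, depth_factors, `*`)
    counts <- matrix(rnbinom(length(mu), size = 1 / dispersion, mu = mu),
                     nrow = n_regions,
                     dimnames = list(sprintf("region%05d", seq_len(n_regions)),
                                     paste0(rep(c("ctrl", "sen"), each = n_rep),
                                            "_", rep(seq_len(n_rep), 2))))
    list(counts = counts, condition = condition, lfc = lfc)
  })
}

#' Simulate a per-cell fluorescence intensity table
#'
#' Senescent cells draw channel intensities from a log-shifted lognormal
#' and cytosolic-DNA foci from a Poisson with a rate `foci_ratio` times
#' the non-senescent rate (defaults double it).
#'
#' @param n_cells Number of cells.
#' @param frac_senescent Proportion senescent.
#' @param n_islets Number of islet groups cells are assigned to.
#' @param channels Named list: per channel `c(meanlog, sdlog, shift)`
#'   where `shift` is added to meanlog in senescent cells.
#' @param foci_rate Poisson foci rate in non-senescent cells.
#' @param foci_ratio Senescent / non-senescent foci rate ratio.
#' @param seed RNG seed.
#' @return Tibble: cell, islet, one column per channel, foci_count,
#'   senescent (truth).
#' @export
generate_intensity_table <- function(n_cells = 3000L,
                                     frac_senescent = 0.2,
                                     n_islets = 10L,
                                     channels = list(
                                       p16 = c(meanlog = 4, sdlog = 0.5, shift = 1.2),
                                       HLA_I = c(meanlog = 5, sdlog = 0.5, shift = 0.6)),
                                     foci_rate = 0.5,
                                     foci_ratio = 2.0,
                                     seed = 1L) {
  assert_that(foci_rate > 0 && foci_ratio > 0, "foci rates must be positive")
  with_seed(seed, {
    s <- rbinom(n_cells, 1L, frac_senescent)
    out <- tibble::tibble(
      cell = sprintf("imgcell%05d", seq_len(n_cells)),
      islet = factor(sprintf("islet%02d", sample.int(n_islets, n_cells, TRUE)))
    )
    for (chn in names(channels)) {
      p <- channels[[chn]]
      out[[chn]] <- rlnorm(n_cells, p[["meanlog"]] + p[["shift"]] * s, p[["sdlog"]])
    }
    out$foci_count <- rpois(n_cells, foci_rate * foci_ratio^s)
    out$senescent <- as.integer(s)
    out
  })
}
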