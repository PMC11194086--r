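#' Configuration for a synthetic single-cell population
#'
#' Bundles and validates every knob of the count-matrix generator. The
#' defaults describe the study conditions the package is calibrated
#' against: a rare (15%) senescent state anchored on a marker transcript
#' that is lowly captured (so its marginal detection rate is ~14.6% of
#' cells), a strongly co-regulated "maturation" module, a weaker
#' interferon-response module, and a flat SASP module that does not track
#' the senescent state.
#'
#' @param seed Integer RNG seed; every draw in the generator flows from it.
#' @param n_cells,n_genes Dimensions of the count matrix.
#' @param frac_senescent Proportion of cells in the latent senescent state.
#' @param marker_capture Probability that a senescent cell retains its
#'   marker counts (1 - zero-inflation rate). Low capture models the
#'   marker transcript's poor detection despite stable expression.
#' @param module_sizes Named integer vector: genes per planted module.
#' @param module_loadings Named numeric vector: log-scale effect of the
#'   latent state on each module's genes.
#' @param dispersion NB dispersion phi (Var = mu + phi mu^2).
#' @param depth_lognormal Length-2 vector `c(meanlog, sdlog)` of the
#'   lognormal cell depth distribution.
#' @param n_donors,n_tech Numbers of donor and technology batches.
#' @param batch_sd Log-scale s.d. of per-gene donor and tech effects.
#' @param gene_baseline_sd Log-scale s.d. of per-gene baseline rates.
#' @param marker_gene Name given to the marker gene.
#' @param marker_baseline,marker_loading Log-scale relative rate of the
#'   marker in non-senescent cells and its increment in senescent cells.
#' @param n_mito Number of genes named with the `MT-` prefix (for QC).
#' @param keep_mu Keep the dense matrix of true normalised expected counts
#'   in the truth slot (needed to score recovery accuracy).
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_cells = 2000L,
                       n_genes = 2000L,
                       frac_senescent = 0.15,
                       marker_capture = 0.97,
                       module_sizes = c(maturation = 120L, isg = 60L, sasp = 40L),
                       module_loadings = c(maturation = 1.0, isg = 0.5, sasp = 0.0),
                       dispersion = 0.4,
                       depth_lognormal = c(meanlog = log(2500), sdlog = 0.3),
                       n_donors = 4L,
                       n_tech = 2L,
                       batch_sd = 0.1,
                       gene_baseline_sd = 0.8,
                       marker_gene = "CDKN2A",
                       marker_baseline = -4.5,
                       marker_loading = 6.7,
                       n_mito = 10L,
                       keep_mu = TRUE) {
  assert_that(frac_senescent >= 0 && frac_senescent <= 1,
              "frac_senescent must be in [0,1]")
  assert_that(marker_capture >= 0 && marker_capture <= 1,
              "marker_capture must be in [0,1]")
  assert_that(n_cells > 0 && n_genes > 1, "n_cells and n_genes must be positive")
  assert_that(dispersion > 0, "dispersion must be > 0")
  assert_that(all(module_sizes > 0), "module sizes must be positive")
  assert_that(setequal(names(module_sizes), names(module_loadings)),
              "module_sizes and module_loadings must share names")
  ## marker + mito genes + module genes must fit
  if (sum(module_sizes) + 1L + n_mito > n_genes) {
    rlang::abort("module sizes (plus marker and mito genes) exceed n_genes")
  }
  structure(
    list(seed = as.integer(seed), n_cells = as.integer(n_cells),
         n_genes = as.integer(n_genes), frac_senescent = frac_senescent,
         marker_capture = marker_capture, module_sizes = module_sizes,
         module_loadings = module_loadings, dispersion = dispersion,
         depth_lognormal = depth_lognormal, n_donors = as.integer(n_donors),
         n_tech = as.integer(n_tech), batch_sd = batch_sd,
         gene_baseline_sd = gene_baseline_sd,
         marker_gene = marker_gene, marker_baseline = marker_baseline,
         marker_loading = marker_loading, n_mito = as.integer(n_mito),
         keep_mu = isTRUE(keep_mu)),
    class = "sim_config"
  )
}

#' Generate a synthetic single-cell population with a planted senescent state
#'
#' Draws a sparse gene-by-cell NB count matrix in which a binary latent
#' state drives the marker gene and the planted modules. Per-cell expected
#' counts are formed as `exp(baseline + loading * s_c + donor + tech)`,
#' normalised within each cell to a lognormal target depth, and sampled as
#' NB with the configured dispersion. Marker counts in senescent cells are
#' additionally zeroed with probability `1 - marker_capture` (low capture
#' as zero-inflation, not a lower mean). `cell_meta$library_size` records
#' the realised column sum.
#'
#' @param config A [sim_config()].
#' @return A list of class `cell_population` with elements `counts`
#'   (sparse dgCMatrix, genes x cells), `cell_meta` (tibble: cell, donor,
#'   tech, mito_fraction, library_size, senescent), `gene_meta` (tibble:
#'   gene, is_marker, module, loading) and `truth` (latent state, the true
#'   normalised mean matrix when `keep_mu`, and the config).
#' @export
#' @examples
#' pop <- generate_cell_population(sim_config(seed = 7, n_cells = 100, n_genes = 300))
#' dim(pop$counts)
generate_cell_population <- function(config) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  with_seed(config$seed, {
    nG <- config$n_genes; nC <- config$n_cells

    ## gene names: marker, mito block, then generic ids
    genes <- sprintf("G%04d", seq_len(nG))
    genes[1L] <- config$marker_gene
    if (config$n_mito > 0) {
      genes[2:(1 + config$n_mito)] <- sprintf("MT-G%02d", seq_len(config$n_mito))
    }

    ## module membership: contiguous blocks after marker+mito
    module <- rep(NA_character_, nG)
    loading <- rep(0, nG)
    at <- 2L + config$n_mito
    for (m in names(config$module_sizes)) {
      k <- config$module_sizes[[m]]
      idx <- at:(at + k - 1L)
      module[idx] <- m
      loading[idx] <- config$module_loadings[[m]]
      at <- at + k
    }

    s <- rbinom(nC, 1L, config$frac_senescent)
    donor <- sample.int(config$n_donors, nC, replace = TRUE)
    tech <- sample.int(config$n_tech, nC, replace = TRUE)

    base <- rnorm(nG, mean = 0, sd = config$gene_baseline_sd)
    base[1L] <- config$marker_baseline
    marker_load <- config$marker_loading

    donor_eff <- matrix(rnorm(nG * config$n_donors, sd = config$batch_sd),
                        nrow = nG)
    tech_eff <- matrix(rnorm(nG * config$n_tech, sd = config$batch_sd),
                       nrow = nG)

    log_rate <- base +
      outer(loading, s) +
      donor_eff[, donor, drop = FALSE] +
      tech_eff[, tech, drop = FALSE]
    log_rate[1L, ] <- config$marker_baseline + marker_load * s +
      donor_eff[1L, donor] + tech_eff[1L, tech]
    rate <- exp(log_rate)

    depth <- rlnorm(nC, config$depth_lognormal[[1]], config$depth_lognormal[[2]])
    mu <- sweep(rate, 2L, depth / colSums(rate), `*`)
    dimnames(mu) <- list(genes, sprintf("cell%05d", seq_len(nC)))

    counts <- matrix(
      rnbinom(nG * nC, size = 1 / config$dispersion, mu = mu),
      nrow = nG, dimnames = list(genes, sprintf("cell%05d", seq_len(nC)))
    )

    ## marker dropout: zero-inflation in senescent cells only
    sen <- which(s == 1L)
    if (length(sen)) {
      drop <- sen[runif(length(sen)) > config$marker_capture]
      counts[1L, drop] <- 0L
    }

    mito_idx <- grep("^MT-", genes)
    totals <- colSums(counts)
    mito_frac <- if (length(mito_idx)) colSums(counts[mito_idx, , drop = FALSE]) / pmax(totals, 1) else rep(0, nC)

    structure(list(
      counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
      cell_meta = tibble::tibble(
        cell = colnames(counts),
        donor = factor(paste0("donor", donor)),
        tech = factor(paste0("tech", tech)),
        mito_fraction = mito_frac,
        library_size = totals,
        senescent = as.integer(s)
      ),
      gene_meta = tibble::tibble(
        gene = genes,
        is_marker = genes == config$marker_gene,
        module = module,
        loading = loading
      ),
      truth = list(
        s = as.integer(s),
        mu = if (config$keep_mu) mu else NULL,
        config = config
      )
    ), class = "cell_population")
  })
}

#' @export
print.cell_population <- function(x, ...) {
  cat("<cell_population> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells; ", sum(x$cell_meta$senescent), " senescent cells planted\n",
      sep = "")
  invisible(x)
}
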