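#' Default pipeline configuration
#'
#' Returns the full default configuration for [run_pipeline()] as a
#' nested list; supply overrides as a (partial) list or a YAML file with
#' the same structure. Every stage seed is derived from the single
#' top-level `seed`.
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @param overrides Partial configuration list merged over the defaults.
#' @return Configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("senoscore_run_"),
                            overrides = list()) {
  base <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(simulate = TRUE, qc = TRUE, recover = TRUE, rank = TRUE,
                  signatures = TRUE, classify = TRUE, de = TRUE,
                  bootstrap = TRUE, enrichment = TRUE, chromatin = TRUE),
    sim = list(n_cells = 1200L, n_genes = 800L),
    landscape = list(),
    qc_profile = "tenx",
    recover = list(n_components = 20L, ridge = 1e-2),
    signature = list(N = 100L, n_bins = 25L, n_ctrl = 100L),
    classify = list(upper_pct = 70, lower_pct = 30),
    de = list(preset = "scrna", use_cdr = TRUE),
    bootstrap = list(n_cycles = 150L, n_cells = 500L),
    gsea = list(n_perm = 500L, weight_p = 1, min_size = 5L)
  )
  cfg <- utils::modifyList(base, overrides)
  structure(cfg, class = "pipeline_config")
}

read_pipeline_config <- function(path) {
  pipeline_config(overrides = yaml::read_yaml(path))
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes simulate -> qc -> expression transform -> recovery -> marker
#' ranking -> signatures and module scores -> percentile classification
#' -> hurdle DE (+ bootstrap CIs) -> GSEA/ORA -> chromatin element
#' classification, differential binding and the boundary-upregulation
#' test, writing each stage's tables under `config$out_dir` and
#' returning a provenance record (config snapshot, package version,
#' per-file checksums, stage timings, warnings). Stages can be toggled
#' in `config$stages`; a stage whose inputs were toggled off aborts with
#' a diagnostic naming the missing dependency.
#'
#' @param config A [pipeline_config()], a partial override list, or a
#'   YAML file path.
#' @return List of class `run_provenance`; stage results are attached in
#'   `$results`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    config <- pipeline_config(overrides = config)
  }
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  res <- list()
  timings <- list()
  warns <- character()
  note <- function(w) warns <<- c(warns, w)
  stage <- function(name, enabled, fn) {
    if (!isTRUE(enabled)) return(invisible(NULL))
    t0 <- Sys.time()
    out <- withCallingHandlers(fn(), warning = function(w) {
      note(paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }
  need <- function(x, what, from) {
    if (is.null(x)) {
      rlang::abort(sprintf("missing %s: enable the '%s' stage", what, from))
    }
    x
  }
  tsv <- function(x, name) {
    readr::write_tsv(x, file.path(config$out_dir, name))
  }
  st <- config$stages

  res$population <- stage("simulate", st$simulate, function() {
    pop <- generate_cell_population(
      do.call(sim_config, c(list(seed = config$seed), config$sim)))
    res$landscape <<- generate_regulatory_landscape(
      do.call(landscape_config, c(list(seed = config$seed + 100L),
                                  config$landscape)))
    res$intensity <<- generate_intensity_table(seed = config$seed + 200L)
    write_fixtures(pop, res$landscape, res$intensity,
                   file.path(config$out_dir, "fixtures"))
    pop
  })

  res$counts <- stage("qc", st$qc, function() {
    pop <- need(res$population, "count matrix", "simulate")
    m <- compute_cell_qc(pop$counts)
    tsv(m, "cell_qc.tsv")
    filter_cells(pop$counts, m, profile = config$qc_profile)
  })

  res$recovered <- stage("recover", st$recover, function() {
    counts <- need(res$counts, "QC-filtered counts", "qc")
    ex <- transform_ex(counts)
    ex <- filter_genes(ex)
    ## the marker must survive gene filtering to anchor the ranking
    marker <- res$population$gene_meta$gene[res$population$gene_meta$is_marker]
    res$ex <<- ex
    recover_expression(counts[rownames(ex), , drop = FALSE],
                       n_components = config$recover$n_components,
                       ridge = config$recover$ridge)
  })

  res$ranking <- stage("rank", st$rank, function() {
    rec <- need(res$recovered, "recovered expression", "recover")
    marker <- res$population$gene_meta$gene[res$population$gene_meta$is_marker]
    rk <- rank_genes_by_marker(rec, marker)
    tsv(rk[c("gene", "r", "r_adj", "rank")], "marker_ranking.tsv")
    rk
  })

  res$scores <- stage("signatures", st$signatures, function() {
    rk <- need(res$ranking, "marker ranking", "rank")
    es <- scale_genes(res$recovered$lambda)
    res$es <<- es
    sig <- build_marker_signature(rk, config$signature$N)
    ex_means <- rowMeans(res$ex)
    ctrl <- match_control_genes(sig, ex_means,
                                n_bins = config$signature$n_bins,
                                n_ctrl = config$signature$n_ctrl,
                                seed = config$seed + 300L)
    sc <- score_modules(es, sig, ctrl)
    ## planted module signatures alongside the marker signature
    gm <- res$population$gene_meta
    planted <- split(gm$gene[!is.na(gm$module)], gm$module[!is.na(gm$module)])
    all_scores <- list(sc)
    for (m in names(planted)) {
      genes_in <- intersect(planted[[m]], rownames(es))
      if (length(genes_in) < 5) next
      ps <- gene_signature(genes_in, m)
      pc <- match_control_genes(ps, ex_means,
                                n_bins = config$signature$n_bins,
                                n_ctrl = config$signature$n_ctrl,
                                seed = config$seed + 301L)
      all_scores <- c(all_scores, list(score_modules(es, ps, pc)))
    }
    scores <- dplyr::bind_rows(all_scores)
    tsv(scores, "module_scores.tsv")
    res$signature <<- sig
    if (length(all_scores) >= 2) {
      res$sig_cor <<- correlate_signatures(all_scores)
    }
    scores
  })

  res$labels <- stage("classify", st$classify, function() {
    rec <- need(res$recovered, "recovered expression", "recover")
    marker <- res$population$gene_meta$gene[res$population$gene_meta$is_marker]
    lab <- classify_cells_by_value(
      setNames(rec$lambda[marker, ], colnames(rec$lambda)),
      upper_pct = config$classify$upper_pct,
      lower_pct = config$classify$lower_pct)
    tsv(lab, "cell_classes.tsv")
    lab
  })

  res$de <- stage("de", st$de, function() {
    lab <- need(res$labels, "cell class labels", "classify")
    meta <- res$population$cell_meta
    cov <- meta[match(lab$cell, meta$cell), c("cell", "donor", "tech")]
    fit <- fit_hurdle(res$ex, lab, covariates = cov,
                      use_cdr = config$de$use_cdr)
    de <- test_de(fit, preset = config$de$preset)
    tsv(de[setdiff(names(de), character())], "de_results.tsv")
    ## gene-level expression-change table for the chromatin side: the
    ## landscape carries planted per-gene changes
    if (!is.null(res$landscape)) {
      res$gene_de <<- res$landscape$gene_truth
    }
    de
  })

  res$bootstrap <- stage("bootstrap", st$bootstrap, function() {
    lab <- need(res$labels, "cell class labels", "classify")
    bs <- bootstrap_log2fc(res$ex, lab,
                           n_cycles = config$bootstrap$n_cycles,
                           n_cells = config$bootstrap$n_cells,
                           seed = config$seed + 400L)
    tsv(bs, "bootstrap_ci.tsv")
    bs
  })

  res$enrichment <- stage("enrichment", st$enrichment, function() {
    rk <- need(res$ranking, "marker ranking", "rank")
    gm <- res$population$gene_meta
    sets <- split(gm$gene[!is.na(gm$module)], gm$module[!is.na(gm$module)])
    gs <- gsea_preranked(setNames(rk$r_adj, rk$gene), sets,
                         weight_p = config$gsea$weight_p,
                         n_perm = config$gsea$n_perm,
                         seed = config$seed + 500L,
                         min_size = config$gsea$min_size)
    tsv(gs[setdiff(names(gs), "leading_edge")], "gsea_results.tsv")
    de <- res$de
    if (!is.null(de)) {
      up <- de$gene[de$significant & de$direction == "up"]
      if (length(up)) {
        ora <- ora_hypergeometric(up, sets, universe = de$gene)
        tsv(ora, "ora_results.tsv")
        res$ora <<- ora
      }
    }
    gs
  })

  res$chromatin <- stage("chromatin", st$chromatin, function() {
    land <- need(res$landscape, "regulatory landscape", "simulate")
    prom <- call_active_promoters(land$tss, land$peaks,
                                  chrom_sizes = land$chrom_sizes)
    enh <- call_enhancers(land$peaks$H3K27ac, land$peaks$H3K4me1,
                          dplyr::transmute(prom[prom$active, ],
                                           chrom, start = window_start,
                                           end = window_end))
    enh <- link_nearest_gene(enh, land$tss)
    db <- differential_region_test(land$region_counts, land$condition)
    cat_ <- categorize_ctcf_sites(land$ctcf_sites, prom, enh, land$tss,
                                  land$tad_boundaries)
    gene_de <- need(res$gene_de, "DE result", "de")
    bt <- boundary_upregulation_test(cat_, gene_de, binding = db)
    tsv(prom, "promoters.tsv")
    write_bed(enh[c("chrom", "start", "end", "name")],
              file.path(config$out_dir, "enhancers.bed"))
    tsv(db, "diffbind.tsv")
    tsv(dplyr::select(cat_, -dplyr::any_of("binding_class")) |>
          dplyr::mutate(category = as.character(category)),
        "ctcf_catalog.tsv")
    jsonlite::write_json(unclass(bt),
                         file.path(config$out_dir, "boundary_test.json"),
                         auto_unbox = TRUE, digits = NA)
    list(promoters = prom, enhancers = enh, diffbind = db, catalog = cat_,
         boundary = bt)
  })

  version <- as.character(utils::packageVersion("senoscore"))
  jsonlite::write_json(
    list(version = version, timings = timings, warnings = warns),
    file.path(config$out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA)
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  structure(list(
    config = config,
    version = version,
    timings = timings,
    files = tibble::tibble(file = sub(paste0("^", config$out_dir, "/?"), "",
                                      files),
                           md5 = unname(tools::md5sum(files))),
    warnings = warns,
    results = res
  ), class = "run_provenance")
}

#' @export
print.run_provenance <- function(x, ...) {
  cat("<run_provenance> senoscore ", x$version, "; ",
      length(x$timings), " stages, ", nrow(x$files), " files, ",
      length(x$warnings), " warnings\n", sep = "")
  invisible(x)
}
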