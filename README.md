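# senoscore

Marker-anchored senescence signature scoring and regulatory-element
analysis for single-cell expression and chromatin peak data.

## The problem

Senescent cells inside a tissue are rare, and the marker that defines
them — the CDK4/6 inhibitor p16 (*CDKN2A*) — is transcribed at levels so
low that droplet single-cell RNA-seq detects it in only ~15% of cells.
senoscore implements an analysis built around that constraint, for
anyone who needs to characterise a rare cell state anchored on a sparse
marker transcript:

* **Expression recovery.** A Gamma–Poisson empirical-Bayes model: with
  cell size factors *s<sub>c</sub>*, a low-rank prediction
  *μ<sub>gc</sub>* and per-gene NB dispersion *φ<sub>g</sub>*, the
  posterior mean is
  *λ̂ = (y + 1/φ) / (s<sub>c</sub> + 1/(φμ))*, a compromise between
  observation and prediction, with a per-gene reliability weight
  *w<sub>g</sub> = √(Var(λ̂)/(Var(λ̂) + posterior var))*.
* **Marker-anchored signatures.** Genes ranked by reliability-adjusted
  correlation *r·w<sub>g</sub>·w<sub>marker</sub>* to the marker; the
  top 100 (or 250, 500) form a signature scored per cell as
  *SC = mean(E<sub>s</sub>(G)) − mean(E<sub>s</sub>(C))* against an
  expression-matched control set, on z-scaled expression
  *E<sub>s</sub>* of *Ex = log2((CPM/10)+1)*.
* **Percentile classes and hurdle DE.** Cells above the 70th / below the
  30th percentile of marker expression (80/20 for image intensities)
  are compared with a two-part model — logistic detection + Gaussian
  expression given detection, with donor/tech covariates and the
  cellular detection rate — combined by likelihood-ratio test, BH
  correction, and 95% bootstrap CIs from 150 cycles of resampling 500
  cells per class.
* **Enrichment.** Weighted-KS preranked GSEA with gene-label
  permutation nulls, and upper-tail hypergeometric over-representation.
* **Chromatin rules.** Active promoters (H3K27ac ∧ ATAC ∧ H3K4me3
  within ±2 kb of a TSS), enhancers (H3K27ac ∩ H3K4me1 outside promoter
  windows), nearest-gene links, a simplified NB differential-binding
  test (median-of-ratios size factors, moderated method-of-moments
  dispersion, Wald), exact PWM motif thresholds by dynamic programming,
  CTCF site categorisation (promoter / enhancer–promoter intervening
  within 200 kb / TAD boundary / other), and a hypergeometric test for
  coupling between boundary CTCF loss and gene upregulation.
* **Synthetic data with planted truth** for every stage: an NB count
  matrix with a latent senescent state, low-capture marker and planted
  gene modules; a toy regulatory landscape with planted element classes
  and binding changes; per-cell intensity tables.

See `vignettes/senoscore-methods.Rmd` for the models, defaults and
design decisions.

## Worked example

```r
library(senoscore)

pop    <- generate_cell_population(sim_config(seed = 42, n_cells = 1500, n_genes = 1500))
counts <- filter_cells(pop$counts, profile = "tenx")
ex     <- filter_genes(transform_ex(counts))
rec    <- recover_expression(counts[rownames(ex), ])
rec
#> <recovered_expression> 1500 genes x 1500 cells; 20 components; median phi = 0.438

rk <- rank_genes_by_marker(rec, "CDKN2A")
head(rk, 3)
#>   gene      r r_adj constant  rank
#> 1 G0031 0.742 0.592 FALSE        1
#> 2 G0017 0.582 0.479 FALSE        2
#> 3 G0104 0.575 0.474 FALSE        3
```

The top-ranked genes are the planted senescence-coupled module: all 100
genes of the top-100 signature come from the 120-gene "maturation"
module the generator planted.

```r
sig    <- build_marker_signature(rk, 100)
ctrl   <- match_control_genes(sig, rowMeans(ex), n_ctrl = 30, seed = 1)
scores <- score_modules(scale_genes(rec$lambda), sig, ctrl)
labels <- classify_cells_by_value(setNames(rec$lambda["CDKN2A", ], colnames(rec$lambda)))
tapply(pop$cell_meta$senescent[match(labels$cell, pop$cell_meta$cell)],
       labels$class, mean)
#> high  mid  neg
#> 0.48 0.00 0.00
```

Marker-high cells (top 30% of recovered p16) are 48% truly senescent
against a 14% base rate, and every planted senescent cell that the
classifier sees lands in the `high` class — the recovered marker
separates the state far better than its 15% raw detection rate could.

```r
de <- test_de(fit_hurdle(ex, labels, covariates = pop$cell_meta[, c("cell", "donor", "tech")]))
bt <- bootstrap_log2fc(ex, labels, seed = 2)
head(dplyr::arrange(bt, dplyr::desc(log2FC)), 3)
#>   gene   log2FC ci_low ci_high n_cycles n_cells
#> 1 CDKN2A   3.92  3.54     4.27      150     500
#> 2 G0115    1.60  1.29     1.96      150     500
#> 3 G0128    1.32  0.961    1.64      150     500
```

The marker itself tops the fold-change table (log2FC 3.9, 95% bootstrap
CI [3.5, 4.3]) followed by planted module genes. `autoplot(de)`,
`autoplot(labels)` and `plot_bootstrap_ci(bt)` draw the standard
figures; `tidy()`/`glance()` methods give per-gene and one-row
summaries of fitted objects. `run_pipeline(pipeline_config(seed = 1))`
chains every stage, including the chromatin side, from one seeded
configuration and writes per-file checksums into a provenance record.

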