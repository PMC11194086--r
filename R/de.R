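## ridge-stabilised logistic regression via Newton/IRLS.
## The tiny penalty (default 1e-4) tames complete separation without
## noticeably biasing coefficients; deviance is reported unpenalised.
logistic_ridge <- function(X, y, lambda = 1e-4, maxit = 50, tol = 1e-8) {
  p <- ncol(X)
  pen <- diag(c(0, rep(2 * lambda, p - 1L)), p)
  beta <- numeric(p)
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    W <- mu * (1 - mu)
    H <- crossprod(X * W, X) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
    dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
    if (abs(dev_old - dev) < tol * (abs(dev) + 1)) { converged <- TRUE; break }
    dev_old <- dev
  }
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
  list(beta = beta,
       deviance = -2 * sum(y * log(mu) + (1 - y) * log(1 - mu)),
       converged = converged)
}

## Gaussian part: MLE deviance n*log(RSS/n); with require_col2 (the full
## model's class term) returns NULL when that coefficient is inestimable
gaussian_part <- function(X, y, require_col2 = TRUE) {
  if (nrow(X) < ncol(X) + 1L) return(NULL)
  fit <- lm.fit(X, y)
  if (require_col2 && any(is.na(fit$coefficients[2L]))) return(NULL)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  se <- NA_real_
  if (fit$df.residual > 0 && rss > 0) {
    XtXinv <- tryCatch(solve(crossprod(X)), error = function(e) NULL)
    if (!is.null(XtXinv)) {
      sigma2 <- rss / fit$df.residual
      ## column 2 is the class term by construction
      se <- sqrt(sigma2 * XtXinv[2L, 2L])
    }
  }
  list(coef = unname(fit$coefficients[2L]), se = se, rss = rss, n = n)
}

#' Fit two-part (hurdle) models per gene
#'
#' For each gene, a logistic model of the detection indicator
#' (`Ex > 0`) and a Gaussian linear model of Ex among detected cells,
#' each on class + covariates + the centred cellular detection rate
#' (CDR). The logistic part carries a small L2 penalty (default 1e-4) to
#' tame separation. Only cells labelled `high` or `neg` enter the fit.
#'
#' @param ex Gene-by-cell Ex matrix.
#' @param labels A [classify_cells_by_value()] result (or tibble with
#'   cell and class columns using levels high/mid/neg).
#' @param covariates Optional data frame of per-cell covariates (e.g.
#'   donor, tech), with a `cell` column or row order matching `ex`.
#' @param use_cdr Include the centred cellular detection rate (default
#'   TRUE, the two-part-model convention).
#' @param ridge L2 penalty on the logistic part.
#' @return Object of class `hurdle_fit`: per-gene tibble `genes` with
#'   detection/continuous coefficients, deviance drops and dfs, plus the
#'   class cell sets and call info.
#' @export
fit_hurdle <- function(ex, labels, covariates = NULL, use_cdr = TRUE,
                       ridge = 1e-4) {
  keep <- labels$class %in% c("high", "neg")
  assert_that(any(labels$class == "high") && any(labels$class == "neg"),
              "both classes must be nonempty")
  cells <- labels$cell[keep]
  assert_that(all(cells %in% colnames(ex)), "labelled cells missing from matrix")
  exs <- ex[, cells, drop = FALSE]
  z <- as.numeric(labels$class[keep] == "high")

  X <- cbind(`(Intercept)` = 1, class = z)
  if (!is.null(covariates)) {
    cov <- as.data.frame(covariates)
    if ("cell" %in% names(cov)) {
      cov <- cov[match(cells, cov$cell), setdiff(names(cov), "cell"), drop = FALSE]
    } else {
      assert_that(nrow(cov) == ncol(ex), "covariates must align to cells")
      cov <- cov[match(cells, colnames(ex)), , drop = FALSE]
    }
    mm <- stats::model.matrix(~ ., data = cov)[, -1, drop = FALSE]
    X <- cbind(X, mm)
  }
  if (use_cdr) {
    cdr <- colMeans(exs > 0)
    X <- cbind(X, cdr = cdr - mean(cdr))
  }
  Xr <- X[, -2L, drop = FALSE]  # reduced: drop the class column

  res <- purrr::map_dfr(seq_len(nrow(exs)), function(g) {
    y <- exs[g, ]
    det <- as.numeric(y > 0)
    n_det <- sum(det)
    if (n_det < 3) {
      return(tibble::tibble(
        gene = rownames(exs)[g], skipped = TRUE, converged = FALSE,
        coef_detection = NA_real_, coef_continuous = NA_real_,
        se_continuous = NA_real_, dev_drop_detection = NA_real_,
        df_detection = 0L, dev_drop_continuous = NA_real_,
        df_continuous = 0L, n_detected = n_det))
    }
    ## detection part: degenerate when all cells detect the gene
    if (n_det == length(det)) {
      dd <- NA_real_; dfd <- 0L; bd <- NA_real_; conv_d <- TRUE
    } else {
      f1 <- logistic_ridge(X, det, lambda = ridge)
      f0 <- logistic_ridge(Xr, det, lambda = ridge)
      dd <- max(f0$deviance - f1$deviance, 0)
      dfd <- 1L
      bd <- f1$beta[2L]
      conv_d <- f1$converged && f0$converged
    }
    ## continuous part on detected cells
    di <- det == 1
    g1 <- gaussian_part(X[di, , drop = FALSE], y[di])
    cc <- NA_real_; sec <- NA_real_; dc <- NA_real_; dfc <- 0L
    if (!is.null(g1)) {
      g0 <- gaussian_part(Xr[di, , drop = FALSE], y[di], require_col2 = FALSE)
      if (!is.null(g0) && g1$rss > 0) {
        dc <- g1$n * log(g0$rss / g1$rss)
        dfc <- 1L
        cc <- g1$coef; sec <- g1$se
      } else if (!is.null(g0) && g1$rss == 0) {
        dc <- NA_real_; dfc <- 0L; cc <- g1$coef
      }
    }
    tibble::tibble(
      gene = rownames(exs)[g], skipped = FALSE,
      converged = conv_d && (dfd > 0 || dfc > 0),
      coef_detection = if (dfd > 0) bd else NA_real_,
      coef_continuous = cc, se_continuous = sec,
      dev_drop_detection = dd, df_detection = dfd,
      dev_drop_continuous = dc, df_continuous = dfc,
      n_detected = n_det)
  })

  structure(list(
    genes = res,
    cells_high = cells[z == 1], cells_neg = cells[z == 0],
    use_cdr = use_cdr, ridge = ridge,
    ex_means_high = rowMeans(exs[, z == 1, drop = FALSE]),
    ex_means_neg = rowMeans(exs[, z == 0, drop = FALSE])
  ), class = "hurdle_fit")
}

#' Likelihood-ratio differential-expression test from a hurdle fit
#'
#' The LRT statistic is the sum of the per-part deviance drops for the
#' class term, with degrees of freedom equal to the number of
#' contributing parts (2 when both estimable, 1 when detection is
#' complete or the continuous part is inestimable); p from the
#' chi-square, BH-adjusted across tested genes. log2FC is the difference
#' of class means of Ex (high minus neg).
#'
#' @param fit A [fit_hurdle()] result.
#' @param padj_max,min_fc Significance thresholds (p_adj and linear fold
#'   change); the `significant` column applies both.
#' @param preset Optional named preset: `"scrna"` (p_adj < 0.05, no FC
#'   filter) or `"bulk"` (p_adj < 0.1, FC > 1.5).
#' @return Tibble of class `de_result`: gene, log2FC, lrt, df, p, p_adj,
#'   direction, significant (+ the fit columns).
#' @export
test_de <- function(fit, padj_max = 0.05, min_fc = 1,
                    preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("scrna", "bulk"))
    if (preset == "scrna") { padj_max <- 0.05; min_fc <- 1 }
    if (preset == "bulk") { padj_max <- 0.1; min_fc <- 1.5 }
  }
  g <- fit$genes
  lrt <- rowSums(cbind(g$dev_drop_detection, g$dev_drop_continuous), na.rm = TRUE)
  df <- g$df_detection + g$df_continuous
  testable <- !g$skipped & df > 0 & g$converged
  if (!any(testable)) rlang::abort("no testable genes")
  p <- rep(NA_real_, nrow(g))
  p[testable] <- pchisq(lrt[testable], df[testable], lower.tail = FALSE)
  p_adj <- rep(NA_real_, nrow(g))
  p_adj[testable] <- p.adjust(p[testable], "BH")
  log2fc <- unname(fit$ex_means_high - fit$ex_means_neg)
  out <- tibble::tibble(
    gene = g$gene, log2FC = log2fc, lrt = lrt, df = df, p = p, p_adj = p_adj,
    direction = ifelse(log2fc >= 0, "up", "down"),
    significant = !is.na(p_adj) & p_adj < padj_max &
      abs(log2fc) > log2(min_fc),
    tested = testable
  )
  attr(out, "thresholds") <- c(padj_max = padj_max, min_fc = min_fc)
  class(out) <- c("de_result", class(out))
  out
}

#' Bootstrap confidence intervals for per-gene log2 fold changes
#'
#' Repeats `n_cycles` cycles of sampling `n_cells` cells per class with
#' replacement, recomputing the per-gene log2FC (difference of class
#' means of Ex) each cycle, and reports the 2.5/97.5 percentile interval.
#' Defaults (150 cycles x 500 cells) reproduce the published resampling
#' recipe.
#'
#' @param ex Gene-by-cell Ex matrix.
#' @param labels Cell class labels (high/neg used).
#' @param n_cycles Number of resampling cycles.
#' @param n_cells Cells drawn per class per cycle (with replacement, so
#'   classes smaller than this are allowed).
#' @param seed RNG seed.
#' @return Tibble: gene, log2FC (point estimate on all labelled cells),
#'   ci_low, ci_high, n_cycles, n_cells.
#' @export
bootstrap_log2fc <- function(ex, labels, n_cycles = 150L, n_cells = 500L,
                             seed = 1L) {
  hi <- labels$cell[labels$class == "high"]
  lo <- labels$cell[labels$class == "neg"]
  assert_that(length(hi) > 0 && length(lo) > 0, "both classes must be nonempty")
  ex_hi <- ex[, hi, drop = FALSE]
  ex_lo <- ex[, lo, drop = FALSE]
  draws <- with_seed(seed, {
    vapply(seq_len(n_cycles), function(i) {
      ih <- sample.int(length(hi), n_cells, replace = TRUE)
      il <- sample.int(length(lo), n_cells, replace = TRUE)
      rowMeans(ex_hi[, ih, drop = FALSE]) - rowMeans(ex_lo[, il, drop = FALSE])
    }, numeric(nrow(ex)))
  })
  draws <- matrix(draws, nrow = nrow(ex))
  ci <- apply(draws, 1L, quantile, probs = c(0.025, 0.975), names = FALSE)
  tibble::tibble(
    gene = rownames(ex),
    log2FC = unname(rowMeans(ex_hi) - rowMeans(ex_lo)),
    ci_low = ci[1L, ], ci_high = ci[2L, ],
    n_cycles = as.integer(n_cycles), n_cells = as.integer(n_cells)
  )
}
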