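## shared generators for hurdle-model calibration tests

hurdle_labels <- function(n_high, n_neg) {
  tibble::tibble(
    cell = paste0("c", seq_len(n_high + n_neg)),
    class = factor(rep(c("high", "neg"), c(n_high, n_neg)),
                   levels = c("high", "mid", "neg")))
}

## two-part data on the model's own terms: Bernoulli detection and a
## Gaussian expression shift of `delta` among detected cells of the
## high class (first `n_alt` genes carry the shift)
sim_hurdle_ex <- function(n_genes, n_high, n_neg, delta = 0, n_alt = 0,
                          detect_p = 0.7, seed = 1) {
  withr::with_seed(seed, {
    n <- n_high + n_neg
    cls <- rep(c(1, 0), c(n_high, n_neg))
    ex <- matrix(0, n_genes, n,
                 dimnames = list(paste0("g", seq_len(n_genes)),
                                 paste0("c", seq_len(n))))
    for (g in seq_len(n_genes)) {
      d <- if (g <= n_alt || n_alt == 0 && delta != 0) delta else 0
      det <- rbinom(n, 1, detect_p)
      val <- 2 + rnorm(n, sd = 0.8) + d * cls
      ex[g, ] <- ifelse(det == 1, pmax(val, 0.1), 0)
    }
    ex
  })
}
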