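# Shared fixture builders: small panels/designs used across test files.

tiny_cell_types <- c("Epithelial", "Fibroblast", "CD4T", "Monocyte", "Bcell")

tiny_panel <- function(p = 300, seed = 42, ...) {
  synthesize_reference(p, tiny_cell_types, seed = seed, ...)
}

tiny_design <- function(p = 300, n = 60, snr = 11, n_diff_per_type = 20,
                        ...) {
  design_450k(p = p, n = n, snr = snr,
              n_diff_per_type = n_diff_per_type, ...)
}

tiny_sim <- function(seed = 7, p = 300, n = 60, snr = 11,
                     n_diff_per_type = min(20L, p %/% 10L),
                     panel_seed = 42) {
  panel <- tiny_panel(p = p, seed = panel_seed)
  design <- tiny_design(p = p, n = n, snr = snr,
                        n_diff_per_type = n_diff_per_type)
  simulate_mixture(design, panel, seed = seed)
}

# Independent brute-force oracles -------------------------------------------

# Pooled variance via explicit centred residuals.
oracle_pooled_var <- function(groups) {
  res <- unlist(lapply(groups, function(x) x - mean(x)))
  sum(res^2) / (length(res) - length(groups))
}

# AUROC by enumerating all positive-negative pairs (ties count 1/2).
oracle_auroc <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# BH step-up adjusted p-values by direct enumeration.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Bayesian-FDR rejection set by enumerating every prefix of the sorted list.
oracle_bayes_fdr <- function(posteriors, alpha) {
  q <- 1 - posteriors
  ord <- order(q)
  best <- 0L
  for (k in seq_along(q))
    if (mean(q[ord[seq_len(k)]]) <= alpha) best <- k
  reject <- logical(length(q))
  if (best > 0L) reject[ord[seq_len(best)]] <- TRUE
  reject
}
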