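#' Specify an in-silico mixture simulation design
#'
#' Bundles everything that defines one benchmarking scenario: the per-cell-type
#' uniform fraction distributions, the sample size and case-control balance,
#' the signal-to-noise ratio multiplying the pooled per-CpG standard deviation
#' into the planted effect size, and the layout of differential CpGs
#' (per-cell-type counts plus optional sets shared between two cell types).
#'
#' @param p number of CpG sites to simulate.
#' @param fraction_bounds K x 2 matrix (rows named by cell type) of uniform
#'   bounds `[lo_k, hi_k]` inside \[0, 1\] for the raw fraction draws.
#' @param n number of bulk samples.
#' @param snr signal-to-noise ratio; planted effect size is
#'   `snr * sqrt(pooled_var)` per CpG.
#' @param n_diff named vector of differential-CpG counts per cell type
#'   (cell types absent from it get 0).
#' @param shared optional list of shared-effect specifications, each a list
#'   with `pair` (two cell-type names) and `n` (count shared between them).
#' @param case_fraction proportion of case samples (default 0.5, a 1:1 ratio).
#' @param effect_sign `"+"` (hypermethylation in cases, default), `"-"`, or
#'   `"random"` (per-CpG random sign, for bidirectional scenarios).
#' @param clip_output clip mixtures into `[epsilon, 1 - epsilon]`? Default TRUE.
#' @param epsilon clipping threshold (default 1e-6).
#' @param n_replicates replicate count bundled with the design (default 50).
#' @return object of class `sim_design`.
#' @seealso [design_450k()], [design_epic()] for the bundled presets.
#' @export
sim_design <- function(p,
                       fraction_bounds,
                       n = 100L,
                       snr = 11,
                       n_diff = integer(),
                       shared = list(),
                       case_fraction = 0.5,
                       effect_sign = c("+", "-", "random"),
                       clip_output = TRUE,
                       epsilon = 1e-6,
                       n_replicates = 50L) {
  effect_sign <- match.arg(effect_sign)
  fraction_bounds <- as.matrix(fraction_bounds)
  if (ncol(fraction_bounds) != 2L || is.null(rownames(fraction_bounds)))
    stop("'fraction_bounds' must be a K x 2 matrix with cell-type rownames")
  if (any(fraction_bounds < 0) || any(fraction_bounds > 1) ||
      any(fraction_bounds[, 1] > fraction_bounds[, 2]))
    stop("fraction bounds must satisfy 0 <= lo_k <= hi_k <= 1")
  cell_types <- rownames(fraction_bounds)
  if (case_fraction <= 0 || case_fraction >= 1)
    stop("'case_fraction' must lie in (0, 1)")
  if (snr < 0) stop("'snr' must be non-negative")
  p <- as.integer(p)
  if (p < 1L) stop("'p' must be positive")

  counts <- stats::setNames(integer(length(cell_types)), cell_types)
  if (length(n_diff)) {
    if (is.null(names(n_diff)) || !all(names(n_diff) %in% cell_types))
      stop("'n_diff' must be named by cell types present in 'fraction_bounds'")
    counts[names(n_diff)] <- as.integer(n_diff)
  }
  if (any(counts < 0)) stop("differential counts must be non-negative")
  shared_total <- 0L
  for (s in shared) {
    if (!is.list(s) || length(s$pair) != 2L || !all(s$pair %in% cell_types))
      stop("each 'shared' entry needs a 'pair' of two known cell types")
    if (s$n > min(counts[s$pair]))
      stop("shared count exceeds a member cell type's differential count")
    shared_total <- shared_total + as.integer(s$n)
  }
  if (sum(counts) - shared_total > p)
    stop("total distinct differential CpGs exceeds 'p'")

  structure(list(
    p = p, fraction_bounds = fraction_bounds, cell_types = cell_types,
    n = as.integer(n), snr = snr, n_diff = counts, shared = shared,
    case_fraction = case_fraction, effect_sign = effect_sign,
    clip_output = isTRUE(clip_output), epsilon = epsilon,
    n_replicates = as.integer(n_replicates)
  ), class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat("Mixture simulation design\n")
  cat("  CpGs:", x$p, "  samples:", x$n,
      sprintf("(%.0f%% cases)", 100 * x$case_fraction),
      "  SNR:", x$snr, "\n")
  b <- x$fraction_bounds
  cat("  fractions:",
      paste(sprintf("%s~U(%g,%g)", rownames(b), b[, 1], b[, 2]),
            collapse = ", "), "\n")
  cat("  differential CpGs:",
      paste(sprintf("%s=%d", names(x$n_diff), x$n_diff), collapse = ", "),
      "\n")
  for (s in x$shared)
    cat("  shared:", s$n, "CpGs between", paste(s$pair, collapse = " and "),
        "\n")
  invisible(x)
}

#' Bundled 450k-style benchmarking design
#'
#' Five cell types with fractions Epithelial ~ U(0.3, 0.4), Fibroblast ~
#' U(0.35, 0.45), CD4T ~ U(0.1, 0.2), Monocyte ~ U(0, 0.1), Bcell ~ U(0, 0.1),
#' and non-overlapping differential sets of 500 CpGs each in epithelial, CD4T
#' and monocyte cells (fibroblasts and B-cells stay null).
#'
#' @param p CpG count (default 10000).
#' @param n sample count (default 100).
#' @param snr signal-to-noise ratio (default 11; the benchmark grid is
#'   7 to 15 in steps of 2).
#' @param n_diff_per_type differential CpGs per affected cell type
#'   (default 500).
#' @param ... passed to [sim_design()].
#' @return a `sim_design`.
#' @export
design_450k <- function(p = 10000L, n = 100L, snr = 11,
                        n_diff_per_type = 500L, ...) {
  bounds <- rbind(Epithelial = c(0.3, 0.4),
                  Fibroblast = c(0.35, 0.45),
                  CD4T       = c(0.1, 0.2),
                  Monocyte   = c(0.0, 0.1),
                  Bcell      = c(0.0, 0.1))
  sim_design(p = p, fraction_bounds = bounds, n = n, snr = snr,
             n_diff = c(Epithelial = n_diff_per_type,
                        CD4T = n_diff_per_type,
                        Monocyte = n_diff_per_type), ...)
}

#' Bundled EPIC-style benchmarking designs
#'
#' Six blood cell types with fractions Neutrophil ~ U(0.4, 0.6), CD4T ~
#' U(0.2, 0.3), CD8T ~ U(0.05, 0.15), Monocyte ~ U(0, 0.1), Bcell ~ U(0, 0.1),
#' NK ~ U(0, 0.1). Four effect layouts:
#' * `"1a"`: 1,000 differential CpGs each in neutrophils, CD4T, CD8T and
#'   monocytes (4,000 total);
#' * `"1b"`: as 1a but 500 CpGs shared between CD4T and CD8T (3,500 unique);
#' * `"2a"`: 1,000 each in CD4T, CD8T and monocytes only (3,000 total);
#' * `"2b"`: as 2a with 500 shared between CD4T and CD8T (2,500 unique).
#'
#' @param setting one of `"1a"`, `"1b"`, `"2a"`, `"2b"`.
#' @param p CpG count (default 20000).
#' @param n sample count (default 100).
#' @param snr signal-to-noise ratio (default 11).
#' @param ... passed to [sim_design()].
#' @return a `sim_design`.
#' @export
design_epic <- function(setting = c("1a", "1b", "2a", "2b"),
                        p = 20000L, n = 100L, snr = 11, ...) {
  setting <- match.arg(setting)
  bounds <- rbind(Neutrophil = c(0.40, 0.60),
                  CD4T       = c(0.20, 0.30),
                  CD8T       = c(0.05, 0.15),
                  Monocyte   = c(0.00, 0.10),
                  Bcell      = c(0.00, 0.10),
                  NK         = c(0.00, 0.10))
  n_diff <- switch(setting,
    "1a" = , "1b" = c(Neutrophil = 1000L, CD4T = 1000L, CD8T = 1000L,
                      Monocyte = 1000L),
    "2a" = , "2b" = c(CD4T = 1000L, CD8T = 1000L, Monocyte = 1000L))
  shared <- if (setting %in% c("1b", "2b"))
    list(list(pair = c("CD4T", "CD8T"), n = 500L)) else list()
  sim_design(p = p, fraction_bounds = bounds, n = n, snr = snr,
             n_diff = n_diff, shared = shared, ...)
}
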