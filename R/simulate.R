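#' Draw cell-type fractions
#'
#' Draws each cell type's raw fraction uniformly within its design interval
#' and renormalizes every sample's row to sum to 1, preserving the intended
#' relative abundances.
#'
#' @param design a [sim_design()].
#' @param n number of samples (defaults to `design$n`).
#' @param seed integer seed or `NULL`.
#' @return n x K matrix of fractions; rows sum to 1; attribute `"raw"` holds
#'   the unnormalized uniform draws.
#' @export
draw_fractions <- function(design, n = design$n, seed = NULL) {
  b <- design$fraction_bounds
  K <- nrow(b)
  with_seed(seed, {
    raw <- vapply(seq_len(K),
                  function(k) stats::runif(n, b[k, 1], b[k, 2]),
                  numeric(n))
    raw <- matrix(raw, nrow = n, ncol = K,
                  dimnames = list(NULL, rownames(b)))
    f <- raw / rowSums(raw)
    attr(f, "raw") <- raw
    f
  })
}

#' Plant the cell-type-specific effect layout
#'
#' Chooses which CpGs carry a case-control effect in which cell type. Counts
#' per cell type are exact; non-shared sets are disjoint across cell types;
#' shared sets (e.g. CpGs differential in both CD4T and CD8T) are placed in
#' both members. Effect sizes are `snr * sqrt(pooled_var)` per CpG, with a
#' per-CpG sign shared across cell types.
#'
#' @param design a [sim_design()].
#' @param pooled_sd length-p vector of pooled per-CpG SDs.
#' @param seed integer seed or `NULL`.
#' @return object of class `effect_map`: list with `truth` (p x K logical),
#'   `effect_size` (length p, `snr * pooled_sd`), `sign` (length p in
#'   \{-1, +1\}).
#' @export
assign_effects <- function(design, pooled_sd, seed = NULL) {
  p <- design$p
  if (length(pooled_sd) != p)
    stop("'pooled_sd' must have length ", p)
  cts <- design$cell_types
  counts <- design$n_diff
  with_seed(seed, {
    truth <- matrix(FALSE, p, length(cts), dimnames = list(NULL, cts))
    remaining <- counts
    shared_total <- sum(vapply(design$shared, function(s) s$n, numeric(1)))
    n_unique <- sum(counts) - shared_total
    pool <- sample.int(p, n_unique)
    used <- 0L
    take <- function(m) {
      idx <- pool[used + seq_len(m)]
      used <<- used + m
      idx
    }
    for (s in design$shared) {
      idx <- take(s$n)
      truth[idx, s$pair] <- TRUE
      remaining[s$pair] <- remaining[s$pair] - s$n
    }
    for (ct in cts) if (remaining[ct] > 0L)
      truth[take(remaining[ct]), ct] <- TRUE

    sgn <- switch(design$effect_sign,
                  "+" = rep(1, p),
                  "-" = rep(-1, p),
                  "random" = sample(c(-1, 1), p, replace = TRUE))
    structure(list(truth = truth,
                   effect_size = effect_size(design$snr, pooled_sd),
                   sign = sgn),
              class = "effect_map")
  })
}

#' Planted effect size from signal-to-noise ratio
#'
#' The per-CpG effect size is `s_c = snr * sigma_c`, the signal-to-noise
#' ratio times the pooled per-CpG standard deviation.
#'
#' @param snr non-negative scalar.
#' @param pooled_sd positive vector of pooled SDs.
#' @return vector `snr * pooled_sd`.
#' @export
effect_size <- function(snr, pooled_sd) {
  if (length(snr) != 1L || snr < 0) stop("'snr' must be a non-negative scalar")
  if (any(pooled_sd <= 0)) stop("'pooled_sd' must be positive")
  snr * pooled_sd
}

#' Simulate per-cell-type methylation profiles
#'
#' Each sample's profile in cell type k at CpG c is Gaussian with mean
#' `mu_ck` (controls, and cases at null positions) or `mu_ck + sign_c * s_c`
#' (cases at planted positions), and common pooled variance `sigma_c^2`.
#'
#' @param panel a [synthesize_reference()] panel.
#' @param effects an `effect_map` from [assign_effects()].
#' @param phenotype binary 0/1 vector of length n (1 = case).
#' @param seed integer seed or `NULL`.
#' @return p x K x n array of beta-scale profiles (unclipped).
#' @export
simulate_cell_profiles <- function(panel, effects, phenotype, seed = NULL) {
  p <- nrow(panel$mu); K <- ncol(panel$mu); n <- length(phenotype)
  if (!all(phenotype %in% c(0, 1))) stop("'phenotype' must be binary 0/1")
  if (!identical(dim(effects$truth), dim(panel$mu)))
    stop("effect map and panel dimensions disagree")
  sd_c <- sqrt(panel$pooled_var)
  delta <- effects$truth * (effects$sign * effects$effect_size)  # p x K
  with_seed(seed, {
    # rnorm recycles the length-p sd vector down the first dimension
    prof <- array(stats::rnorm(p * K * n, mean = 0, sd = sd_c),
                  dim = c(p, K, n),
                  dimnames = list(panel$cpg_ids, panel$cell_types, NULL))
    prof <- prof + c(panel$mu)                # broadcast p x K over samples
    case_idx <- which(phenotype == 1)
    for (i in case_idx) prof[, , i] <- prof[, , i] + delta
    prof
  })
}

#' Mix cell profiles into bulk beta values
#'
#' Forms the convex combination `X_c = sum_k X_ck * f_k` per sample, the
#' bulk-tissue signal implied by the cell composition, optionally clipping
#' into `[epsilon, 1 - epsilon]` for beta-value validity.
#'
#' @param profiles p x K x n array from [simulate_cell_profiles()].
#' @param fractions n x K matrix; rows must sum to 1 within `1e-9`.
#' @param clip clip the mixture into the valid beta band?
#' @param epsilon clipping threshold.
#' @return p x n bulk matrix.
#' @export
mix_profiles <- function(profiles, fractions, clip = TRUE, epsilon = 1e-6) {
  d <- dim(profiles)
  if (length(d) != 3L) stop("'profiles' must be a p x K x n array")
  if (nrow(fractions) != d[3] || ncol(fractions) != d[2])
    stop("'fractions' must be n x K matching the profile array")
  check_fraction_rows(fractions)
  p <- d[1]; K <- d[2]; n <- d[3]
  bulk <- matrix(0, p, n, dimnames = list(dimnames(profiles)[[1]], NULL))
  for (k in seq_len(K))
    bulk <- bulk + profiles[, k, , drop = TRUE] *
      rep(fractions[, k], each = p)
  if (clip) bulk <- pmin(pmax(bulk, epsilon), 1 - epsilon)
  bulk
}

#' Simulate a bulk-mixture benchmarking dataset
#'
#' Composes the full generative pipeline: draw cell-type fractions, plant the
#' differential-CpG layout, simulate case/control per-cell-type Gaussian
#' profiles around the reference means with pooled variance, and mix them
#' into bulk beta values. The phenotype has `round(case_fraction * n)` cases.
#' Component seeds are derived deterministically from `seed`, so the same
#' `(design, panel, seed)` triple reproduces the dataset bitwise; replicate
#' r of a benchmark uses `seed + r`.
#'
#' @param design a [sim_design()].
#' @param panel a [synthesize_reference()] panel with `design$p` CpGs and the
#'   design's cell types.
#' @param seed integer seed or `NULL`.
#' @return object of class `ctsdm_sim`: list with `bulk` (p x n), `phenotype`
#'   (0/1 length n), `fractions` (n x K), `effects` (`effect_map`), `design`,
#'   `panel_seed`, `seed`.
#' @examples
#' panel <- synthesize_reference(300, c("Epithelial", "Fibroblast", "CD4T",
#'                                      "Monocyte", "Bcell"), seed = 1)
#' sim <- simulate_mixture(design_450k(p = 300, n_diff_per_type = 20),
#'                         panel, seed = 1)
#' sim
#' @export
simulate_mixture <- function(design, panel, seed = NULL) {
  if (!inherits(design, "sim_design")) stop("'design' must be a sim_design")
  if (!inherits(panel, "reference_panel"))
    stop("'panel' must be a reference_panel")
  if (nrow(panel$mu) != design$p)
    stop("panel has ", nrow(panel$mu), " CpGs but the design expects ",
         design$p)
  if (!identical(panel$cell_types, design$cell_types))
    stop("panel and design cell types disagree")
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 3L))
  n <- design$n
  n_case <- round(design$case_fraction * n)
  phenotype <- rep(c(1L, 0L), c(n_case, n - n_case))
  fractions <- draw_fractions(design, n, seed = sub[1])
  effects <- assign_effects(design, sqrt(panel$pooled_var), seed = sub[2])
  profiles <- simulate_cell_profiles(panel, effects, phenotype,
                                     seed = sub[3])
  bulk <- mix_profiles(profiles, fractions, clip = design$clip_output,
                       epsilon = design$epsilon)
  colnames(bulk) <- sprintf("S%03d", seq_len(n))
  rownames(fractions) <- colnames(bulk)
  structure(list(bulk = bulk, phenotype = phenotype, fractions = fractions,
                 effects = effects, design = design,
                 panel_seed = panel$seed, seed = seed),
            class = "ctsdm_sim")
}

#' @export
print.ctsdm_sim <- function(x, ...) {
  cat("In-silico bulk methylation mixture\n")
  cat("  CpGs:", nrow(x$bulk), "  samples:", ncol(x$bulk),
      sprintf("(%d cases / %d controls)",
              sum(x$phenotype == 1), sum(x$phenotype == 0)), "\n")
  cat("  SNR:", x$design$snr, "  differential CpGs per cell type:",
      paste(sprintf("%s=%d", colnames(x$effects$truth),
                    colSums(x$effects$truth)), collapse = ", "), "\n")
  invisible(x)
}
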