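#' Synthesize a purified-cell reference panel
#'
#' Generates a per-CpG, per-cell-type reference of beta-value means and
#' variances emulating a pool of purified-cell methylation samples. Each CpG
#' receives a true mean \eqn{\mu_{ck}} drawn uniformly within `mean_hyper`
#' (independently per cell type) and a per-CpG standard deviation drawn
#' uniformly within `sd_hyper` and shared across cell types, reflecting the
#' common-variance structure that a homogeneity-of-variance check on purified
#' blood cells supports. Pure-cell replicates are then simulated around those
#' parameters, and the panel stores the empirical per-cell-type variances
#' together with a pooled variance across the designated pooling cell types.
#'
#' @param p number of CpG sites.
#' @param cell_types character vector of cell-type labels.
#' @param mean_hyper length-2 interval inside (0, 1) for the true means.
#' @param sd_hyper length-2 interval inside (0, 0.5) for the per-CpG SD.
#' @param pure_samples_per_type number of simulated pure replicates per cell
#'   type (single value or one per cell type); at least 2.
#' @param pooling_types cell types entering the pooled variance; defaults to
#'   all of them.
#' @param seed integer seed; the same seed reproduces the panel bitwise.
#' @return An object of class `reference_panel`: a list with `cpg_ids`,
#'   `cell_types`, `mu` (p x K), `var` (p x K empirical), `pooled_var`
#'   (length p), `sd_true`, `n_pure`, and the hyperparameters.
#' @examples
#' panel <- synthesize_reference(100, c("Epi", "CD4T", "Mono"), seed = 1)
#' range(panel$mu)
#' @export
synthesize_reference <- function(p,
                                 cell_types,
                                 mean_hyper = c(0.1, 0.9),
                                 sd_hyper = c(0.01, 0.05),
                                 pure_samples_per_type = 20L,
                                 pooling_types = cell_types,
                                 seed = NULL) {
  if (!is.numeric(p) || length(p) != 1L || p < 1)
    stop("'p' must be a positive CpG count")
  p <- as.integer(p)
  if (length(cell_types) < 1L || anyDuplicated(cell_types))
    stop("'cell_types' must be a non-empty vector of unique labels")
  cell_types <- as.character(cell_types)
  K <- length(cell_types)
  if (length(mean_hyper) != 2L || mean_hyper[1] > mean_hyper[2] ||
      mean_hyper[1] <= 0 || mean_hyper[2] >= 1)
    stop("'mean_hyper' must be an interval inside (0, 1)")
  if (length(sd_hyper) != 2L || sd_hyper[1] > sd_hyper[2] ||
      sd_hyper[1] <= 0 || sd_hyper[2] >= 0.5)
    stop("'sd_hyper' must be an interval inside (0, 0.5)")
  n_pure <- rep_len(as.integer(pure_samples_per_type), K)
  if (any(n_pure < 2L))
    stop("'pure_samples_per_type' must be at least 2")
  if (!all(pooling_types %in% cell_types))
    stop("'pooling_types' must be a subset of 'cell_types'")

  with_seed(seed, {
    mu <- matrix(runif(p * K, mean_hyper[1], mean_hyper[2]), p, K,
                 dimnames = list(NULL, cell_types))
    sd_true <- runif(p, sd_hyper[1], sd_hyper[2])
    var_emp <- matrix(NA_real_, p, K, dimnames = list(NULL, cell_types))
    for (k in seq_len(K)) {
      reps <- mu[, k] + matrix(rnorm(p * n_pure[k], sd = sd_true), p, n_pure[k])
      var_emp[, k] <- row_vars(reps)
    }
    pool_idx <- match(pooling_types, cell_types)
    w <- n_pure[pool_idx] - 1L
    pooled <- as.vector(var_emp[, pool_idx, drop = FALSE] %*% w) / sum(w)

    cpg_ids <- sprintf("cg%06d", seq_len(p))
    rownames(mu) <- rownames(var_emp) <- cpg_ids
    structure(list(
      cpg_ids = cpg_ids, cell_types = cell_types,
      mu = mu, var = var_emp, pooled_var = pooled,
      sd_true = sd_true, n_pure = stats::setNames(n_pure, cell_types),
      pooling_types = as.character(pooling_types),
      mean_hyper = mean_hyper, sd_hyper = sd_hyper, seed = seed
    ), class = "reference_panel")
  })
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("Synthetic purified-cell reference panel\n")
  cat("  CpGs:       ", length(x$cpg_ids), "\n")
  cat("  cell types: ", paste(x$cell_types, collapse = ", "), "\n")
  cat("  pure replicates per type: ",
      paste(x$n_pure, collapse = ", "), "\n")
  cat("  pooled SD range: ",
      paste(signif(range(sqrt(x$pooled_var)), 3), collapse = " - "), "\n")
  invisible(x)
}

#' Clip beta values away from 0 and 1
#'
#' Replaces values below `epsilon` with `epsilon` and above `1 - epsilon`
#' with `1 - epsilon`, the usual numerical-stability step before logit-like
#' transforms of methylation beta values. Idempotent; interior values pass
#' through unchanged.
#'
#' @param values numeric vector/matrix of beta values in \[0, 1\].
#' @param epsilon clipping threshold in (0, 0.5); default `1e-6`.
#' @return object of the same shape with all entries in `[epsilon, 1 - epsilon]`.
#' @export
clip_beta <- function(values, epsilon = 1e-6) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon <= 0 || epsilon >= 0.5)
    stop("'epsilon' must lie in (0, 0.5)")
  if (any(values < 0 | values > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  values[values < epsilon] <- epsilon
  values[values > 1 - epsilon] <- 1 - epsilon
  values
}

#' Detection-p masking and call-rate filtering
#'
#' Applies the standard array QC sequence: entries whose detection p-value
#' exceeds `detection_threshold` are set missing; samples (columns) with a
#' call rate below `sample_rate` are removed first; then probes (rows) with a
#' call rate below `probe_rate` among the surviving samples are removed.
#'
#' @param values CpG x sample beta matrix (may contain `NA`).
#' @param detection_p matrix of detection p-values, same shape, or `NULL` to
#'   skip masking.
#' @param detection_threshold probes with detection p above this are treated
#'   as missing (default `1e-16`).
#' @param sample_rate minimum sample call rate (default 0.95).
#' @param probe_rate minimum probe call rate (default 0.90).
#' @return list with `values` (filtered matrix), `kept_samples`,
#'   `kept_probes` (integer indices into the input).
#' @export
apply_call_rate_filters <- function(values,
                                    detection_p = NULL,
                                    detection_threshold = 1e-16,
                                    sample_rate = 0.95,
                                    probe_rate = 0.90) {
  values <- as.matrix(values)
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    if (!identical(dim(values), dim(detection_p)))
      stop("'values' and 'detection_p' must have identical dimensions")
    values[detection_p > detection_threshold] <- NA_real_
  }
  if (sample_rate <= 0 || sample_rate > 1 || probe_rate <= 0 || probe_rate > 1)
    stop("call-rate thresholds must lie in (0, 1]")

  sample_cr <- colMeans(!is.na(values))
  kept_samples <- which(sample_cr >= sample_rate)
  values <- values[, kept_samples, drop = FALSE]
  probe_cr <- rowMeans(!is.na(values))
  kept_probes <- which(probe_cr >= probe_rate)
  values <- values[kept_probes, , drop = FALSE]
  list(values = values, kept_samples = kept_samples, kept_probes = kept_probes)
}

#' Pooled variance across groups
#'
#' Sample-size-weighted average of within-group variances,
#' \eqn{\sum_g (n_g - 1) s_g^2 / \sum_g (n_g - 1)}; the classical pooled
#' variance used when a common variance across purified cell types is
#' justified.
#'
#' @param group_values list of numeric vectors, one per group, each with at
#'   least 2 observations.
#' @return pooled variance (scalar).
#' @export
pooled_variance <- function(group_values) {
  if (!is.list(group_values) || length(group_values) < 2L)
    stop("need at least 2 groups")
  n <- vapply(group_values, length, integer(1))
  if (any(n < 2L)) stop("every group needs at least 2 observations")
  s2 <- vapply(group_values, stats::var, numeric(1))
  sum((n - 1) * s2) / sum(n - 1)
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA F test on absolute deviations from each group's centre
#' (mean for classical Levene, median for the Brown-Forsythe variant), with
#' `(K - 1, N - K)` degrees of freedom. Used to decide whether a common
#' per-CpG variance across cell types is defensible.
#'
#' @param group_values list of numeric vectors, one per group.
#' @param centering `"mean"` (default) or `"median"`.
#' @return list with `statistic`, `p_value`, `df` (length 2).
#' @export
levene_common_variance_test <- function(group_values,
                                        centering = c("mean", "median")) {
  centering <- match.arg(centering)
  if (!is.list(group_values) || length(group_values) < 2L)
    stop("need at least 2 groups")
  n <- vapply(group_values, length, integer(1))
  if (any(n < 2L)) stop("every group needs at least 2 observations")
  centre <- if (centering == "mean") mean else stats::median
  dev <- lapply(group_values, function(x) abs(x - centre(x)))
  z <- unlist(dev, use.names = FALSE)
  g <- factor(rep(seq_along(dev), times = n))
  K <- nlevels(g); N <- length(z)
  gm <- mean(z)
  means <- tapply(z, g, mean)
  ss_between <- sum(n * (means - gm)^2)
  ss_within <- sum((z - means[g])^2)
  if (ss_within == 0) {
    if (all(z == 0))
      stop("degenerate input: all deviations are zero in every group; ",
           "Levene statistic undefined")
    if (ss_between == 0)
      return(list(statistic = 0, p_value = 1, df = c(K - 1, N - K)))
    return(list(statistic = Inf, p_value = 0, df = c(K - 1, N - K)))
  }
  stat <- (ss_between / (K - 1)) / (ss_within / (N - K))
  list(statistic = stat,
       p_value = stats::pf(stat, K - 1, N - K, lower.tail = FALSE),
       df = c(K - 1, N - K))
}
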