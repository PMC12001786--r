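#' Confusion-matrix performance metrics
#'
#' Computes the benchmarking metric suite from calls against planted truth:
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), empirical FDR
#' FP/(TP+FP) (0 when nothing is rejected), false omission rate FN/(FN+TN)
#' (0 when everything is rejected), and F1 = 2TP/(2TP+FP+FN) (0 when the
#' denominator is 0).
#'
#' @param calls logical vector of rejections.
#' @param truth logical vector of planted differential status, same length.
#' @return list with the five metrics plus raw counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(calls, truth) {
  if (length(calls) != length(truth)) stop("'calls' and 'truth' lengths differ")
  calls <- as.logical(calls); truth <- as.logical(truth)
  tp <- sum(calls & truth); fp <- sum(calls & !truth)
  fn <- sum(!calls & truth); tn <- sum(!calls & !truth)
  list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    empirical_fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
    for_rate = if (fn + tn > 0) fn / (fn + tn) else 0,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0,
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' Rank-based AUROC
#'
#' Mann-Whitney AUROC of scores against binary truth, ties counted one half:
#' the probability that a random truly-differential CpG outscores a random
#' null one.
#'
#' @param scores numeric vector; larger = more significant (use `1 - p` for
#'   p-value methods, the posterior itself for posterior methods).
#' @param truth logical vector, same length; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, truth) {
  if (length(scores) != length(truth))
    stop("'scores' and 'truth' lengths differ")
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: truth must contain both classes")
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical type-I error on null tests
#'
#' Proportion of unadjusted p-values below `alpha` among tests known to be
#' null (e.g. cell types with no planted effects).
#'
#' @param p_values numeric vector of null-test p-values.
#' @param alpha nominal level in (0, 1).
#' @return rejection proportion.
#' @export
type1_error <- function(p_values, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  if (length(p_values) == 0L) stop("empty p-value vector")
  mean(p_values < alpha)
}

#' Replicated simulation benchmark of detection methods
#'
#' For each design and replicate: synthesize (or reuse) a reference panel,
#' simulate a bulk mixture, run every method, call CpGs at the BH-adjusted
#' `alpha` within each cell type, and record the full metric suite per cell
#' type. Replicate r uses seed `seed + r`. A method is a function
#' `function(sim)` returning a p x K matrix of p-values (the built-in
#' `"interaction"` method wraps [ctsdm()] with the true fractions).
#'
#' @param designs a `sim_design` or list of them.
#' @param methods named list of method functions, or the default built-in.
#' @param alpha nominal FDR level for calls (default 0.05).
#' @param n_replicates replicates per design (default from each design).
#' @param seed base seed; replicate r of design d uses
#'   `seed + (d - 1) * n_replicates + r`.
#' @param panel_args list of arguments forwarded to
#'   [synthesize_reference()] (e.g. `mean_hyper`, `sd_hyper`); one panel is
#'   synthesized per replicate with the replicate seed.
#' @return data.frame, one row per design x replicate x method x cell type,
#'   with columns `design`, `replicate`, `snr`, `n`, `method`, `cell_type`,
#'   `affected`, the confusion metrics, `auroc`, `type1_error`, and raw
#'   counts. Metrics that are undefined for a cell type (e.g. sensitivity
#'   where nothing was planted) are `NA`.
#' @examples
#' \donttest{
#' res <- run_benchmark(design_450k(p = 500, n_diff_per_type = 25,
#'                                  n_replicates = 2), seed = 1)
#' aggregate(sensitivity ~ cell_type, res, mean)
#' }
#' @export
run_benchmark <- function(designs,
                          methods = list(interaction = method_interaction()),
                          alpha = 0.05,
                          n_replicates = NULL,
                          seed = 1L,
                          panel_args = list()) {
  if (inherits(designs, "sim_design")) designs <- list(designs)
  if (!length(designs) || !length(methods))
    stop("need at least one design and one method")
  if (is.null(names(methods)))
    names(methods) <- paste0("method", seq_along(methods))
  rows <- list()
  for (d in seq_along(designs)) {
    design <- designs[[d]]
    reps <- n_replicates %||% design$n_replicates
    for (r in seq_len(reps)) {
      rep_seed <- seed + (d - 1L) * reps + r
      panel <- do.call(synthesize_reference,
                       c(list(p = design$p, cell_types = design$cell_types,
                              seed = rep_seed), panel_args))
      sim <- simulate_mixture(design, panel, seed = rep_seed)
      truth <- sim$effects$truth
      for (m in names(methods)) {
        pmat <- methods[[m]](sim)
        padj <- apply(pmat, 2, stats::p.adjust, method = "BH")
        for (ct in design$cell_types) {
          tr <- truth[, ct]
          calls <- padj[, ct] < alpha
          cm <- confusion_metrics(calls, tr)
          au <- if (any(tr) && !all(tr)) auroc(1 - pmat[, ct], tr)
                else NA_real_
          t1 <- if (!any(tr)) type1_error(pmat[, ct], alpha) else NA_real_
          rows[[length(rows) + 1L]] <- data.frame(
            design = d, replicate = r, snr = design$snr, n = design$n,
            method = m, cell_type = ct, affected = any(tr),
            sensitivity = cm$sensitivity, specificity = cm$specificity,
            empirical_fdr = cm$empirical_fdr, for_rate = cm$for_rate,
            f1 = cm$f1, auroc = au, type1_error = t1,
            tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Built-in interaction-model detection method for [run_benchmark()]
#'
#' @param adjust passed to [ctsdm()].
#' @param fraction_noise if positive, the true fractions are perturbed with
#'   [perturb_fractions()] before fitting, emulating estimated proportions.
#' @return a function `function(sim)` returning the p x K p-value matrix.
#' @export
method_interaction <- function(adjust = "within", fraction_noise = 0) {
  function(sim) {
    fr <- if (fraction_noise > 0)
      perturb_fractions(sim$fractions, fraction_noise,
                        seed = (sim$seed %||% 0L) + 10000L)
    else sim$fractions
    ctsdm(sim$bulk, sim$phenotype, fr, adjust = adjust)$p_values
  }
}

#' Pooled empirical FDR across affected cell types
#'
#' Pools TP/FP counts over the cell types with planted effects within each
#' replicate (summing counts, not averaging ratios) and returns
#' FP/(FP+TP) per design x replicate x method, 0 where nothing was rejected.
#'
#' @param bench result of [run_benchmark()].
#' @return data.frame with columns `design`, `replicate`, `method`,
#'   `empirical_fdr`.
#' @export
pooled_fdr <- function(bench) {
  aff <- bench[bench$affected, , drop = FALSE]
  agg <- stats::aggregate(cbind(tp, fp) ~ design + replicate + method,
                          data = aff, FUN = sum)
  agg$empirical_fdr <- ifelse(agg$tp + agg$fp > 0,
                              agg$fp / (agg$tp + agg$fp), 0)
  agg[, c("design", "replicate", "method", "empirical_fdr")]
}

#' Per-setting summary of a benchmark table
#'
#' Means and medians of each metric over replicates, per design x method x
#' cell type.
#'
#' @param bench result of [run_benchmark()].
#' @return data.frame of summaries.
#' @export
summarize_benchmark <- function(bench) {
  metrics <- c("sensitivity", "specificity", "empirical_fdr", "for_rate",
               "f1", "auroc", "type1_error")
  key <- interaction(bench$design, bench$method, bench$cell_type, drop = TRUE)
  out <- lapply(split(bench, key), function(g) {
    row <- g[1, c("design", "snr", "n", "method", "cell_type", "affected")]
    for (m in metrics) {
      row[[paste0("mean_", m)]] <- mean(g[[m]], na.rm = TRUE)
      row[[paste0("median_", m)]] <- stats::median(g[[m]], na.rm = TRUE)
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
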