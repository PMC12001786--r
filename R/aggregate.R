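#' Assemble a p-value cube from multiple detection methods
#'
#' Stacks per-method CpG x cell-type tables into a single p x K x m array.
#' Methods reporting posterior probabilities of differential methylation are
#' converted entrywise to `1 - posterior` so every slice is on the p-value
#' scale. Entries may violate \[0, 1\] by at most `1e-12` (floating-point
#' slack) and are clipped back; larger violations are an error.
#'
#' @param tables list of p x K numeric matrices, one per method.
#' @param source_kinds character vector, `"p-value"` or `"posterior"` per
#'   method.
#' @param method_labels unique labels, one per method.
#' @return object of class `pvalue_cube`: p x K x m array with
#'   `method_labels` dimnames on the third margin and attribute
#'   `source_kinds`.
#' @export
assemble_cube <- function(tables, source_kinds, method_labels) {
  m <- length(tables)
  if (m == 0L) stop("'tables' must be non-empty")
  if (length(source_kinds) != m || length(method_labels) != m)
    stop("'source_kinds' and 'method_labels' must match length(tables)")
  if (anyDuplicated(method_labels)) stop("'method_labels' must be unique")
  if (!all(source_kinds %in% c("p-value", "posterior")))
    stop("'source_kinds' entries must be \"p-value\" or \"posterior\"")
  first <- as.matrix(tables[[1]])
  d <- dim(first)
  dn <- dimnames(first) %||% list(NULL, NULL)
  cube <- array(NA_real_, c(d[1], d[2], m),
                dimnames = list(dn[[1]], dn[[2]], method_labels))
  tol <- 1e-12
  for (i in seq_len(m)) {
    tab <- as.matrix(tables[[i]])
    if (!identical(dim(tab), d))
      stop("table '", method_labels[i], "' is not conformable")
    assert_prob_matrix(tab, paste0("entries of '", method_labels[i], "'"),
                       tol = tol)
    if (source_kinds[i] == "posterior") tab <- 1 - tab
    cube[, , i] <- pmin(pmax(tab, 0), 1)
  }
  structure(cube, source_kinds = stats::setNames(source_kinds, method_labels),
            class = c("pvalue_cube", class(cube)))
}

resolve_subset <- function(cube, subset) {
  labels <- dimnames(cube)[[3]]
  if (is.null(subset)) subset <- labels
  if (length(subset) == 0L) stop("method subset must be non-empty")
  unknown <- setdiff(subset, labels)
  if (length(unknown))
    stop("unknown method label(s): ", paste(unknown, collapse = ", "))
  subset
}

#' Probit-average ensemble p-value (avepv)
#'
#' Combines the m methods' p-values at each (CpG, cell type) as
#' \deqn{\mathrm{avepv}_{ck} = \Phi\left(\frac{1}{m}\sum_{i=1}^m
#'   \Phi^{-1}(p_{cki})\right),}
#' the normal-CDF map of the mean probit-transformed p-value (an unweighted
#' Stouffer-style average). Boundary p-values are clipped to
#' `[1e-15, 1 - 1e-15]` before the probit so the result stays finite and
#' monotone. Calibrated under independence of the component p-values.
#'
#' @param cube a [assemble_cube()] p-value cube.
#' @param subset method labels to combine (default: all).
#' @return p x K matrix of ensemble p-values.
#' @export
avepv <- function(cube, subset = NULL) {
  subset <- resolve_subset(cube, subset)
  sl <- cube[, , subset, drop = FALSE]
  eps <- 1e-15
  z <- stats::qnorm(pmin(pmax(sl, eps), 1 - eps))
  out <- stats::pnorm(apply(z, c(1, 2), mean))
  dimnames(out) <- dimnames(cube)[1:2]
  out
}

#' Beta-transformed minimum ensemble p-value (minpv)
#'
#' Combines the m methods' p-values at each (CpG, cell type) as
#' \deqn{\mathrm{minpv}_{ck} = F_{\mathrm{Beta}(1,m)}\left(\min_i
#'   p_{cki}\right) = 1 - (1 - \min_i p_{cki})^m,}
#' the CDF of the minimum of m independent uniforms evaluated at the observed
#' minimum, so the result is itself uniform under independent null p-values.
#' With a single method this is the identity map.
#'
#' @inheritParams avepv
#' @return p x K matrix of ensemble p-values.
#' @export
minpv <- function(cube, subset = NULL) {
  subset <- resolve_subset(cube, subset)
  sl <- cube[, , subset, drop = FALSE]
  m <- length(subset)
  mn <- apply(sl, c(1, 2), min)
  out <- stats::pbeta(mn, 1, m)
  dimnames(out) <- dimnames(cube)[1:2]
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted p-values (monotone, capped at 1), as used to call
#' CpGs at a nominal FDR level.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  assert_prob_matrix(p)
  stats::p.adjust(p, method = "BH")
}

#' Newton-style Bayesian FDR thresholding of posterior probabilities
#'
#' For posterior probabilities of differential methylation, defines
#' `q_j = 1 - posterior_j`, sorts ascending and rejects the largest prefix
#' whose running mean of q stays at or below `alpha` — the direct
#' posterior-expected-FDR rule used to put posterior-based methods on the
#' same FDR footing as p-value methods. Ties (including posteriors exactly
#' 1, q = 0) keep their original order within the sort, so certain calls are
#' rejected before any uncertain ones.
#'
#' @param posteriors vector of posterior probabilities in \[0, 1\].
#' @param alpha target FDR level in (0, 1).
#' @return list with `reject` (logical, original order), `fdr_path` (running
#'   mean of sorted q), `n_reject`.
#' @export
bayesian_fdr_threshold <- function(posteriors, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  assert_prob_matrix(posteriors, "posterior probabilities")
  q <- 1 - posteriors
  ord <- order(q)                      # stable: original order breaks ties
  path <- cumsum(q[ord]) / seq_along(q)
  k <- if (any(path <= alpha)) max(which(path <= alpha)) else 0L
  reject <- logical(length(q))
  if (k > 0L) reject[ord[seq_len(k)]] <- TRUE
  list(reject = reject, fdr_path = path, n_reject = k)
}
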