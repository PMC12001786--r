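#' Fit the cell-type interaction model for differential methylation
#'
#' The central fitting function. For every CpG c it fits, by ordinary least
#' squares, the no-intercept linear model
#' \deqn{X_c = \sum_k \beta_{ck} f_k + \sum_k \gamma_{ck} f_k y + Z\alpha_c +
#'   \varepsilon_c,}
#' where `f_k` are the pre-estimated cell-type fractions, `y` is the binary
#' phenotype and `Z` optional additive covariates. With fractions summing to
#' 1 an intercept would be collinear with the fraction block, so the design
#' uses all K fraction columns and all K phenotype-by-fraction interaction
#' columns; the interaction coefficient \eqn{\gamma_{ck}} is the
#' cell-type-specific case-control methylation difference in cell type k.
#' Each \eqn{\gamma_{ck}} is tested against zero with a two-sided t test on
#' `n - 2K - q` residual degrees of freedom, and p-values are
#' Benjamini-Hochberg adjusted within each cell type (or globally).
#'
#' The design matrix is shared across CpGs, so a single QR decomposition
#' serves all p regressions.
#'
#' @param bulk p x n matrix of bulk beta values (CpGs in rows).
#' @param phenotype binary 0/1 vector of length n (1 = case).
#' @param fractions n x K matrix of cell-type fractions; rows must sum to 1
#'   within `1e-9` and columns must be named.
#' @param covariates optional n x q numeric matrix of additive covariates.
#' @param adjust `"within"` (BH within each cell type, default) or
#'   `"global"` (BH across all p x K tests at once).
#' @return object of class `ctsdm` with components `estimates`, `std_errors`,
#'   `statistics`, `p_values`, `adjusted_p` (all p x K, cell types in
#'   columns), `coefficients` (full (2K+q) x p matrix), `df`, `sigma2`,
#'   `qr`, `xtx_inv`, and the inputs' dimensions. Supports `print()`,
#'   `summary()`, `coef()`, `fitted()` and `residuals()`.
#' @examples
#' panel <- synthesize_reference(200, c("Epithelial", "Fibroblast", "CD4T",
#'                                      "Monocyte", "Bcell"), seed = 2)
#' sim <- simulate_mixture(design_450k(p = 200, n_diff_per_type = 15),
#'                         panel, seed = 2)
#' fit <- ctsdm(sim$bulk, sim$phenotype, sim$fractions)
#' summary(fit)
#' @export
ctsdm <- function(bulk, phenotype, fractions, covariates = NULL,
                  adjust = c("within", "global")) {
  adjust <- match.arg(adjust)
  bulk <- as.matrix(bulk)
  fractions <- as.matrix(fractions)
  n <- ncol(bulk)
  if (length(phenotype) != n)
    stop("'phenotype' length must equal ncol(bulk)")
  if (!all(phenotype %in% c(0, 1)))
    stop("'phenotype' must be coded 0/1 with cases = 1")
  if (nrow(fractions) != n)
    stop("'fractions' must have one row per sample")
  if (is.null(colnames(fractions)))
    colnames(fractions) <- paste0("CT", seq_len(ncol(fractions)))
  check_fraction_rows(fractions)
  K <- ncol(fractions)
  cts <- colnames(fractions)

  X <- cbind(fractions, fractions * phenotype)
  colnames(X) <- c(cts, paste0(cts, ":pheno"))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      stop("'covariates' must have one row per sample")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  q <- ncol(X) - 2L * K
  if (n <= ncol(X))
    stop("need n > 2K + q samples (n = ", n, ", columns = ", ncol(X), ")")

  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; offending column(s): ",
         paste(dropped, collapse = ", "))
  }
  coefs <- qr.coef(qx, t(bulk))                    # (2K+q) x p
  res <- t(bulk) - X %*% coefs                     # n x p
  df <- n - ncol(X)
  sigma2 <- colSums(res^2) / df                    # length p
  xtx_inv <- chol2inv(chol(crossprod(X)))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))

  gamma_idx <- K + seq_len(K)
  est <- t(coefs[gamma_idx, , drop = FALSE])       # p x K
  se <- sqrt(outer(sigma2, diag(xtx_inv)[gamma_idx]))
  tstat <- est / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  colnames(est) <- colnames(se) <- colnames(tstat) <- colnames(pval) <- cts
  rownames(est) <- rownames(se) <- rownames(tstat) <- rownames(pval) <-
    rownames(bulk)

  padj <- if (adjust == "within") apply(pval, 2, stats::p.adjust,
                                        method = "BH")
          else matrix(stats::p.adjust(pval, method = "BH"),
                      nrow(pval), K, dimnames = dimnames(pval))

  structure(list(
    estimates = est, std_errors = se, statistics = tstat,
    p_values = pval, adjusted_p = padj,
    coefficients = coefs, df = df, sigma2 = sigma2,
    xtx_inv = xtx_inv, design_matrix = X, residual_matrix = t(res),
    cell_types = cts, n = n, p = nrow(bulk), q = q, adjust = adjust,
    call = match.call()
  ), class = "ctsdm")
}

#' @export
print.ctsdm <- function(x, ...) {
  cat("Cell-type interaction model fit\n")
  cat("  CpGs:", x$p, "  samples:", x$n, "  cell types:",
      paste(x$cell_types, collapse = ", "), "\n")
  cat("  residual df:", x$df, "  covariates:", x$q, "\n")
  invisible(x)
}

#' @export
summary.ctsdm <- function(object, alpha = 0.05, ...) {
  hits <- colSums(object$adjusted_p < alpha)
  out <- list(fit = object, alpha = alpha, n_significant = hits)
  class(out) <- "summary.ctsdm"
  out
}

#' @export
print.summary.ctsdm <- function(x, ...) {
  print(x$fit)
  cat("  significant CpGs (BH <", x$alpha, "per cell type):\n")
  print(x$n_significant)
  invisible(x)
}

#' Extract cell-type-specific effect estimates
#'
#' @param object a `ctsdm` fit.
#' @param which `"interaction"` (default) returns the p x K matrix of
#'   cell-type-specific case-control effect estimates; `"all"` the full
#'   p x (2K+q) coefficient matrix.
#' @param ... unused.
#' @export
coef.ctsdm <- function(object, which = c("interaction", "all"), ...) {
  which <- match.arg(which)
  if (which == "interaction") object$estimates else t(object$coefficients)
}

#' @export
fitted.ctsdm <- function(object, ...) {
  t(object$design_matrix %*% object$coefficients)
}

#' @export
residuals.ctsdm <- function(object, ...) {
  object$residual_matrix
}

#' Tidy long-format results table
#'
#' @param x a `ctsdm` fit.
#' @param ... unused.
#' @return data.frame with columns `CpG`, `cell_type`, `estimate`, `se`,
#'   `t`, `p`, `p_adj`.
#' @export
as.data.frame.ctsdm <- function(x, ...) {
  cpg <- rownames(x$p_values) %||% sprintf("cg%06d", seq_len(x$p))
  data.frame(
    CpG = rep(cpg, times = length(x$cell_types)),
    cell_type = rep(x$cell_types, each = x$p),
    estimate = c(x$estimates), se = c(x$std_errors),
    t = c(x$statistics), p = c(x$p_values), p_adj = c(x$adjusted_p),
    stringsAsFactors = FALSE
  )
}

#' General linear contrast test on a cell-type interaction fit
#'
#' Tests the single linear combination `c' beta = 0` per CpG with an F test
#' on (1, df) degrees of freedom, the device used to compare coefficients
#' across cell types or conditions. For a unit contrast selecting one
#' interaction coefficient the F statistic equals the squared t statistic and
#' the p-value matches the two-sided t test exactly.
#'
#' @param fit a `ctsdm` fit.
#' @param contrast numeric vector of length `2K + q`, in the order of
#'   `colnames(fit$design_matrix)` (K fraction columns, K interaction
#'   columns, covariates). Must be non-zero.
#' @return data.frame with columns `estimate`, `statistic` (F), `p_value`,
#'   one row per CpG.
#' @export
ctsdm_contrast <- function(fit, contrast) {
  if (!inherits(fit, "ctsdm")) stop("'fit' must be a ctsdm fit")
  k <- ncol(fit$design_matrix)
  if (length(contrast) != k)
    stop("'contrast' must have length ", k)
  if (all(contrast == 0)) stop("'contrast' must be non-zero")
  est <- as.vector(crossprod(contrast, fit$coefficients))   # length p
  cvc <- as.numeric(t(contrast) %*% fit$xtx_inv %*% contrast)
  Fstat <- est^2 / (fit$sigma2 * cvc)
  data.frame(
    estimate = est, statistic = Fstat,
    p_value = stats::pf(Fstat, 1, fit$df, lower.tail = FALSE),
    row.names = rownames(fit$p_values)
  )
}

#' Perturb cell-type fractions
#'
#' Adds bounded uniform noise to a fraction matrix and renormalizes rows to
#' the simplex, for studying how fraction-estimation error propagates into
#' cell-type-specific detection.
#'
#' @param fractions n x K matrix with rows summing to 1.
#' @param noise_scale half-width of the uniform noise; 0 returns the input
#'   unchanged.
#' @param seed integer seed or `NULL`.
#' @return perturbed n x K matrix, rows non-negative and summing to 1.
#' @export
perturb_fractions <- function(fractions, noise_scale, seed = NULL) {
  if (noise_scale < 0) stop("'noise_scale' must be non-negative")
  if (noise_scale == 0) return(fractions)
  with_seed(seed, {
    noise <- matrix(stats::runif(length(fractions), -noise_scale,
                                 noise_scale),
                    nrow(fractions), ncol(fractions))
    f <- pmax(fractions + noise, 0)
    # guard against all-zero rows at extreme noise
    zero <- rowSums(f) == 0
    f[zero, ] <- fractions[zero, ]
    f / rowSums(f)
  })
}
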