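# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so library code never clobbers user seeds.
# seed = NULL uses (and advances) the current RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Row variances of a numeric matrix, denominator n - 1.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 columns to compute row variances")
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

assert_prob_matrix <- function(p, what = "p-values", tol = 0) {
  if (any(!is.finite(p))) stop(what, " contain non-finite entries")
  if (any(p < -tol) || any(p > 1 + tol))
    stop(what, " must lie in [0, 1]")
  invisible(p)
}

check_fraction_rows <- function(fractions, tol = 1e-9) {
  s <- rowSums(fractions)
  bad <- which(abs(s - 1) > tol)
  if (length(bad))
    stop("fraction rows must sum to 1 (tolerance ", format(tol),
         "); first offending row: ", bad[1L])
  invisible(fractions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
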