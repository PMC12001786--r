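test_that("fraction draws respect design intervals and the simplex", {
  # K = 1 with degenerate bounds: all fractions exactly 1
  d1 <- sim_design(p = 10, fraction_bounds = rbind(A = c(1, 1)), n = 5)
  expect_equal(unname(draw_fractions(d1, seed = 1)),
               matrix(1, 5, 1), ignore_attr = TRUE)

  # 450k design: raw draws inside their intervals, rows sum to 1
  d <- tiny_design(n = 200)
  f <- draw_fractions(d, seed = 2)
  raw <- attr(f, "raw")
  b <- d$fraction_bounds
  for (k in seq_len(nrow(b))) {
    expect_true(all(raw[, k] >= b[k, 1] & raw[, k] <= b[k, 2]))
  }
  expect_equal(rowSums(f), rep(1, 200))
  expect_identical(f, draw_fractions(d, seed = 2))

  # Monte-Carlo mean of the epithelial fraction ~ 0.35 / sum of midpoints
  f_big <- draw_fractions(d, n = 10000, seed = 3)
  expect_equal(mean(attr(f_big, "raw")[, "Epithelial"]), 0.35,
               tolerance = 0.01)
  expect_equal(mean(f_big[, "Epithelial"]), 0.35, tolerance = 0.02)
})

test_that("effect layouts have exact counts, disjoint unless shared", {
  pooled_sd <- rep(0.03, 10000)

  # 450k default: 500 each in epithelial, CD4T, monocytes; disjoint rows
  d <- design_450k(p = 10000)
  em <- assign_effects(d, pooled_sd, seed = 4)
  expect_equal(unname(colSums(em$truth)), c(500L, 0L, 500L, 500L, 0L))
  expect_true(all(rowSums(em$truth) <= 1))
  expect_equal(sum(em$truth), 1500L)
  expect_equal(em$effect_size, 11 * pooled_sd)

  # EPIC setting 1b: 1,000 per affected type, 500 shared CD4T/CD8T,
  # 3,500 unique differential CpGs
  d1b <- design_epic("1b", p = 20000)
  em1b <- assign_effects(d1b, rep(0.03, 20000), seed = 5)
  expect_equal(unname(colSums(em1b$truth)),
               c(1000L, 1000L, 1000L, 1000L, 0L, 0L))
  expect_equal(sum(rowSums(em1b$truth) > 0), 3500L)
  expect_equal(sum(em1b$truth[, "CD4T"] & em1b$truth[, "CD8T"]), 500L)
  # shared CpGs are differential in exactly those two cell types
  shared_rows <- which(rowSums(em1b$truth) == 2)
  expect_true(all(em1b$truth[shared_rows, "CD4T"] &
                    em1b$truth[shared_rows, "CD8T"]))

  # counts are seed-independent, membership is not
  em2 <- assign_effects(d, pooled_sd, seed = 99)
  expect_equal(colSums(em2$truth), colSums(em$truth))
  expect_false(identical(em2$truth, em$truth))

  # zero counts everywhere
  d0 <- sim_design(p = 100, fraction_bounds = rbind(A = c(0.4, 0.6),
                                                    B = c(0.4, 0.6)))
  em0 <- assign_effects(d0, rep(0.03, 100), seed = 1)
  expect_false(any(em0$truth))

  # guard rails
  expect_error(sim_design(p = 100, fraction_bounds = rbind(A = c(0, 1)),
                          n_diff = c(A = 200L)), "exceeds 'p'")
  expect_error(sim_design(p = 100,
                          fraction_bounds = rbind(A = c(0, 1), B = c(0, 1)),
                          n_diff = c(A = 3L, B = 10L),
                          shared = list(list(pair = c("A", "B"), n = 5L))),
               "shared count exceeds")
})

test_that("effect size is SNR times pooled SD", {
  expect_equal(effect_size(10, 0.02), 0.2)
  expect_equal(effect_size(7, 0.05), 0.35)
  expect_equal(effect_size(0, c(0.01, 0.05)), c(0, 0))
  expect_error(effect_size(-1, 0.02), "non-negative")
  expect_error(effect_size(10, c(0.02, 0)), "positive")
})

test_that("cell profiles are Gaussian around the reference with planted shifts", {
  # near-zero variance: a planted case value equals mu + s exactly
  pan <- synthesize_reference(5, c("A", "B"), mean_hyper = c(0.4, 0.4),
                              sd_hyper = c(0.02, 0.02), seed = 1)
  pan$pooled_var[] <- 1e-24
  truth <- matrix(FALSE, 5, 2, dimnames = list(NULL, c("A", "B")))
  truth[2, 1] <- TRUE
  em <- structure(list(truth = truth, effect_size = rep(0.2, 5),
                       sign = rep(1, 5)), class = "effect_map")
  prof <- simulate_cell_profiles(pan, em, phenotype = c(1, 0), seed = 2)
  expect_equal(prof[2, 1, 1], pan$mu[2, 1] + 0.2, tolerance = 1e-9)
  expect_equal(prof[2, 1, 2], pan$mu[2, 1], tolerance = 1e-9)
  expect_equal(prof[2, 2, 1], pan$mu[2, 2], tolerance = 1e-9)

  # determinism
  expect_identical(prof, simulate_cell_profiles(pan, em, c(1, 0), seed = 2))

  # control-only sample means converge to mu
  pan2 <- tiny_panel(p = 50)
  em2 <- assign_effects(tiny_design(p = 50, n_diff_per_type = 5),
                        sqrt(pan2$pooled_var), seed = 3)
  prof2 <- simulate_cell_profiles(pan2, em2, rep(0, 2000), seed = 4)
  emp_mean <- apply(prof2, c(1, 2), mean)
  expect_lt(max(abs(emp_mean - pan2$mu)), 4.5 * sqrt(max(pan2$pooled_var) / 2000))
})

test_that("mixing is the fraction-weighted convex combination", {
  # K = 1, f = 1: identity
  prof <- array(runif(20), c(10, 1, 2))
  f <- matrix(1, 2, 1)
  expect_equal(mix_profiles(prof, f, clip = FALSE),
               prof[, 1, ], ignore_attr = TRUE)

  # equal profiles: convexity returns the constant
  prof2 <- array(0.37, c(4, 3, 2))
  f2 <- matrix(1 / 3, 2, 3)
  expect_equal(unname(mix_profiles(prof2, f2, clip = FALSE)),
               matrix(0.37, 4, 2))

  # two-component arithmetic: 0.25 * 0.2 + 0.75 * 0.8 = 0.65
  prof3 <- array(c(0.2, 0.8), c(1, 2, 1))
  f3 <- matrix(c(0.25, 0.75), 1, 2)
  expect_equal(unname(mix_profiles(prof3, f3, clip = FALSE)[1, 1]), 0.65)

  # fraction rows must sum to 1
  expect_error(mix_profiles(prof3, matrix(c(0.25, 0.70), 1, 2)), "sum to 1")
  expect_error(mix_profiles(prof3, matrix(0.5, 2, 2)), "n x K")
})

test_that("simulated datasets honour the design and are reproducible", {
  sim <- tiny_sim(seed = 10, n = 100)
  expect_equal(sum(sim$phenotype == 1), 50)
  expect_equal(sum(sim$phenotype == 0), 50)
  expect_true(all(sim$bulk >= 1e-6 & sim$bulk <= 1 - 1e-6))
  expect_equal(rowSums(sim$fractions), rep(1, 100), ignore_attr = TRUE)
  expect_identical(sim$bulk, tiny_sim(seed = 10, n = 100)$bulk)
  expect_false(identical(sim$bulk, tiny_sim(seed = 11, n = 100)$bulk))
})

test_that("case-control mixture gap at planted CpGs matches s_c * E[f_k]", {
  panel <- tiny_panel(p = 200, seed = 3)
  design <- tiny_design(p = 200, n = 2000, n_diff_per_type = 30)
  sim <- simulate_mixture(design, panel, seed = 12)
  gap <- rowMeans(sim$bulk[, sim$phenotype == 1]) -
    rowMeans(sim$bulk[, sim$phenotype == 0])
  for (ct in c("Epithelial", "CD4T")) {
    planted <- which(sim$effects$truth[, ct] & rowSums(sim$effects$truth) == 1)
    expected <- sim$effects$effect_size[planted] * mean(sim$fractions[, ct])
    expect_equal(mean(gap[planted] / expected), 1, tolerance = 0.1)
  }
  null_rows <- rowSums(sim$effects$truth) == 0
  expect_lt(mean(abs(gap[null_rows])), 0.005)
})

test_that("under SNR = 0 planted CpGs behave like nulls", {
  panel <- tiny_panel(p = 400, seed = 5)
  # equalize means across cell types so that random case/control composition
  # imbalance cannot shift the bulk mean: the naive two-sample t-test is
  # only calibrated when the mixture mean is composition-free, and this
  # check targets the absence of planted signal, not composition effects
  panel$mu <- matrix(panel$mu[, 1], nrow(panel$mu), ncol(panel$mu),
                     dimnames = dimnames(panel$mu))
  design <- tiny_design(p = 400, n = 80, snr = 0, n_diff_per_type = 40)
  pv <- unlist(lapply(1:5, function(r) {
    sim <- simulate_mixture(design, panel, seed = 100 + r)
    planted <- which(rowSums(sim$effects$truth) > 0)
    vapply(planted, function(c)
      t.test(sim$bulk[c, sim$phenotype == 1],
             sim$bulk[c, sim$phenotype == 0])$p.value, numeric(1))
  }))
  expect_gt(ks.test(pv, "punif")$p.value, 1e-3)
})

test_that("the mixture mean gap grows with SNR", {
  panel <- tiny_panel(p = 300, seed = 6)
  gaps <- vapply(c(7, 11, 15), function(snr) {
    design <- tiny_design(p = 300, n = 200, snr = snr, n_diff_per_type = 30)
    g <- vapply(1:3, function(r) {
      sim <- simulate_mixture(design, panel, seed = 200 + r)
      gap <- rowMeans(sim$bulk[, sim$phenotype == 1]) -
        rowMeans(sim$bulk[, sim$phenotype == 0])
      mean(gap[rowSums(sim$effects$truth) > 0])
    }, numeric(1))
    mean(g)
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})
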