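---
title: "Benchmarking cell-type-specific differential methylation detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking cell-type-specific differential methylation detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctsdm)
```

## The problem

DNA methylation assayed in bulk tissue is a mixture signal: at CpG site $c$,
the measured beta value of sample $i$ is the fraction-weighted sum of the
cell-type-specific methylation levels,

$$X_{c}(i) = \sum_{k=1}^{K} X_{ck}(i)\, f_{ik},$$

where $f_{ik}$ is the proportion of cell type $k$ in sample $i$. A
case-control methylation difference confined to one cell type is therefore
diluted by the factor $f_k$, and naive site-level tests on the bulk signal
confound true cell-type-specific effects with composition differences.
`ctsdm` provides the machinery to study how well cell-type-specific
differences can be recovered from bulk data: a generative simulator with
known planted truth, a native detector, ensemble p-value statistics for
combining several detectors, and a replicated evaluation harness.

## The generative model

### Reference panel

`synthesize_reference()` builds a panel emulating a pool of purified-cell
methylation samples. Each CpG receives a true mean $\mu_{ck}$ drawn
uniformly inside `mean_hyper` (default $(0.1, 0.9)$, covering the
informative range of beta values away from the boundaries) independently per
cell type, and a per-CpG standard deviation drawn uniformly inside
`sd_hyper` (default $(0.01, 0.05)$, the magnitude of within-cell-type
replicate variation seen on methylation arrays). The SD is shared across
cell types: on purified blood-cell data a homogeneity-of-variance check
(Levene's test, available as `levene_common_variance_test()`) supports a
common per-CpG variance, and the panel mirrors that structure. Pure-cell
replicates (default 20 per cell type) are then simulated and the panel
stores their empirical per-cell-type variances $\hat\sigma^2_{ck}$ together
with the pooled variance

$$\hat\sigma^2_c = \frac{\sum_k (n_k - 1)\,\hat\sigma^2_{ck}}
                        {\sum_k (n_k - 1)}.$$

Because the generator gives every cell type the same true SD, the choice of
which cell types enter the pooling (`pooling_types`, default all) is
immaterial here; the argument exists so that panels built from real purified
pools, where low-replicate cell types are better excluded, can restrict the
pooling set.

The panel module also carries the standard preprocessing steps used on real
purified pools — `clip_beta()` (replace 0 and 1 by $\varepsilon = 10^{-6}$
and $1-\varepsilon$), and `apply_call_rate_filters()` (detection-p masking
at $10^{-16}$, then sample call rate $\ge$ 95%, then probe call rate $\ge$
90%, in that order) — so that a real reference matrix can be funnelled into
the same downstream machinery. The simulator itself never produces
missingness; imputation is intentionally out of scope.

### Fractions, effects, mixtures

`draw_fractions()` draws each cell type's raw fraction uniformly inside its
design interval and renormalizes rows to the simplex. The bundled `"450k"`
design uses Epithelial $\sim U(0.3, 0.4)$, Fibroblast $\sim U(0.35, 0.45)$,
CD4T $\sim U(0.1, 0.2)$, Monocyte $\sim U(0, 0.1)$, B-cell $\sim U(0,
0.1)$; the EPIC designs use Neutrophil $\sim U(0.4, 0.6)$, CD4T $\sim
U(0.2, 0.3)$, CD8T $\sim U(0.05, 0.15)$ and $U(0, 0.1)$ for monocytes,
B-cells and NK cells. The interval means sum to 1 by construction;
individual draws do not, and renormalization preserves the intended
relative abundances while keeping every sample exactly on the simplex.

`assign_effects()` plants the differential layout: exact per-cell-type
counts (500 per affected type in the 450k design; 1,000 in the EPIC
settings, with an optional 500-CpG set shared between CD4T and CD8T),
disjoint across cell types unless a shared set is requested. A shared CpG
receives the same effect size and the same sign in both members — the
effect size and sign are per-CpG quantities — which represents a common
regulatory change visible in two related lymphocyte subsets.

The planted effect size is tied to the noise level through the
signal-to-noise ratio:

$$s_c = \mathrm{SNR} \cdot \sigma_c,$$

with $\sigma_c$ the pooled per-CpG SD. The benchmark grid runs SNR from 7
to 15 in steps of 2; at $\sigma_c \in (0.01, 0.05)$ and SNR 11 this gives
absolute cell-type-level effects of roughly 0.11–0.55 beta units, diluted
by $f_k$ in the bulk. Case profiles at planted positions are
$N(\mu_{ck} + s_c, \sigma^2_c)$; all other profiles are
$N(\mu_{ck}, \sigma^2_c)$. The default effect direction is
hypermethylation in cases; `effect_sign = "random"` produces bidirectional
changes.

`mix_profiles()` forms the convex combination and, by default, clips the
mixture into $[\varepsilon, 1-\varepsilon]$ so outputs are valid beta
values; Gaussian draws can leave $[0, 1]$ near the boundaries, and
`clip_output = FALSE` reproduces the literal Gaussian model when exact
linearity matters (for instance in the parameter-recovery checks, the
default clipping binds so rarely at the default hyperparameters that
recovery is unaffected). Phenotypes are balanced 1:1 by default
(`case_fraction = 0.5`).

### Reproducibility

Every stochastic function takes an explicit `seed` and restores the
caller's RNG state afterwards. `simulate_mixture()` derives its component
seeds (fractions, effect layout, profiles) deterministically from its own
seed, so a `(design, panel, seed)` triple is bitwise reproducible;
replicate $r$ of a benchmark uses `seed + r`, making each replicate
independently re-runnable.

## The detector

`ctsdm()` fits, per CpG, the no-intercept OLS model

$$X_c = \sum_k \beta_{ck} f_k + \sum_k \gamma_{ck}\, f_k y + Z\alpha_c +
\varepsilon_c,$$

with $y$ the 0/1 phenotype and $Z$ optional additive covariates (age, sex,
smoking status in typical EWAS adjustments; covariate-by-fraction
interactions are deliberately not included). Because the fractions sum
to 1, an intercept would be collinear with the fraction block, so the
design keeps all $K$ fraction columns and all $K$ interaction columns and
$\gamma_{ck}$ is directly the case-control methylation difference within
cell type $k$. Each $\gamma_{ck}$ gets a two-sided t test on
$n - 2K - q$ degrees of freedom with classical OLS standard errors (the
model is Gaussian by construction here, so no sandwich correction), and BH
adjustment is applied within each cell type (a global mode is available;
the within-cell-type default treats each cell type as its own testing
family, which matches how per-cell-type calls are reported downstream).
The design matrix is shared across CpGs, so one QR factorization serves
all $p$ regressions and fitting 2,000 CpGs takes milliseconds.

`ctsdm_contrast()` tests any linear combination $c'\beta = 0$ with an
F(1, df) test; for a unit contrast selecting one $\gamma_k$ the F statistic
is exactly the squared t statistic, so the two formulations of the
per-cell-type test coincide to machine precision — the same identity that
makes interaction-model detectors and contrast-based linear-model detectors
select identical CpG sets.

```{r example}
panel <- synthesize_reference(500, c("Epithelial", "Fibroblast", "CD4T",
                                     "Monocyte", "Bcell"), seed = 1)
design <- design_450k(p = 500, n = 100, snr = 11, n_diff_per_type = 25)
sim <- simulate_mixture(design, panel, seed = 1)
fit <- ctsdm(sim$bulk, sim$phenotype, sim$fractions)
summary(fit)
```

## Ensemble statistics

External detectors (linear interaction models, matrix-factorization
methods, hierarchical Bayesian methods, ...) can be normalized into a
common CpG $\times$ cell type $\times$ method cube with `assemble_cube()`;
posterior-probability methods enter as $1 - \text{posterior}$. Two
combination rules are provided.

**Probit averaging** (`avepv()`):
$\Phi\!\left(\frac{1}{m}\sum_i \Phi^{-1}(p_i)\right)$. Note the $1/m$
normalization: under independent uniform nulls the probit mean is
$N(0, 1/m)$, so the statistic concentrates toward 0.5 rather than being
uniform — it is a *conservative* combined p-value (at $m = 5$ the
probability of falling below 0.05 under the null is about $7\times
10^{-5}$). This is a property of the statistic as defined, not an
implementation artefact; it is why probit averaging trades sensitivity for
a very low false discovery rate while remaining an excellent ranking
statistic (high AUROC). A Stouffer-calibrated variant would divide by
$\sqrt{m}$; the package implements the $1/m$ form and the test suite
documents its actual null law. Boundary p-values are clipped to
$[10^{-15}, 1-10^{-15}]$ before the probit so the result stays finite and
strictly monotone in every input.

**Beta-transformed minimum** (`minpv()`):
$F_{\mathrm{Beta}(1,m)}(\min_i p_i) = 1 - (1 - \min_i p_i)^m$, the exact
CDF of the minimum of $m$ independent uniforms, hence exactly uniform
under independent nulls and the identity map at $m = 1$. The Beta
parameter follows the subset size, so combining 2 or 3 methods uses
Beta(1, 2) or Beta(1, 3).

Both rules are calibrated under independence; p-values from methods run on
the same data are positively correlated, which makes `minpv` somewhat
anticonservative and `avepv` even more conservative than stated. The
package reports the combinations as defined and leaves dependence
corrections out of scope.

For posterior-based methods, `bayesian_fdr_threshold()` implements the
direct posterior-expected-FDR rule: with $q_j = 1 - \text{posterior}_j$
sorted ascending, reject the largest prefix whose running mean of $q$ stays
at or below $\alpha$. Posteriors exactly 1 have $q = 0$ and are always
rejected first, with stable original-order tie-breaking.

## Evaluation harness

`run_benchmark()` loops design $\times$ replicate $\times$ method:
simulate, detect, BH-adjust within cell type, call at $\alpha = 0.05$, and
record sensitivity, specificity, empirical FDR, false omission rate, F1,
AUROC (score $= 1 - p$; rank-based with ties counted one half) and — on
cell types with no planted effects — the type-I error at unadjusted
$\alpha = 0.05$, per cell type with raw confusion counts retained.
`pooled_fdr()` aggregates the empirical FDR across affected cell types by
pooling TP/FP counts within each replicate rather than averaging
per-cell-type ratios, so cell types with few rejections do not dominate.
Conventions for degenerate cases: empirical FDR is 0 when nothing is
rejected, FOR is 0 when everything is, F1 is 0 when its denominator
vanishes, and AUROC is only reported where both classes exist.

## Numerical and design choices

* Fraction rows must sum to 1 within $10^{-9}$ before mixing or fitting;
  the check fails loudly, naming the first offending row.
* Rank-deficient designs (constant fraction column, duplicated covariate,
  $n \le 2K + q$) are an error naming the offending column, not a silent
  drop.
* `assemble_cube()` tolerates bound violations up to $10^{-12}$ (clipped);
  anything larger is an error.
* p-value clipping thresholds: $10^{-6}$ for beta values (the standard
  numerical-stability epsilon on methylation arrays), $10^{-15}$ for the
  probit transform (smallest magnitude keeping `qnorm` finite well inside
  double precision).
* Levene centering defaults to the mean (classical Levene); the
  Brown–Forsythe median variant is a flag.

## What the simulation does and does not emulate

The generator reproduces the statistical skeleton of array-based mixture
benchmarks: realistic fraction ranges, per-CpG noise of the right
magnitude, effect sizes tied to noise through SNR, exact planted truth
counts, and balanced case-control designs. It does not model probe-type
chemistry, batch effects, covariate structure, inter-CpG correlation,
cell-type-correlated means beyond the common-variance structure, or the
error introduced by estimating fractions from reference libraries (though
`perturb_fractions()` lets you inject controlled fraction error). Passing
benchmarks here therefore demonstrates correctness of the detection and
aggregation machinery under the generative model, not performance on any
particular tissue or cohort.

## Problem sizes used in the shipped checks

The package's own acceptance checks run a scaled-down 450k-style study —
2,000 CpGs, 100 planted CpGs per affected cell type, SNR 11, $n = 100$,
10 replicates — which preserves the planted-to-null ratio (5% of sites
differential per affected cell type) and the per-test power of the
full-size design while completing in seconds; the full-size presets
(10,000 and 20,000 CpGs, 50 replicates) remain the defaults for real use.
Parameter-recovery checks use 20 replicates of a 500-CpG design at the
same SNR and sample size.
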