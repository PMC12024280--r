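---
title: "Multi-trait GBLUP for carcass traits in a full-sib shrimp design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait GBLUP for carcass traits in a full-sib shrimp design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Meat yield (MY, the abdominal-muscle share of body weight, in percent) is an
economically central carcass trait in *Penaeus vannamei* breeding, but it can
only be measured by sacrificing the animal. Candidates therefore cannot have
their own MY records, and selection must lean on relatives and on genetically
correlated traits that are measurable on the candidate or cheaper to record:
net meat weight (MW), body weight (BW), body length (BL), abdominal segment
length (AL). This package implements the full genomic evaluation chain for
such a design: single-trait GBLUP (STGM) and bivariate GBLUP (MTGM) animal
models fitted by AI-REML on a VanRaden genomic relationship matrix, with
CV1/CV2 cross-validation to quantify how much an auxiliary trait helps.

The reference experiment the synthetic generator emulates is a nucleus
population of 63 full-sib families with 20 offspring genotyped per family
(1260 stocked), grown in six tanks forming two light-intensity groups with
survival 83.29% and 76.94%, leaving 899 analysed animals genotyped at about
9.2k post-QC SNPs. Its published trait scales, heritabilities, genetic
correlations and CV accuracies are bundled as plain-text reference tables
(`ref_survival()`, `ref_genetic_params()`, `ref_cv_accuracy()`): the raw data
are not public, so those printed values define the stated world of the
simulator and the arithmetic checks, and every empirical claim in the test
suite is computed on synthetic data.

## Model

For one trait, `y = Xb + Zu + e` with fixed effects of sex, tank group and
their interaction (treatment coding, first level as reference), additive
genetic values `u ~ N(0, sigma_a^2 G)` and residuals `e ~ N(0, sigma_e^2 I)`.
`G` is the VanRaden matrix `Z Z' / (2 * sum(p_i (1 - p_i)))` on allele-
frequency-centred dosages, with frequencies computed from the current sample
and a small ridge (default `1e-6`) on the diagonal so `G` is invertible (its
centring otherwise forces one zero eigenvalue). For two traits the records
are stacked trait-major and

* `var(u) = Sigma_a %x% G`, `var(e) = Sigma_e %x% I`,

the standard multi-trait animal-model convention (the stacked-equation form
fixes the design but not the covariance; this is the package's reading).
Records with a missing or masked phenotype contribute no data row but their
individuals keep GEBVs through `G` and, in two-trait fits, through their
observed record on the other trait (missing-at-random REML).

Heritability is `h2 = sigma_a^2 / (sigma_a^2 + sigma_e^2)`; the genetic
correlation is `rg = cov_g / (sigma_g(x) sigma_g(y))`. Both carry
delta-method standard errors with analytic gradients applied to the inverse
average-information matrix, and Z tests use the fixed thresholds
`|Z| >= 1.96` and `|Z| >= 2.58`.

## Fitting: AI-REML, with numbers

`fit_gblup()` maximises the restricted likelihood
`-0.5 (log|V| + log|X'V^-1X| + y'Py)` over the observed records, where
`V[r,s] = Sigma_a[t_r,t_s] G[i_r,i_s] + Sigma_e[t_r,t_s] 1{i_r=i_s}`.
Scores and the average-information matrix are computed exactly on this dense
representation (`tr(P dV)` reduces to an elementwise sum because both
matrices are symmetric), which keeps one `O(N^3)` factorisation per
iteration at the design's desk scale (N <= ~1800 records).

Numerical choices that needed deciding:

* **Parameterisation.** Updates run on log variances and Fisher-z
  (`atanh`) correlations, one transform per covariance matrix. Every finite
  parameter value maps to a positive-definite matrix, so an AI step can
  never leave the PSD cone; an optimum on the boundary (a collapsed
  variance, or |rg| -> 1, which genuinely happens in small samples when the
  true correlation is 0.98) is approached smoothly instead of being crossed
  and projected. Fisher-z also keeps the curvature in the correlation
  direction bounded next to the boundary. A naive update on the covariance
  scale with PSD projection was tried first and stalls several log-likelihood
  units short of the optimum on exactly those fixtures.
* **Fallbacks.** The AI direction is step-halved until the likelihood
  increases; if no step along it helps, a Jacobi-preconditioned gradient
  direction is tried. A trust region caps any single update at one
  log/Fisher-z unit, which tames the first iterations from the default
  start (half the phenotypic variance per component, zero covariances).
  This halving-plus-preconditioned-gradient scheme is the package's
  fallback of choice (rather than interleaved EM steps) because it
  guarantees monotone ascent with far less machinery; the likelihood trace
  is recorded and asserted non-decreasing in the tests.
* **Convergence.** Both `|delta logL| < 1e-8` and a maximum relative
  parameter change below `1e-6` are required. Cross-validation refits use
  looser defaults (`1e-6` / `1e-3`) because per-fold components are
  nuisance parameters.
* **Boundary reporting.** A variance below `1e-5` of its phenotypic scale
  or a correlation with `|rho| >= 0.999` is flagged; flagged components get
  `NA` standard errors and `genetic_correlation()` declines to report.
* **Standard errors** are from the inverse AI matrix at convergence, on the
  covariance scale.

`solve_mme()` is an independent implementation of Henderson's equations
(with `Sigma_a^-1 %x% G^-1`); the tests require it to agree with direct
GLS/BLUP dense-inversion formulas to `1e-8`, and `fit_gblup()` to agree with
an eigendecomposition-based 1-D REML solver (single trait) and a restarted
Nelder-Mead maximiser (two traits) to `1e-4` in log-likelihood.

## The synthetic world

`sim_config()` defaults *are* the reference design: 63 x 20 offspring, two
parents per family drawn SNP-wise Binomial(2, p) with p ~ U(0.05, 0.5),
Mendelian gene dropping, survival 0.8329 / 0.7694 by tank group, uniform
thinning to 899, 2% missing genotype calls, and the published trait means,
SDs, heritabilities and genetic correlations for BW, BL, AL and MW. Marker
effects are multivariate normal with a common correlation across SNPs (the
infinitesimal assumption GBLUP itself makes) and are scaled by the same
`2 sum(p(1-p))` denominator the GRM uses, so simulated heritabilities are
exact in expectation on the G scale and parameter-recovery tests are
well-posed. Specific choices, made once:

* **MY is derived, not simulated**: `MY = MW / BW * 100`, preserving the
  ratio definition. Its genetic parameters are therefore controlled only
  approximately; the recovery tests parameterise two generic traits
  directly at the values of interest (h2 0.16/0.20, rg 0.78) instead of
  relying on the ratio.
* **Residual correlations default to the genetic correlations** — the only
  correlation structure the reference reports. For MW-BW (rg 0.978) this
  gives a phenotypic correlation near 0.98 and a simulated MY mean of ~50.6%
  with a CV slightly tighter (~4%) than the published 4.91%; the qualitative
  Table-2 pattern (MY CV well below MW/BW CVs) holds and is asserted as an
  inequality.
* **Fixed-effect sizes are not published**; defaults are -0.3 SD (male vs
  female), -0.2 SD (low-light group B vs A) and +0.05 SD interaction —
  modest, realistic magnitudes for a grow-out contrast. Sex is
  Bernoulli(0.5); families are blocked into six tanks (10-11 per tank, the
  reference layout at 63 families), three tanks per group.
* **Outlier exclusion (1010 -> 899) is uniform thinning**: the reference
  states only that a small number of abnormal records were excluded, so the
  generator treats exclusion as missing-at-random; the family-size
  distribution among the retained 899 is an assumption, not a claim.
* **No linkage, LD, mutation or selection**: SNPs are exchangeable and
  unlinked. A green recovery test therefore establishes correctness of the
  estimation machinery under the model's own assumptions, not robustness to
  LD structure or genotyping artefacts of real arrays.

## Cross-validation

`run_cv()` implements 5-fold random partitions (sizes differing by at most
one; 899 splits as 180/180/180/180/179). CV1 masks only the target trait of
the validation animals and keeps the auxiliary records; CV2 masks both.
Decisions where the reference is silent:

* Variance components are **re-estimated inside every training fold** (the
  leakage-free reading); `vc =` fixes them instead for the cheaper variant.
* "Repeated 5 times" is read as five independent partitions
  (`repeats = 5`); a single partition is one argument away.
* Accuracy is the Pearson correlation of the **raw** observed phenotype
  with the GEBV, and bias the OLS slope of phenotype on GEBV, exactly as
  defined; no fixed-effect pre-adjustment is applied.
* Folds are simple random, not family-stratified, matching "randomly
  divided"; undefined per-fold metrics (zero variance, non-converged fits)
  are excluded from averages with a warning rather than imputed.

At the reference parameters the dominance ordering CV1 > CV2 for the target
trait is strong and is asserted across seeds with a one-sided sign test; with
rg near 1 CV1's slope inflates above CV2's (over-reliance on the auxiliary
trait compresses GEBV spread), also asserted on average.

## Known limitations

* Bivariate models only (as in the reference); no maternal or
  common-environment random effects, so full-sib designs confound family
  environment with additive variance in ways neither the reference nor this
  package resolves.
* Dense algebra throughout: fine to a few thousand records, not meant for
  ssGBLUP-scale problems.
* The PLINK reader counts the minor allele determined from the data (ties
  to the later-sorted allele); a file whose alternative allele is the major
  one reads back flipped, which leaves `G` unchanged but matters if dosages
  are interpreted allele-specifically.
* At boundary optima the reported components are the PSD-constrained
  maximiser; their AI standard errors are suppressed rather than bent.

## A worked run

```{r}
library(mtgblup)

sim <- simulate_shrimp(sim_config(), seed = 1)
qc <- filter_genotypes(sim$genotypes)
grm <- build_grm(impute_missing(qc$genotypes))

fit <- fit_gblup(sim$pheno, grm, c("MY", "MW"))
heritability(fit)
genetic_correlation(fit)

cv1 <- run_cv(sim$pheno, grm, "MY", auxiliary = "MW", strategy = "cv1",
              repeats = 1, seed = 1)
cv2 <- run_cv(sim$pheno, grm, "MY", auxiliary = "MW", strategy = "cv2",
              repeats = 1, seed = 1)
stgm <- run_cv(sim$pheno, grm, "MY", repeats = 1, seed = 1)
relative_improvement(cv1$accuracy, stgm$accuracy)
```
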