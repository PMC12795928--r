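---
title: "Assessing gene-environment orthogonality with PGI and GREML tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing gene-environment orthogonality with PGI and GREML tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gene-environment interaction (G×E) studies increasingly moderate a polygenic
index (PGI) — a weighted sum of SNP dosages, with weights estimated by a GWAS
in an independent training sample — by a binary environmental exposure E
(a schooling reform, gender, regional socio-economic status). The interaction
coefficient in

$$ Y = \beta_0 + \beta_1\,\mathrm{PGI} + \beta_2\,E +
       \beta_3\,(\mathrm{PGI}\times E) + \gamma' C + \varepsilon $$

is only interpretable as moderation if the environment is *orthogonal* to the
genetic propensity for the outcome. Gene-environment correlation (rGE) —
whether passive (parents transmit genes and rearing environment together) or
active (people select environments matching genetic dispositions) — biases
$\beta_3$ in a direction that cannot be signed in general.

The usual diagnostic is a correlation test between the PGI and E in the
analysis sample. That test inherits every defect of the GWAS weights:
measurement error, shrinkage, model specification and selection in the
training sample all push $\mathrm{Corr}(\mathrm{PGI}, E)$ toward zero even
when the *true* genetic component of Y overlaps the genetic component of E.
Conversely, allele-frequency differences between strata (population
stratification) can produce a PGI-E correlation with no shared SNP effects at
all. This package implements a two-family test battery that separates these
cases:

1. **PGI-distribution tests** in the analysis sample: a pooled-variance
   t test of the PGI mean across the two strata (algebraically identical to
   the Pearson correlation test for binary E — the package checks this
   identity to 1e-10), a conditional correlation after residualizing the PGI
   on covariates, and a two-sample Kolmogorov-Smirnov test sensitive to any
   distributional difference (variance, skew), not just the mean.
2. **GREML tests** that never touch the GWAS weights: SNP-based heritability
   of Y and of E, and the bivariate genetic correlation $\rho_g(Y, E)$ with a
   likelihood-ratio test of $\rho_g = 0$.

The two significance flags define a quadrant verdict:

| Corr(PGI,E) | $\rho_g(Y,E)$ | verdict | reading |
|---|---|---|---|
| n.s. | n.s. | `orthogonal` | E usable for G×E interplay analysis |
| sig. | n.s. | `env_non_genetic` | genetic channels ruled out; look to selection or differential exposure |
| n.s. | sig. | `hidden_genetic_overlap` | genetic mechanisms the weights miss link Y and E |
| sig. | sig. | `not_orthogonal` | E cannot serve as an exogenous moderator |

When the environment's heritability estimate sits at the zero boundary,
$\rho_g$ is undefined and is reported as `N.A.`; an unavailable $\rho_g$
counts as a non-rejection in the verdict, which is how an exogenous policy
reform presents in practice.

## The GREML model and the AI-REML engine

The genetic relatedness matrix uses the standard per-SNP standardization

$$ A_{jk} = \frac{1}{m}\sum_{i=1}^{m}
   \frac{(x_{ij} - 2\hat p_i)(x_{ik} - 2\hat p_i)}{2\hat p_i(1-\hat p_i)}, $$

with $\hat p_i$ the sample allele frequency; zero-variance SNPs are excluded
and reported via `n_snps_used`. Univariate GREML maximizes the restricted
likelihood of $y \sim N(X b,\; \sigma^2_g A + \sigma^2_e I)$; the bivariate
model stacks two traits with covariance
$\Sigma_g \otimes A + \Sigma_e \otimes I$, parameterizing the genetic and
residual covariances directly (the average-information update is then linear
in the parameters) and reporting
$\rho_g = \sigma_{g,12} / \sqrt{\sigma_{g,11}\,\sigma_{g,22}}$. The residual
covariance is estimated jointly, not fixed at zero.

Numerical design:

* **Spectral reduction.** The GRM is eigendecomposed once per dataset; in
  the rotated basis every REML quantity reduces to weighted sums over
  eigenvalues (2×2 blocks per eigenvalue in the bivariate case). When the
  standardized genotype matrix with $m < n$ SNPs is available, the spectrum
  comes from the $m \times m$ Gram matrix at a fraction of the cost, and the
  $n - m$ zero eigenvalues are handled analytically without forming a null
  space basis.
* **AI with EM safeguards.** Three EM warm-start iterations precede
  average-information (Newton-type) updates; an AI step that leaves the
  feasible region or decreases the objective is replaced by step-halving and
  ultimately an EM step, which is monotone. Convergence is declared when the
  restricted log-likelihood moves by less than 1e-8 (cap: 200 iterations).
  When a correlation parameter is pinned at its cap (|rho| = 0.999), EM can
  only crawl along the constraint; a run of ten sub-1e-4 improvements is
  treated as converged-at-boundary.
* **Boundaries.** Variance components are constrained to at least
  `1e-8 * var(y)`. Because the profile likelihood is numerically flat near
  $\sigma^2_g = 0$, the engine also evaluates the *exact* zero solution
  (where the REML residual variance has the OLS closed form) and prefers it
  whenever it attains the maximum within 1e-6 log-units; such fits are
  flagged `boundary`, and a boundary genetic variance in either trait makes
  `rho_g` unavailable. Inside `reml_bivariate` the per-trait boundary
  decision is delegated to the univariate fits, which also provide the warm
  start.
* **Identifiability.** A GRM whose eigenvalue spread is below 1e-6 (e.g. an
  identity matrix) cannot separate genetic from residual variance; the
  engine raises a diagnostic error rather than returning arbitrary
  components.
* **Standard errors** come from the inverse average-information matrix by
  the delta method; `se_rho_g` is `NA` at a correlation boundary. The LRT
  of $\rho_g = 0$ uses a central $\chi^2_1$ reference (an interior null),
  with the statistic clipped at zero.
* The restricted log-likelihood is defined as
  $-\tfrac12[(n-p)\log 2\pi + \log|V| + \log|X'V^{-1}X| + y'Py]$, without
  the constant $\log|X'X|$ term; tests verify the converged value against a
  direct dense evaluation of the same expression.

Fixed effects default to an intercept plus 10 leading GRM principal
components in pipeline use (real-data applications of this design use 40;
the simulated cohorts carry at most one structure axis, and 10 keeps the
design well-conditioned at n in the low thousands).

## What the simulator emulates

`simulate_genotypes()` draws unlinked SNPs with ancestral frequencies uniform
on `maf_range` (default 0.05-0.5); with `fst > 0`, two equal subpopulations
receive Balding-Nichols frequencies
$p_s \sim \mathrm{Beta}(p\,(1{-}F)/F,\ (1{-}p)(1{-}F)/F)$ and dosages are
$\mathrm{Binomial}(2, p_s)$. Monomorphic draws are resampled so
standardization is always defined. Causal effects are drawn
$N(0, h^2_Y / n_\mathrm{causal})$ on dosages standardized by
$\sqrt{2\hat p(1-\hat p)}$ — the same scale the GRM uses — so that
$\mathrm{cov}(g_Y) = h^2_Y A$ holds exactly and GREML is correctly specified
under the generator. The outcome adds $N(0, 1 - h^2_Y)$ noise.

The four environment mechanisms:

* **exogenous** — a fair coin, independent of everything; the latent
  environmental genetic score is identically zero.
* **genetic_selection** — a liability threshold at zero on
  `env_loading * standardize(g_Y) + noise`, so strata are balanced and the
  point-biserial correlation between E and the genetic value is
  approximately `env_loading * dnorm(0) / 0.5`.
* **hidden_overlap** — the causal set is split into disjoint halves S1 and
  S2 with variance shares `h2_Y - s2_share` and `s2_share`. Training-sample
  outcomes load on S1 only; analysis-sample outcomes load on both; E is
  thresholded on the S2 score. GWAS weights estimated in the training rows
  therefore carry no S2 signal — the PGI-E correlation is null by
  construction — while Y and E share the S2 component in the analysis rows
  (with the defaults, $\rho_g \approx \sqrt{s2\_share / h^2_Y} \approx 0.7$).
  The training/analysis partition is a pure function of the scenario seed and
  is shared with `split_sample()`, so the two never disagree. An
  alternative mechanism — weight measurement error — is available through
  `gwas_noise_sd`.
* **strat_confound** — E is the subpopulation label; causal effects are
  identical across subpopulations and Y receives an additive shift
  (`strat_shift`, default 0.5 SD) for subpopulation 2. An uncorrected
  training GWAS absorbs the stratification into its weights, so the PGI
  correlates with E through allele-frequency differentiation alone, while
  GREML with principal-component fixed effects finds no shared SNP effects
  (typically via a boundary heritability of E, reported as `N.A.`).

Default cohort sizes are 2,000 training + 2,000 analysis individuals at
1,000 SNPs, all causal. These are desk-scale stand-ins for biobank designs:
large enough that GREML standard errors are a few percentage points and the
quadrant power studies separate cleanly, small enough that a 50-replicate
study runs in minutes.

What the generator does **not** emulate — and what passing tests therefore do
not establish about real data: linkage disequilibrium (so no LD-aware weight
adjustment is needed or provided), assortative mating, family structure and
close relatedness (pruning is exercised only by sampling noise and
structure), more than two ancestries, dominance/epistasis, binary-trait
liability-scale corrections (heritability of E is reported on the observed
scale), and participation bias beyond the stylized selection mechanisms.

## Relatedness pruning

`prune_related()` greedily removes the individual involved in the most
above-threshold pairs (ties to the lower index) until no kept pair exceeds
the cutoff; the result is a fixed point. The conventional cutoff 0.025 targets
real-scale panels where GRM noise is negligible. Off-diagonal entries between
truly unrelated individuals have standard deviation $1/\sqrt{m}$, so at
desk-scale m the pipeline resolves its default threshold as
`max(0.025, 5/sqrt(m))` — well above the noise floor, collapsing to 0.025
when m is large. Kinship-based pruning of real biobank data (KING) is out of
scope; pruning here operates on GRM entries.

## GWAS and PGI conventions

The training GWAS residualizes the phenotype once on covariates plus an
intercept, then regresses residuals on each SNP separately (simple least
squares; with unrelated simulated samples a mixed-model GWAS reduces to
this). P-values use a Student t on n-2 df; monomorphic SNPs report
`beta = 0, se = Inf, p = 1`, and an exactly perfect fit reports `p = 0`.
The PGI is the weighted dosage sum over the SNP intersection with the weight
table, standardized to mean 0/sd 1; effect-allele mismatches flip dosages
`x -> 2 - x`. Zero-variance raw scores (e.g. all-zero weights) are an error,
not a silent NaN.

## G×E specifications

`fit_gxe()` estimates the simple specification above by OLS with classical
standard errors (HC1 available). The robust specification adds `PGI^2` and
every covariate × E interaction, guarding the interaction term against
nonlinear PGI effects and covariate-E interplay. Covariates are mean-centered
before interacting (default on) to limit collinearity inflation among many
correlated interaction terms. The pipeline skips the G×E stage entirely — with
a warning — when the verdict is `not_orthogonal`, since a biased moderator
renders the interaction uninterpretable.

## Design choices that were genuinely open

* **Which p-value feeds the verdict** when the three distribution tests
  disagree is not standardized anywhere; this package uses the conditional
  correlation p when covariates are supplied and the t-test p otherwise,
  with the KS test reported alongside.
* **Pooled-variance t** rather than Welch, to preserve the exact equivalence
  with the correlation test that motivates reading the t test as a
  correlation test in the first place.
* **Central $\chi^2_1$** for the LRT rather than a boundary mixture:
  $\rho_g = 0$ is an interior hypothesis once both heritabilities are off
  their boundaries (the only situation in which the test is run).
* **Estimated residual covariance** in the bivariate model; fixing it at
  zero is only correct when the two traits are measured on disjoint samples.
* **N.A. counts as non-rejection** when tabulating LRT rejection rates: an
  environment with boundary heritability cannot exhibit genetic overlap.
* **No multiple-testing correction** across the three distribution tests;
  they are reported jointly and interpreted as one family.

## Problem sizes used by the checks

The packaged calibration studies use: heritability recovery at n = 2,000,
m = 1,000 over 50 seeds (mean within ±0.03 of truth); genetic-correlation
recovery at the same size over 30 seeds (±0.05); LRT size at n = 1,000,
m = 400 over 200 seeds (binomial band [0.02, 0.09] around 0.05); and
50-replicate quadrant studies at the default scenario sizes. The
`scripts/acceptance.R` report recomputes the same quantities at comparable
sizes with seeds derived from its `--seed` argument.

## Known limitations

Observed-scale heritability for binary environments understates the liability
scale value; with balanced strata the two differ by the factor
$\varphi(0)^2 / 0.25 \approx 0.64$, which matters for effect-size reading but
not for the zero/nonzero decisions the verdict relies on. The AI-REML
standard errors are asymptotic; at n below a few hundred the 2-SE coverage
degrades. The KS exact p-value is only used when `n0 * n1 <= 10000` and the
scores are tie-free. Real-data ingestion is limited to plain-text dosage
matrices and the PLINK `.raw` dialect.
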