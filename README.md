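# gxeortho

Orthogonality assessment for polygenic gene–environment interaction studies.

## The problem

Gene–environment interaction (G×E) studies estimate how an environment E
moderates the effect of a polygenic index (PGI) on an outcome Y:

    Y = b0 + b1·PGI + b2·E + b3·(PGI × E) + g'C + e

The interaction coefficient `b3` is only interpretable if E is *orthogonal*
to the genetic propensity for Y. The customary diagnostic — correlating the
PGI with E in the analysis sample — inherits every defect of the GWAS
weights behind the PGI: measurement error, shrinkage, specification and
sample selection in the training sample can hide a real genetic overlap
(false reassurance), while allele-frequency differences between strata can
manufacture a PGI–E correlation with no shared SNP effects at all (false
alarm).

`gxeortho` implements a two-family battery that separates these cases:

1. **PGI-distribution tests** — pooled-variance t test of the PGI mean
   across strata (identical, for binary E, to the Pearson correlation test),
   a covariate-conditional correlation, and a two-sample Kolmogorov–Smirnov
   test for any distributional difference.
2. **GREML tests** that never touch the GWAS weights — SNP heritability
   h²_SNP of Y and of E and the bivariate genetic correlation ρ_g(Y, E)
   estimated by average-information REML on a genetic relatedness matrix
   (GRM), with a likelihood-ratio test of ρ_g = 0. When ĥ²(E) sits at the
   zero boundary, ρ_g is undefined and reported N.A.

The two significance flags place the pair (Y, E) in one of four quadrants:
`orthogonal`, `env_non_genetic` (PGI–E correlation without genetic overlap),
`hidden_genetic_overlap` (genetic overlap the weights miss), or
`not_orthogonal`. A seeded forward simulator generates cohorts realizing
each quadrant — exogenous assignment, genetic selection into E, hidden
genetic overlap via causal SNPs absent from the training-sample signal, and
pure population-structure confounding under a Balding–Nichols model — so
the disagreement between the two families can be demonstrated and the
estimators calibrated.

## Worked example

Simulate the headline failure mode — an environment selected on a genetic
component of Y that the GWAS training sample cannot see — and run the full
pipeline (training GWAS → PGI → GRM + pruning → test battery → verdict):

```r
library(gxeortho)

cfg <- gxe_config(scenario = sim_scenario("hidden_overlap", seed = 5))
pl  <- run_pipeline(cfg)
pl$report
```

```
Orthogonality report
  corr(PGI, E)         -0.0227   (t = -1.012, p = 0.3115)
  corr | covariates    -0.0225   (p = 0.316)
  KS statistic          0.0293   (p = 0.785)
  h2_SNP (trait)      0.514 (0.024)
  h2_SNP (env)        0.543 (0.023)
  rho_g               0.643 (0.040)
  LRT p (rho_g = 0)   3.755e-38
  N = 1998
verdict: hidden_genetic_overlap
  The PGI appears uncorrelated with the environment, yet Y and E are
  genetically correlated: genetic mechanisms not captured by the GWAS
  weights link outcome and environment.
```

The correlation test is silent (p = 0.31) while bivariate GREML finds
ρ_g = 0.64 with an overwhelming likelihood-ratio test — exactly the case in
which relying on the PGI–E correlation alone would wrongly certify the
environment as exogenous. Rejection rates across scenarios and seeds come
from the study runner:

```r
st <- run_scenario_study(c("hidden_overlap", "strat_confound"),
                         n_reps = 20, base_seed = 1)
st[, c("scenario", "rejection_rate_corr", "rejection_rate_rg")]
#>         scenario rejection_rate_corr rejection_rate_rg
#> 1 hidden_overlap                0.05                 1
#> 2 strat_confound                1.00                 0
```

The two disagreement quadrants are realized symmetrically: under hidden
overlap only the GREML test fires; under stratification confounding only
the PGI correlation fires (with PC-adjusted GREML reporting a boundary
ĥ²(E), hence N.A.).

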