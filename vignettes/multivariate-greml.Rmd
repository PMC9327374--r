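---
title: "Multivariate GREML with genetic and environmental factor models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate GREML with genetic and environmental factor models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvgreml)
```

## The model

For $N$ unrelated individuals measured on $T$ traits, with $\mathbf{A}$ the
$N \times N$ genomic-relationship matrix (GRM) built from $M$ standardized
SNPs, `mvgreml` fits the multivariate linear mixed model

$$
\mathbf{y} \sim \mathcal{N}\!\left(\mathbf{Z}\boldsymbol\beta,\;
\mathbf{V}_G \otimes \mathbf{A} + \mathbf{V}_E \otimes \mathbf{I}_N\right),
$$

where $\mathbf{y}$ stacks the trait vectors, $\mathbf{Z}$ is the
block-diagonal fixed-effect design (each trait has its own covariate set),
$\mathbf{V}_G$ is the genetic variance matrix and $\mathbf{V}_E$ the
environmental (residual) variance matrix. The quantities of scientific
interest are the SNP-based heritabilities
$h^2_t = \sigma_{G,tt} / (\sigma_{G,tt} + \sigma_{E,tt})$ and the genetic
correlations
$\rho_G(t,s) = \sigma_{G,ts} / \sqrt{\sigma_{G,tt}\,\sigma_{G,ss}}$,
with the environmental correlations defined analogously.

Estimation is by restricted maximum likelihood (REML): the likelihood of
error contrasts, which removes fixed-effect uncertainty from the variance
estimates. Up to a constant,

$$
\ell(\boldsymbol\theta) = -\tfrac{1}{2}\left(
\log\lvert\mathbf{V}\rvert +
\log\lvert\mathbf{Z}^\top\mathbf{V}^{-1}\mathbf{Z}\rvert +
\mathbf{y}^\top\mathbf{M}\mathbf{y}\right),
\qquad
\mathbf{M} = \mathbf{V}^{-1} - \mathbf{V}^{-1}\mathbf{Z}
(\mathbf{Z}^\top\mathbf{V}^{-1}\mathbf{Z})^{-1}
\mathbf{Z}^\top\mathbf{V}^{-1}.
$$

## Factor-model parameterization

Both variance matrices are parameterized through factor models,
$\mathbf{V}_G = \mathbf{C}_G\mathbf{C}_G^\top$ and
$\mathbf{V}_E = \mathbf{C}_E\mathbf{C}_E^\top$, where each $\mathbf{C}$ is a
$T \times F$ loading matrix whose free cells are given by a user-specified
binary pattern (a `factor_model` object, or a labelled 0/1 text file read by
`read_factor_model()`). The default is the *saturated* model: a
lower-triangular pattern with $T(T+1)/2$ free loadings per matrix, which can
represent any positive semidefinite variance matrix. Because every implied
$\mathbf{V}$ is a Gram matrix, estimated correlation matrices are positive
semidefinite with unit diagonal by construction — for any pattern and any
coefficient values — which is the central structural guarantee of this
parameterization. Factors are orthogonal with unit variance; the free
coefficients are unconstrained reals, so no explicit positivity constraints
are needed during optimization.

Model comparison is by likelihood-ratio test: for a main model $A$ and a
model $0$ nested within it, $\mathrm{LRT} = 2(\ell_A - \ell_0)$ is
asymptotically $\chi^2$ with degrees of freedom equal to the difference in
free-loading counts, $(C_{G_A}+C_{E_A}) - (C_{G_0}+C_{E_0})$
(`lrt_df()`, `anova()`). When the null places a parameter on the boundary
of the parameter space (e.g. a trait with no genetic variance at all), the
$\chi^2$ reference can be conservative; the standard $\chi^2$ p-value is
reported regardless, with this caveat.

Identification is the user's responsibility in principle (the usual
structural-equation-modeling conditions apply), but `mvgreml()` refuses to
fit models that fail a numerical check: free counts above $T(T+1)/2$ per
matrix, duplicated factor columns, or a rank-deficient Jacobian of the
half-vectorized $(\mathbf{V}_G, \mathbf{V}_E)$ with respect to the free
coefficients, evaluated at three random interior points. A rank test at
random points detects the permutation and rotation symmetries that make a
pattern unidentifiable while being agnostic to the particular model. Sign
indeterminacy (negating a whole factor column leaves $\mathbf{V}$ unchanged)
is resolved in reporting only: the first free loading of each factor is made
nonnegative.

## The canonical transform and the likelihood kernel

The covariance $\mathbf{V}_G \otimes \mathbf{A} + \mathbf{V}_E \otimes
\mathbf{I}$ is dense, and naive evaluation of $\ell$ would cost
$O(N^3T^3)$. Writing $\mathbf{A} = \mathbf{Q}\boldsymbol\Phi\mathbf{Q}^\top$
for its eigendecomposition and rotating the data by the eigenvectors not
belonging to the $L$ largest eigenvalues turns the covariance into $n = N-L$
independent $T \times T$ blocks $\mathbf{V}_j = d_j\mathbf{V}_G +
\mathbf{V}_E$, one per retained eigenvalue $d_j$. Dropping the $L$ leading
principal components (default $L = 20$, `adjust_pcs`) eliminates their
contribution from the likelihood entirely, absorbing population
stratification without extra fixed effects. Near-zero retained eigenvalues
are kept: a block with $d_j = 0$ simply reduces to $\mathbf{V}_E$ and is
still informative.

Per parameter value, one simultaneous diagonalization of the pair
$(\mathbf{V}_G, \mathbf{V}_E)$ — Cholesky of $\mathbf{V}_E$ followed by a
symmetric eigensolve, $O(T^3)$ once — yields a whitening $\mathbf{W}$ with
$\mathbf{W}\mathbf{V}_E\mathbf{W}^\top = \mathbf{I}$ and
$\mathbf{W}\mathbf{V}_G\mathbf{W}^\top = \mathrm{diag}(\lambda)$, so each
block's inverse and log-determinant become diagonal operations:
$\log\lvert\mathbf{V}_j\rvert = \log\lvert\mathbf{V}_E\rvert + \sum_t
\log(d_j\lambda_t + 1)$. The whole log-likelihood then costs $O(nT(T+k))$
with $k$ covariates, the projection matrix $\mathbf{M}$ is only ever applied
to vectors, and all block sums are vectorized.

The gradient exploits the structure of the derivatives
$\partial\mathbf{V}/\partial\theta_i$: for a loading $\gamma_{tf}$,
$\partial\mathbf{V}_G/\partial\gamma_{tf} = \mathbf{e}_t\mathbf{c}_f^\top +
\mathbf{c}_f\mathbf{e}_t^\top$ is rank $\le 2$ and block-constant, so every
partial derivative is read off two aggregated $T \times T$ matrices
($\sum_j c_j \mathbf{M}_{jj}$ and $\sum_j c_j \mathbf{r}_j\mathbf{r}_j^\top$
with $c_j = d_j$ or $1$, $\mathbf{r}_j$ the j-th residual block of
$\mathbf{M}\mathbf{y}$) at $O(T^2)$ per parameter after one $O(nT^2)$
accumulation — no per-parameter pass over the data. The average-information
(AI) matrix, $\mathrm{AI}_{ij} = \tfrac12 \mathbf{y}^\top \mathbf{M}
\dot{\mathbf{V}}_i \mathbf{M} \dot{\mathbf{V}}_j \mathbf{M}\mathbf{y}$, does
require one operator application of $\mathbf{M}$ per parameter and is
therefore computed only once, at the optimum (or never, with `se = FALSE`).

Numerical safeguards, in one place:

* $\mathbf{V}_E$ must be positive definite for the whitening; if its
  Cholesky fails, one shot of jitter ($10^{-8}\times$ mean diagonal) is
  tried, after which the fit aborts with advice to use a (closer to)
  saturated environmental model.
* generalized eigenvalues $\lambda_t$ and GRM eigenvalues are clipped at
  zero (both are nonnegative in exact arithmetic); a block with
  $d_j\lambda_t + 1 \le 10^{-12}$ raises an error rather than silently
  returning $-\infty$.
* non-finite objective values inside the line search are treated as
  $-\infty$, so the search simply backs away from invalid regions.

A dense-matrix evaluator (`.dense_reml_oracle`, restricted to
$NT \le 400$) materializes the full covariance and serves as the
equivalence oracle in the tests; the transformed kernel agrees with it to
below $10^{-8}$ in log-likelihood, fixed effects, and AI entries.

## Optimization

The free coefficients are estimated by BFGS ascent with a golden-section
line search. The inverse-Hessian approximation starts at a scaled identity,
making the first iteration a gradient-ascent step. The line search brackets
by geometric doubling while the objective improves, then contracts by the
golden ratio; if no improving step exists the iteration counts as unstable.
After `reset_patience = 2` consecutive unstable iterations the
approximation is reset (again gradient ascent); after `ai_after_resets = 2`
consecutive resets a single damped Newton step using the AI matrix — ridge
doubled until the system solves and the step ascends, with step-halving —
is taken before BFGS resumes. BFGS updates are skipped (not damped) when
the curvature condition fails; resets cover pathological stretches.

Starting values split each trait's sample variance 50/50 between the
genetic and environmental side: for each row of each pattern, the first
free loading is set to $\sqrt{0.5\,\widehat{\mathrm{var}}}$ and any further
free loadings to $0.1\,\widehat{\mathrm{sd}}$ — nonzero to break the
symmetry between factors loading on the same traits. Convergence is
declared when the root-mean-square gradient divided by $n$ falls below
`grad_tol = 1e-5`. Defaults (`mvgreml_control()`): `max_iter = 300`,
`gss_tol = 1e-6`. Given the data and control settings the fit is fully
deterministic; the `seed` only feeds the identification check's random
evaluation points.

Accepted iterations never decrease $\ell$ (asserted over the stored trace),
and refits from jittered starts reach the same optimum to $10^{-4}$ on
well-identified problems.

## Standard errors and fixed effects

At $\widehat{\boldsymbol\theta}$, the coefficient covariance is the inverse
AI matrix (pseudo-inverse with a warning when the condition number exceeds
$10^{12}$). Standard errors for $h^2$, $\rho_G$ and $\rho_E$ follow by the
delta method with analytic Jacobians chained through
$\mathbf{V} = \mathbf{C}\mathbf{C}^\top$; a central-finite-difference
cross-check of those Jacobians is part of the test suite. Correlations
involving a trait with exactly zero genetic variance are reported as `NA`
(undefined), never as 0. Estimated correlations are reported unclipped; the
Gram-matrix parameterization already prevents $\lvert\rho\rvert > 1$ beyond
rounding. GLS fixed effects
$\widehat{\boldsymbol\beta} = (\mathbf{Z}^\top\mathbf{V}^{-1}\mathbf{Z})^{-1}
\mathbf{Z}^\top\mathbf{V}^{-1}\mathbf{y}$ and their standard errors come
from the same whitened per-block accumulations as the likelihood.

## The simulator

`simulation_design()` / `simulate_dataset()` generate data *under the
model*, which is exactly what makes them usable as an oracle for the
estimator: allele frequencies uniform on (0.01, 0.5], genotypes
binomial(2, p) standardized in sample, the GRM computed from those
standardized genotypes, per-SNP effects jointly normal across traits with
covariance $\mathbf{V}_G / M$ (so genetic values have covariance
$\mathbf{V}_G \otimes \mathbf{A}$ conditional on the realized GRM), and
environmental residuals with covariance $\mathbf{V}_E$. Total per-trait
variance is 1, so $\mathrm{diag}(\mathbf{V}_G)$ equals the target
heritabilities. Three stock designs cover a uniform correlation across all
pairs (design 1, default $\rho_G = 0.3$), two clusters with random
within-cluster correlations (drawn through a random single-factor structure
with loadings uniform on $[-1, 1]$, which guarantees positive
semidefiniteness) and zero between (design 2), and many independent traits
(design 3, $T = 50$). All SNPs are causal with infinitesimal effects, and
environmental correlations default to zero; both are deliberate simplest
choices consistent with the model being fitted. Replicates draw from
streams derived deterministically from (master seed, replicate), so any
replicate is reproducible in isolation, byte-for-byte in the written
fixture files.

What the simulator does *not* emulate — linkage disequilibrium,
minor-allele-frequency/effect-size coupling, ascertainment, population
structure, missingness — bounds what passing tests show: they validate the
estimator and its inferences under the model's own assumptions, not
robustness of those assumptions on real cohort data. Stratification
correction, in particular, is exercised only through the mechanics of the
`adjust_pcs` option, not by simulating confounded data.

## Problem sizes used in the tests

The test suite works at deliberately modest scale: dense-oracle
equivalence at $N \le 30$, $T \le 3$ (where the $NT \times NT$ covariance
is cheap to build); heritability recovery on 10 replicates at $N = 2000$,
$M = 2000$, $T = 5$ (mean $\widehat{h}^2$ within $\pm 2$ percentage points
of the 50% target); between-cluster structure recovery at $N = 800$,
$T = 10$; and likelihood-ratio calibration from 200 null replicates at
$N = 300$, $T = 2$, where the fitted null (independent genetic factors,
$\rho_G = 0$) is interior to the parameter space so the $\chi^2_1$
reference applies and the p-values are checked for uniformity by a
Kolmogorov–Smirnov test. Estimator consistency appears in the suite as a
decreasing error from $N = 300$ to $N = 1200$ rather than as an asymptotic
claim.

## Known limitations

* One GRM only: no partitioned heritability, no multiple random effects.
* Complete-case analysis: individuals missing any trait or applicable
  covariate are dropped at alignment, keeping the Kronecker structure
  exact. No EM-style handling of partially observed trait vectors.
* Loadings are free or zero; equality constraints across loadings and
  correlated factors are out of scope (correlated factors can be emulated
  by adding shared factors, as in the worked height/BMI model).
* The GRM is taken as given ("unrelated" individuals are the user's
  responsibility); no relatedness pruning is applied.
* The full eigendecomposition is computed in memory, which bounds practical
  $N$ at a few tens of thousands on a workstation.

## A worked example

```{r example, eval = FALSE}
# two clusters of traits with no genetic correlation between clusters
design <- simulation_design(2, N = 800, M = 800, T_traits = 6, seed = 42)
ds <- simulate_dataset(design, replicate = 1)

fit <- mvgreml(ds$pheno, ds$grm, adjust_pcs = 0)
summary(fit)

# do between-cluster genetic correlations improve the fit? The nested
# model has one shared genetic factor per cluster plus one specific factor
# per trait, which fixes the between-cluster block of rho_G at zero
pat <- cbind(kronecker(diag(2), matrix(1, 3, 1)), diag(6))
nested <- mvgreml(ds$pheno, ds$grm, adjust_pcs = 0, se = FALSE,
                  genetic_model = factor_model(pat, traits = ds$pheno$traits))
anova(fit, nested)
```
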