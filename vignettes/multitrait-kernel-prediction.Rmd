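---
title: "Multitrait multienvironment kernel prediction: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitrait multienvironment kernel prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MTKern)
```

## The model

MTKern fits, for $n$ line-by-environment cells and $n_T$ traits,

$$Y = X_E \beta_E + Z_L g + Z_{EL}\, gE + \epsilon,$$

with $g \sim MN(0, K_l, \Sigma_T)$ (matrix-variate normal: $\mathrm{vec}(g)$
is Gaussian with covariance $\Sigma_T \otimes K_l$),
$gE \sim MN(0, K_L \circ K_E, \Sigma_{TE})$ and
$\epsilon \sim MN(0, I_n, R)$. $K_l$ is one of four marker kernels; $K_L =
Z_L K_l Z_L^T$ expands it to cells, $K_E = X_E X_E^T$ is the
environment block kernel, and $\circ$ is the Hadamard product. With complete
cells in environment-major order, $K_L \circ K_E$ is block-diagonal with one
copy of $K_l$ per environment — the Kronecker interaction form with an
identity environment covariance.

Assumptions worth stating explicitly: phenotype rows are exchangeable given
their line and environment (no spatial field structure); residual rows are
i.i.d. across cells with a shared unstructured trait covariance $R$ (no
heterogeneous residual variance per environment); and missingness is
ignorable (missing at random given the observed traits of the row).

### Kernels and marker scaling

All four kernels consume the same scaled marker matrix: each column centered,
each polymorphic column standardised to unit **population** variance (the
$1/J$ denominator, so a two-line column $(0,2)$ scales to $(-1,1)$),
monomorphic columns set to zero rather than raising an error (they carry no
signal and are common after filtering), and the whole matrix divided by
$\sqrt{p}$. Row inner products and squared distances are then $O(1)$
regardless of marker count, which is what makes the shared default
$\gamma = 1$ meaningful:

| kernel | formula | defaults |
|---|---|---|
| linear (GBLUP) | $x_i^T x_j$ | — |
| polynomial | $(\gamma x_i^T x_j + a)^d$ | $\gamma=1$, $a=0$, $d=3$ |
| sigmoid | $\tanh(x_i^T x_j + a)$ | $a=0$ |
| Gaussian | $\exp(-\gamma \lVert x_i - x_j\rVert^2)$ | $\gamma=1$ |

Two conventions were genuinely open. First, whether Gaussian distances are
computed before or after the $\sqrt{p}$ division: we compute them after, on
the same matrix every kernel sees, for consistency and invariance to marker
count (a different choice only rescales the effective $\gamma$). Second, the
sigmoid offset $a$ is nowhere specified by the method's sources; we default
to $a = 0$, matching the polynomial default and $\tanh$'s natural zero. The
sigmoid kernel is not positive semidefinite in general, which is why every
kernel passes through spectral preparation before use as a covariance.

### Spectral repair and the eigenspace sampler

`spectralDecompose()` retains eigenpairs with
$\lambda > \text{tol}\cdot\lambda_{max}$ (default $10^{-8}$) and replaces the
kernel by $\sum_m \lambda_m v_m v_m^T$. Truncation (projection onto the PSD
cone) is used rather than diagonal loading because the sampler then works
*exactly* on the repaired operator: the cell-level effect of a term is
$u = V b$ with independent rows $b_m \sim N(0, \lambda_m \Sigma)$, and no
approximation error is reintroduced. A kernel with no positive eigenvalue is
rejected as degenerate.

## The Gibbs sweep

Each iteration, in order:

1. **Environment means.** With a flat prior and i.i.d. residual rows, the
   conditional for environment $e$'s mean vector is
   $N(\bar r_e, R / n_e)$ with $\bar r_e$ the average partial residual in
   that environment. One mean per environment per trait is the full-rank
   parameterisation: a separate global intercept would be non-identifiable,
   so the reported trait intercept is simply the average of environment
   means.
2. **Eigen-coefficients.** For each random term, project the partial
   residual onto the kernel's eigenvectors; coefficient row $b_m$ has
   conditional precision $R^{-1} + \lambda_m^{-1}\Sigma^{-1}$. Because only
   $\lambda_m$ varies across $m$, $R$ and $\Sigma$ are jointly diagonalised
   once per sweep ($R = U^TU$, $U\Sigma^{-1}U^T = Q\Phi Q^T$), after which
   all $r$ rows update in a handful of dense matrix products.
3. **Trait covariances.** $\Sigma \mid b \sim
   IW(v_0 + r,\; S_0 + B^T D^{-1} B)$ with $D = \mathrm{diag}(\lambda)$.
4. **Residual covariance.** $R \mid \cdot \sim IW(v_R + n,\; S_R + E^TE)$
   with $E$ the full residual matrix.
5. **Missing traits.** Every cell's missing entries are redrawn from the
   Gaussian conditional of $N(\eta_i, R)$ given the row's observed traits
   ($\eta_i$ the current linear predictor). Rows are grouped by missingness
   pattern so the conditional weights are formed once per pattern.

At every iteration fitted + residual reconstructs the current imputed $Y$
exactly; the maximum reconstruction error over the whole chain is stored in
the fit's diagnostics and asserted in the tests.

**Predictions.** For entries masked during fitting, the prediction is the
posterior mean of the imputed draws — which is how observed auxiliary traits
in a test cell (the MT\_P scenario) inform the target trait through $R$. For
observed entries it is the posterior mean of the linear predictor.

### Priors and defaults

The inverse-Wishart convention here is the one with prior mean
$S/(v - n_T - 1)$; conventions differ across software, so all degrees of
freedom below are in this parameterisation. Defaults, used when the caller
supplies none:

* $v_0 = n_T + 2$ for every covariance — the smallest integer df with a
  finite mean, hence weakly informative;
* scales set by a standard variance-partition heuristic: the prior mean of
  each random term's trait covariance is $(0.5/\#\text{terms})\cdot
  \mathrm{diag}(\widehat{\mathrm{var}}(Y_{obs}))$ and the prior mean of $R$
  is $0.5\cdot$ the same diagonal. The method's sources state no values.
* MCMC lengths: `nIter = 10000`, `burnIn = 2000`, `thin = 5` for production;
  the test suite uses 1500/500/2 and documents where it scales further down.
  The sources give the iteration counts only symbolically.
* Missing entries initialise at their trait's observed mean within
  environment, falling back to the global trait mean.

Each random term gets its **own** trait covariance ($\Sigma_T$ for lines,
$\Sigma_{TE}$ for the interaction). The model statement in the method's
sources reuses one $\Sigma_T$ for both, but the reference software fits one
covariance per term; we follow the software semantics and do not provide a
shared-covariance mode. Similarly, the interaction is implemented through the
Hadamard kernel (environment covariance fixed at identity), with
environment-scale differences absorbed into $\Sigma_{TE}$, because that is
the construction the two-step implementation actually uses.

### Randomness and determinism

R has a single global RNG stream, so instead of named substreams every entry
point with randomness (`fitMultitrait`, `cv2Folds`, `runCVExperiment`, the
simulators, the CLI) takes a `seed` argument and seeds once on entry.
Identical seed + configuration + data gives bit-identical draws, which the
tests assert, including byte-identical CLI report files. Row order is
canonicalised (environment-major) at `PhenotypeTable` construction, so
permuted input rows cannot change results through RNG consumption order.

## Cross-validation protocol

`cv2Folds()` partitions *cells* uniformly into $k$ near-equal folds (sizes
differ by at most one). Because cells rather than lines are partitioned, a
line is typically trained in some environments and tested in others — the
CV2 design that mimics incomplete trials. No stratification by environment is
applied beyond random balance, since the protocol's description specifies
none. `runCVExperiment()` reuses identical folds and masks for every method
in the grid (a paired design; the published percent comparisons suggest
shared partitions, and pairing strictly sharpens the comparison), defaults to
a single 5-fold repetition, and aggregates as: across folds first (unweighted
mean per environment-trait stratum), then across environments (unweighted
mean of the per-environment values, *not* a pooled MSE — the rule validated
in the tests against the published per-environment/across-environment table
pair). Under MT\_P the default mask predicts the first trait and keeps all
others observed; both sets are fully configurable since the protocol's exact
observed set is not pinned down by its description.

`"brr"` is accepted as a method name but is implemented as the linear-kernel
model: Gaussian i.i.d. marker effects are posterior-predictive-equivalent to
linear-kernel GBLUP, and the equivalence is verified in the acceptance suite
against an explicit marker-effect ridge solve rather than assumed.

## What the simulator emulates — and what it does not

`simulateMultitrait()` draws from exactly the model above: binomial 0/1/2
dosages with per-marker allele frequency uniform on (0.05, 0.95) (a
post-QC-like frequency spectrum), genetic effects drawn in kernel space so
that any kernel — including the Gaussian — can be the *true* architecture,
and all components stored for exact-reconstruction and recovery tests. A
`markerEffects = TRUE` mode instead draws i.i.d. marker effects, creating a
true-linear world for the GBLUP/ridge equivalence checks.

Stated-world defaults, chosen once: $J = 150$ lines, $p = 300$ markers,
$I = 3$ environments, $n_T = 2$ traits (a desk-scale shrink of elite yield
trials with hundreds of lines, ~2000 markers and 4–5 environments); genetic
trait correlation 0.9 at unit variance (the recovery target used throughout
the tests, chosen near the high correlations reported for maturity traits);
interaction covariance at half the genetic scale with the same correlation
(G×E present but subordinate to the main effect, as in multi-irrigation
trials); residual correlation 0.5 at unit variance (traits share measurement
conditions but less tightly than genetics); environment-mean spread
`envEffectSd = 2` trait-units (environment shifts visibly larger than
residual noise, as days-to-heading differs across irrigation regimes); no
missingness.

What it does **not** emulate: linkage disequilibrium or pedigree structure
among lines, dominance/epistasis generated at the marker level, spatial field
trends, non-Gaussian traits, or informative missingness. A green recovery
test therefore establishes that the sampler inverts its own generative model
at realistic shapes and noise levels — not that the model is correct for any
particular field dataset.

## Numerical choices

* Kernel symmetry tolerance $10^{-10}$ relative; construction symmetrises
  $(K + K^T)/2$ before validation.
* Spectral truncation threshold $10^{-8}\cdot\lambda_{max}$.
* PSD checks on row covariances allow eigenvalues down to
  $-10^{-8}\cdot\lambda_{max}$ (numerical zeros), and matrix-normal sampling
  uses the eigendecomposition, never Cholesky, so rank-deficient repaired
  kernels are accepted.
* Monomorphic marker columns scale to zero; environments with fewer than two
  observed cells trigger a warning (their means are weakly determined) but do
  not error.
* Inverse-Wishart draws go through the Wishart-of-the-inverse route using the
  stock Wishart sampler, with symmetrisation after each inversion.

## Limitations

* The residual covariance is shared across environments; heterogeneous $R_e$
  is out of scope.
* No REML/frequentist fitting, no convergence diagnostics beyond the stored
  covariance traces (effective-sample-size analysis can be run on
  `fit@draws`), and no variable-selection priors.
* Kernel hyperparameters are fixed per fit, not tuned; the CV harness is the
  intended tuning loop.
* Marker QC and genotype imputation are upstream of this package: the CSV
  reader mean-imputes missing marker cells only as a convenience, and says
  so.
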