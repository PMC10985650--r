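---
title: "Mass-univariate linear mixed models on product forms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-univariate linear mixed models on product forms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxlmm)
```

## The model

At every voxel $v$ of an analysis mask, voxlmm fits the linear mixed model

$$Y_v = X\beta_v + Z b_v + \epsilon_v, \qquad
  \epsilon_v \sim N(0, \sigma_v^2 I_n), \qquad
  b_v \sim N(0, \sigma_v^2 D_v),$$

where the $n \times p$ fixed design $X$ and the $n \times q$ random design
$Z$ are shared across voxels while the response and all parameters vary
voxel-wise. Random effects are organised by *factors*: factor $k$ groups
$q_k$ effect regressors (its raw regressor matrix $z_k$) into $l_k$ levels
(its factor vector $g_k$). $Z$ concatenates one block per factor, each block
the row-wise Khatri–Rao product of the level-indicator matrix $J_k$ with
$z_k$; columns are ordered level-major (all effects of level 1, then level 2,
…), the same ordering used for $\mathrm{vec}(D_k)$ everywhere downstream.
The covariance is block-diagonal, $D = \bigoplus_k (I_{l_k} \otimes D_k)$,
with one free $q_k \times q_k$ symmetric block per factor. Note that $D$ is
*relative* to $\sigma^2$: the random-effect covariance in response units is
$\sigma^2 D$.

Estimation maximises the restricted likelihood (constants dropped)

$$\ell_R(\theta) = -\tfrac12\left\{(n_v - p)\log\sigma^2
   + \sigma^{-2} e' V^{-1} e + \log|V| + \log|X' V^{-1} X|\right\},
  \qquad V = I + Z D Z',\; e = Y - X\beta,$$

with $n_v$ the voxel's observed-image count (see missingness below).

## Missingness by zero-ing

Large-$n$ image sets are missing data near tissue boundaries: a voxel is
treated as missing in an image when the per-image mask excludes it or the
stored value is exactly 0 or NaN. Missing responses are encoded as 0 and the
matching design rows are zero-ed. Because every quantity the model needs is
a cross-product, zero rows contribute nothing: the zero-ed formulation is
exactly the row-deleted formulation, with $n_v$ replacing $n$ in the
likelihood. Voxels sharing a missingness pattern share the design-dependent
cross-products, so patterns are grouped (exactly, by packed-bit key with
verification) and $P$, $R$, $U$ and the rank checks are computed once per
group. A missingness threshold (default 50%, boundary inclusive, i.e.
retained iff $n_v \ge \lceil 0.5\,n\rceil$) removes voxels with too little
data; after that, a rank filter drops voxels whose observed design has lost
numerical rank relative to the complete design (singular values above
$\max(p,q)\,\epsilon\,\sigma_{\max}$), unless safe mode is turned off. The
reference is the *full design's own* rank rather than $p$ and $q$
outright, because crossed random-intercept designs are structurally
rank-deficient in $Z'Z$ — each factor's intercept columns sum to the ones
vector — which is benign; only missingness-induced additional deficiency
(for example a factor level with no observed images at the voxel) marks a
voxel as unestimable.

## Product forms

Everything after input reduction uses only the six cross-products

$$P = X_v'X_v,\; Q = X_v'Y_v,\; R = X_v'Z_v,\; S = Y_v'Y_v,\;
  T = Y_v'Z_v,\; U = Z_v'Z_v,$$

whose sizes depend on $p$ and $q$ but never on $n$. They are accumulated by
an image-wise map-reduce: rows are split into $B$ contiguous batches (sizes
differing by at most one), each batch computes partial forms, and a reducer
sums them pairwise in fixed batch order so results are bit-reproducible and
independent of $B$. Partial forms can be persisted as flat binary plus a
JSON sidecar, letting an interrupted run resume at the reduction boundary.
The in-process batch loop deliberately preserves the partition → partial →
central-sum contract of a cluster deployment, so a scheduler backend is a
drop-in replacement.

All likelihood quantities are recovered from the forms through the Woodbury
identity and the matrix determinant lemma:

$$X'V^{-1}X = P - R\,D(I_q + UD)^{-1}R', \qquad
  \log|V| = \log|I_q + UD|,$$

and analogously for $X'V^{-1}Y$, $Y'V^{-1}Y$, $Z'V^{-1}Z$, $Z'V^{-1}X$,
$Z'V^{-1}Y$. For a single-factor model $U$ is block-diagonal by level
(levels occupy disjoint rows), so $(I + UD)$ factors into $l_k$ blocks of
size $q_k$ and the per-iteration cost drops from $O(q^3)$ to
$O(l_k q_k^3)$; this block route and the dense route are algebraically
identical and are required by the test suite to agree to $10^{-10}$.

## The scoring optimiser

Each iteration updates $(\beta, \sigma^2)$ by generalised least squares and
each $\mathrm{vec}(D_k)$ by a Fisher-scoring step
$\mathrm{vec}(D_{s+1}^k) = \mathrm{vec}(D_s^k) + \alpha_s (F^k)^{-1}\partial^k$,
followed by projection of $D_k$ onto the non-negative-definite cone
(symmetrise, clip negative eigenvalues, reconstruct). The score is

$$\partial^k = \mathrm{vec}\!\left(\sum_j \sigma^{-2}
  (Z_j'V^{-1}e)(Z_j'V^{-1}e)' - Z_j'V^{-1}Z_j
  + Z_j'V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}Z_j\right),$$

twice the gradient of $\ell_R$ in the "full" (all $q_k^2$ coordinates)
representation; the factor two cancels against the simplified information
$F^k = \sum_{i,j} (Z_i'V^{-1}Z_j) \otimes (Z_i'V^{-1}Z_j)$, so the update
equals the expected-information step. The $\sigma^{-2}$ on the residual
outer product is essential: without it the fixed point is not the REML
stationary point of the $\sigma^2$-relative covariance unless
$\sigma^2 = 1$.

Three design choices matter for the optimiser's final accuracy, all
verified against the dense oracle below:

* **$\sigma^2$-profiled step.** Because $(\beta,\sigma^2)$ are re-profiled
  every iteration, the curvature relevant to the $D_k$ step is the Schur
  complement of the $\sigma^2$ row of the information. The step therefore
  uses $F^k - c_k c_k'/(n_v - p)$ with
  $c_k = \mathrm{vec}(\sum_j Z_j' P_V Z_j)$, a rank-one correction whose
  ingredients are already computed for the score. With the uncorrected
  $F^k$ the $\sigma^2$–$D$ alternation converges only linearly and stalls
  about three decades short of the optimum at any realistic tolerance.
* **Step halving between iterations.** $\alpha$ resets to 1 each iteration
  and is halved (at most 20 times, then the update is skipped and the voxel
  flagged) whenever the *end-of-iteration* restricted likelihood — i.e.
  after the next GLS update — would decrease. Judging the step at frozen
  $(\beta, \sigma^2)$ instead rejects every full profiled step and forces
  $\alpha = 1/2$ permanently.
* **Single-factor polish.** For one-factor models the converged interior
  optimum is refined by Newton root-finding on the profiled score (cheap in
  the block route), driving it to stationarity at machine precision. This
  reproduces the known accuracy ordering of the optimised single-factor
  paths versus the general multi-factor path; the general path remains pure
  profiled scoring.

Convergence is declared when the absolute change in restricted likelihood
between successive iterations falls below `tol` (default $10^{-6}$);
exceeding `maxnit` (default $10^4$) or an unrecoverable numerical failure
(Cholesky with one jitter retry of $10^{-10}\cdot\mathrm{tr}/q$) flags the
voxel, which never aborts its batch. Well-specified designs converge in
about 5–30 iterations. The GLS variance denominator is $n_v - p$ by default
(`sigma_denom = "reml"`), the value that maximises $\ell_R$ — confirmed by
the oracle tests; the $n_v$ ("ml") form is exposed for completeness.
Starting values are OLS for $\beta$, the residual mean square for
$\sigma^2$, and for each $D_k$ an isotropic method-of-moments value (the
variance of level-wise OLS residual means relative to $\sigma^2$, floored at
$10^{-6}$); the oracle-agreement tests are insensitive to this choice.

Degenerate and boundary behaviour: $r = 0$ routes to ordinary least squares
(the null model of the random-effect likelihood-ratio test); optima on the
cone boundary (singular $\widehat D_k$) are reached with the projection
active and are left unpolished. Projected scoring can, on boundary-heavy
small-sample voxels, settle on a different face of the cone than a global
search would — the same behaviour that makes multi-effect models agree with
reference implementations less tightly than single-effect ones.

## Inference

For a contrast $L$ the Wald statistics are
$T = L\hat\beta / \sqrt{\hat\sigma^2 L(X'\widehat V^{-1}X)^{-1}L'}$ and
$F = \hat\beta'L'[L(X'\widehat V^{-1}X)^{-1}L']^{-1}L\hat\beta /
(\hat\sigma^2\,\mathrm{rank}\,L)$, referred to $t$ and $F$ distributions
with Welch–Satterthwaite degrees of freedom
$\hat\nu = 2 (S^2)^2 / \widehat{\mathrm{Var}}(S^2)$,
$S^2 = \hat\sigma^2 L (X'\widehat V^{-1}X)^{-1}L'$. The variance of $S^2$
is the delta-method form $g'\,\mathrm{Var}(\hat\eta)\,g$ with $g = dS^2/d\eta$
in closed form and $\mathrm{Var}(\hat\eta)$ the inverse expected restricted
information of the variance parameters. Two conventions are deliberate:

* $\eta$ uses the *unique* elements of each $D_k$ (vech), not all $q_k^2$
  coordinates: the full-coordinate information is indefinite along
  antisymmetric directions (the likelihood sees only $ZDZ'$), while the
  vech information is the Fisher information of the identified
  parameterisation — the convention of the standard mixed-model testing
  packages. The assembly is validated against a dense trace-formula oracle
  ($\tfrac12\mathrm{tr}(P\dot\Sigma_u P\dot\Sigma_w)$ computed with dense
  matrices) and against the closed-form limit $\hat\nu = n_v - p$ when no
  random effects are present.
* Expected rather than observed information, consistent with the scoring
  machinery already computed; both are consistent estimators and expected
  information is the one available from product forms alone.

Multi-row contrasts pool per-direction degrees of freedom over an
orthogonal decomposition of $L(X'\widehat V^{-1}X)^{-1}L'$ (the
Fai–Cornelius construction used by lmerTest). T tests are two-sided by
default (configurable); both raw $p$ and $-\log_{10} p$ maps are written.
Multiple testing over the mask is Bonferroni (FWE) or Benjamini–Hochberg
(FDR).

Random-effect inclusion is tested by the likelihood-ratio statistic
$2(\ell_{\mathrm{full}} - \ell_{\mathrm{null}})$, clipped at zero (the
boundary null makes tiny negative values numerically possible; values below
$-10^{-6}$ are flagged), referred to an even mixture
$\tfrac12\chi^2_{q-\tilde q} + \tfrac12\chi^2_{q}$ where $q$ counts the
within-level random effects of the single factor and $\tilde q$ those
removed under the null ($\chi^2_0$ is a point mass at zero, so a zero
statistic has $p = 1$). A random-intercept test is thus a
$\chi^2_{0{:}1}$ mixture and an intercept-plus-slope versus intercept test a
$\chi^2_{1{:}2}$ mixture — the boundary-null convention for variance
components. The comparison requires single-factor models fit on identical
voxel sets and missingness; anything else is refused with an error.

## The dense oracle

Correctness of the product-form path rests on a deliberately independent
reference: `direct_reml()` evaluates $\ell_R$ with dense
$V = I + ZDZ'$, profiles $\beta$ and $\sigma^2$ analytically, and maximises
over a log-Cholesky parameterisation of each $D_k$ (feasible by
construction, no projections) with multi-start BFGS and a quadratic polish.
For single-variance models ($D = dI$) `direct_reml_1var()` uses one SVD of
$Z_v$ per missingness pattern, making each criterion evaluation $O(np)$ and
allowing whole-image cross-validation; its maximum is refined to near
machine precision by root-finding on a Richardson-extrapolated derivative.
The oracle shares no code with the scoring path beyond design construction.

## The synthetic-data generator

`simulate_design()` reproduces three canonical study designs at
$\beta = (4,3,2,1,0)'$, $\sigma^2 = 1$: (1) one factor, one effect, 100
levels; (2) one factor, two effects, 50 levels; (3) crossed factors of
2 effects × 20 levels and 1 effect × 10 levels. The fixed design is an
intercept plus four uniform $[-0.5, 0.5]$ regressors; the first random
effect is an intercept and additional effect regressors are uniform
$[-0.5, 0.5]$; covariance blocks have unit diagonal and 0.5 off-diagonal.
Level assignment is uniform *conditioned on every level receiving at least
$q_k$ observations* (pinned, order randomised): an unconstrained uniform
draw almost surely leaves some level with fewer, which makes the
within-level block of $Z'Z$ singular and would have the rank filter discard
every voxel of the two-effect design — the generator must respect the
pipeline's own well-posedness condition.

`simulate_images()` builds $Y_v = X\beta + Zb_v + \epsilon_v$ from
independent Gaussian fields, smooths each response image with a separable
isotropic Gaussian ($\sigma = \mathrm{FWHM}/2.3548$ voxels, truncated at
$4\sigma$, rows renormalised at the boundary so constants are preserved
exactly), and masks each image by a random perturbation of an ellipsoidal
base mask (~46% of the volume, standing in for a standard-space brain
mask). The perturbation adds a unit-variance smoothed Gaussian field, scaled
by an amplitude of 0.05, to the smoothed mask indicator and re-thresholds at
0.5; this flips only voxels in the edge band and was calibrated once so
roughly 5–15% of edge-band voxels drop per image. Because smoothing scales
the marginal variances of $b$ and $\epsilon$ by the same kernel factor
$c = \sum w^2 < 1$, the estimands $\beta$ and the $\sigma^2$-relative $D$
are untouched while $\hat\sigma^2$ concentrates near $c$ — the recovery
experiments therefore compare $\hat\beta$ and $\widehat D$ against the
generating values, and treat $\sigma^2$ only as a diagnostic. What the
generator does *not* emulate: physiological artefacts, spatially varying
smoothness, realistic mask anatomy, or any spatial structure in the
*parameters*; passing tests demonstrate numerical and statistical
correctness of the estimator under the stated model, not robustness to real
acquisition artefacts. The spatial correlation the smoothing induces is not
itself characterised, so recovery tests compare means across voxels and
instances rather than spatial covariances.

## Problem sizes used in validation

The full-scale study conditions (volumes of $100^3$ voxels, 1000 instances
per setting) are configuration, not code; the shipped experiments are
scaled down to sizes a single workstation handles comfortably while keeping
the designs' ratio structure: oracle agreement runs 10 instances of design
1 at $n = 200$ on a $16^3$ grid (about 19,000 voxel fits against the
spectral oracle at tolerance $10^{-10}$); recovery runs 25 instances of
designs 1 and 2 at $n = 200$ on $12^3$ grids; convergence medians use 3
instances per design on $10^3$ grids at $n = 150$. The measured
scoring-vs-oracle mean absolute difference for design 1 at these sizes sits
at the square-root-propagated double-precision level ($\approx 10^{-9}$ to
$10^{-8}$), and `scripts/acceptance.R` recomputes all of these quantities
from scratch.

## Known limitations

* Multi-factor (crossed) models use the dense $q \times q$ route; memory and
  time grow with $q^3$ per iteration, and final parameter accuracy carries
  the expected-information scoring tail (order $10^{-6}$–$10^{-5}$ at tight
  tolerance) rather than the single-factor machine-precision polish.
* Projected scoring does not perform constrained optimisation on the
  non-negative-definite cone's faces; boundary voxels can settle on
  face-local optima.
* Maximum-likelihood (non-restricted) estimation, structured covariance
  constraints, sparse backends and permutation inference are out of scope.
* The likelihood-ratio test covers single-factor nested pairs only, as the
  mixture reference distribution is derived for that case.
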