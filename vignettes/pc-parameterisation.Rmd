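---
title: "AI-REML for multivariate animal models: the principal-components parameterisation"
author: "pcreml"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AI-REML for multivariate animal models: the principal-components parameterisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcreml)
```

## The model

`pcreml` estimates genetic and residual covariance matrices for the
multivariate linear mixed ("animal") model over $q$ traits,

$$\mathbf{y} = \mathbf{X}\boldsymbol\beta + \mathbf{Z}\mathbf{u} + \mathbf{e},$$

with observations and genetic effects ordered traits within individuals.
Residuals are independent between animals with per-animal blocks equal to the
submatrix of $\boldsymbol\Sigma_e$ for the traits actually recorded, and
$\mathrm{Var}(\mathbf{u}) = \mathbf{H}\otimes\boldsymbol\Sigma_u$, where
$\mathbf{H}$ is a relationship matrix between individuals: the pedigree-based
numerator relationship matrix $\mathbf{A}$, or the joint ("single-step")
matrix combining pedigree and genomic information, whose inverse is
$\mathbf{H}^{-1} = \mathbf{A}^{-1} + \Delta$ with $\Delta$ nonzero only in the
genotyped block, where it equals $\mathbf{G}^{*-1} - \mathbf{A}_{22}^{-1}$.
Additional random terms (e.g. maternal genetic and maternal permanent
environmental effects) follow the same pattern, each with its own
relationship structure and $q\times q$ covariance matrix; direct and maternal
genetic effects are treated as uncorrelated but share the relationship
matrix.

Restricted maximum likelihood estimates are found with the
average-information (AI) algorithm: a damped Newton iteration on a working
parameter vector $\boldsymbol\theta$ holding the elements of the lower
Cholesky factors of all covariance matrices, with logarithms of the diagonal
elements.  This guarantees positive definite estimates at every iterate and
is the scale on which gradients and the AI matrix are formed.

## Two equivalent parameterisations

The coefficient matrix of the mixed model equations under the standard
multivariate (MV) parameterisation is

$$\mathbf{C} = \begin{bmatrix}
\mathbf{X}'\mathbf{R}^{-1}\mathbf{X} & \mathbf{X}'\mathbf{R}^{-1}\mathbf{Z}\\
\mathbf{Z}'\mathbf{R}^{-1}\mathbf{X} & \mathbf{Z}'\mathbf{R}^{-1}\mathbf{Z}
  + \mathbf{H}^{-1}\otimes\boldsymbol\Sigma_u^{-1}
\end{bmatrix}.$$

Every nonzero of $\mathbf{H}^{-1}$ contributes a dense $q\times q$ block.
With genomic information $\mathbf{H}^{-1}$ contains a dense block for the
genotyped animals, so this term dominates storage and, more importantly, the
cost of the REML first derivatives, which require the elements of
$\mathbf{C}^{-1}$ at all positions of
$\partial\mathbf{C}/\partial\theta_i = \mathbf{H}^{-1}\otimes
\partial\boldsymbol\Sigma_u^{-1}/\partial\theta_i$.

Rewriting the genetic effects as unit-variance principal-component scores
$\mathbf{u}^\star = (\mathbf{I}\otimes\mathbf{Q}^{-1})\mathbf{u}$ with
$\mathbf{Q}\mathbf{Q}' = \boldsymbol\Sigma_u$ gives an equivalent model whose
design matrix $\mathbf{Z}^\star = \mathbf{Z}(\mathbf{I}\otimes\mathbf{Q})$
carries the trait covariances, while the relationship part of the
coefficient matrix collapses to $\mathbf{H}^{-1}\otimes\mathbf{I}_q$: each
off-diagonal element of $\mathbf{H}^{-1}$ now contributes $q$ rather than
$q^2$ nonzeros, and — decisively — this part no longer depends on the
parameters, so the derivatives of $\mathbf{C}^\star$ with respect to the
genetic parameters touch only the data part, which is block-diagonal for
animals.  `pcreml` takes $\mathbf{Q}$ as the lower Cholesky factor of
$\boldsymbol\Sigma_u$ (rather than the eigenvector form
$\mathbf{E}\boldsymbol\Lambda^{1/2}$): it has $q(q+1)/2$ nonzeros and is
exactly the quantity parameterised by $\boldsymbol\theta$, so the two
parameterisations share one working parameter vector.

Both parameterisations are implemented end to end (`param = "mv"` /
`param = "pc"` in `reml_fit()`).  Because the likelihoods are the same
function of $\boldsymbol\theta$ — analytically,
$\log|\mathbf{C}^\star| = \log|\mathbf{C}| + N\log|\boldsymbol\Sigma_u|$, the
exact term by which the explicit $N\log|\boldsymbol\Sigma_u|$ contribution
differs — gradients and AI matrices coincide, the Newton paths coincide, and
the estimates coincide.  The test suite asserts this literally: identical
$-2\log\mathcal{L}$ at matched parameters, identical likelihood changes in
each AI iterate, and identical converged estimates, across pedigree-only and
single-step data sets.

## Likelihood, derivatives, and the sparse machinery

On the MME scale, dropping the constant,

$$-2\log\mathcal{L} = \log|\mathbf{R}| + q\log|\mathbf{H}| +
  N\log|\boldsymbol\Sigma_u| + \log|\mathbf{C}| + \mathbf{y}'\mathbf{P}\mathbf{y},$$

with $\mathbf{y}'\mathbf{P}\mathbf{y} = \mathbf{y}'\mathbf{R}^{-1}\mathbf{y}
- \mathbf{b}'\hat{\mathbf{x}}$ from the right-hand side and solution of the
MME (under PC the $N\log|\boldsymbol\Sigma_u|$ term is absorbed into
$\log|\mathbf{C}^\star|$).  First derivatives combine
$\mathrm{tr}(\mathbf{R}^{-1}\partial\mathbf{R})$,
$N\,\mathrm{tr}(\boldsymbol\Sigma_u^{-1}\partial\boldsymbol\Sigma_u)$,
$\mathrm{tr}(\mathbf{C}^{-1}\partial\mathbf{C})$ and the derivative of the
data quadratic, which is evaluated through the solution vector and working
residual $\mathbf{t} = \mathbf{R}^{-1}(\mathbf{y}-\mathbf{W}\hat{\mathbf{x}})$
without ever forming $\mathbf{P}$.  The AI matrix is
$\tfrac12\,\mathbf{f}_i'\mathbf{P}\mathbf{f}_j$ with working vectors
$\mathbf{f}_i = (\partial\mathbf{V}/\partial\theta_i)\mathbf{P}\mathbf{y}$;
each product $\mathbf{P}\mathbf{f}$ costs one extra solve on the current
factorisation.

The sparse side uses CHOLMOD (via the Matrix package) for the fill-reducing
ordering, symbolic and numeric Cholesky factorisation and solves.  The trace
terms need selected elements of $\mathbf{C}^{-1}$; these are computed by a
Takahashi-type backward recursion over the factor pattern, implemented in
compiled code, which yields $\mathbf{C}^{-1}$ exactly at all positions of the
factor (and hence of $\mathbf{C}$) without forming the full inverse.  To
make this sound, the coefficient matrix is assembled on a *structural*
pattern: positions that can be nonzero for some parameter value are kept as
explicit zeros, so the pattern of every $\partial\mathbf{C}/\partial\theta_i$
is always contained in the factorised pattern.  A position outside the
pattern raises an error rather than being silently treated as zero.

Derivative bookkeeping is organised over groups of records sharing a design
signature (missing-trait pattern, fixed-effect pattern, term presence): all
records in a group share one small coefficient template, so per-parameter
trace contributions reduce to one gathered $\mathbf{C}^{-1}$ block sum per
group — the data-part computations are independent of the density of
$\mathbf{H}^{-1}$, which is precisely the PC advantage for the genetic
parameters.

## Relationship matrices

* `build_A_inverse()` applies Henderson's rules with exact inbreeding from
  the Meuwissen–Luo recursion (the dense-oracle equivalence tests require
  exactness; an inbreeding-ignorant approximation would fail them).
* `build_A22()` extracts the genotyped submatrix of $\mathbf{A}$ via sparse
  solves with $\mathbf{A}^{-1}$ (one solve per genotyped animal), never
  forming dense $\mathbf{A}$.
* `build_grm()` is VanRaden Method 1, $\mathbf{G} = \mathbf{M}\mathbf{M}'/
  (2\sum_i p_i(1-p_i))$, with counts centred by twice the observed allele
  frequency.  Frequencies are computed on all SNPs first; SNPs with minor
  allele frequency strictly below 2% (default) are then excluded from both
  $\mathbf{M}$ and the denominator.  A SNP at exactly the threshold is
  retained.  Missing genotype calls are rejected rather than imputed.
* `align_grm()` rescales $\mathbf{G}^* = a + b\,\mathbf{G}$ so that the mean
  diagonal and overall mean match those of $\mathbf{A}_{22}$ (two moment
  conditions, solved exactly).
* `build_H_inverse()` assembles $\mathbf{A}^{-1} + \Delta$; if $\mathbf{G}^*$
  fails its Cholesky it is blended once, $\mathbf{G}^* \leftarrow
  0.99\,\mathbf{G}^* + 0.01\,\mathbf{A}_{22}$ (weight configurable), the
  usual single-step conditioning convention.  No further scaling of the
  genotyped block is applied.

## Tuning parameters

| parameter | default | meaning |
|---|---|---|
| `maf_min` | 0.02 | minimum minor allele frequency retained in the GRM |
| `blend` | 0.01 | $\mathbf{A}_{22}$ weight if $\mathbf{G}^*$ is not PD |
| `maxit` | 50 | maximum AI-REML iterates |
| `tol_L` | 5e-4 | convergence threshold on the change in $-2\log\mathcal{L}$ |
| `tol_g` | 1e-3 | convergence threshold on the largest gradient element |
| `start` | data-driven | $\boldsymbol\Sigma_e = \tfrac12 \hat{\mathbf{P}}_y$, random terms split the other half, where $\hat{\mathbf{P}}_y$ is the pairwise-complete phenotypic covariance (eigenvalue-floored to be PD) |

The step factor $\omega$ starts at 1 each iterate and is halved (at most 10
times) until $-2\log\mathcal{L}$ does not deteriorate; convergence requires
both a small likelihood change and a small gradient.  A numerically singular
AI matrix triggers a scaled gradient step for that iterate.  Step halving
costs extra likelihood evaluations; a production run near the optimum
typically accepts the full Newton step, giving one evaluation per iterate.

## The synthetic-data generator

`simulate_pedigree()`, `simulate_genotypes()` and `simulate_phenotypes()`
emulate a generation-structured livestock population: discrete generations,
each progeny with a sire and dam drawn from designated parents of the
previous generation; unlinked gene-dropped SNPs with founder allele
frequencies uniform on (0.05, 0.95); infinitesimal breeding values built
generation-recursively (founder draws from
$N(\mathbf{0},\boldsymbol\Sigma_u)$ plus within-family Mendelian deviations
with variance $\tfrac12\boldsymbol\Sigma_u$ by default — the exact
$(\tfrac12 - \tfrac14(F_s+F_d))$ scaling is available via
`exact_mendelian = TRUE`); iid residuals; iid normal contemporary-group
effects within generation; per-generation genotyping proportions and
per-trait missing-record rates.  The `"dataset1"` preset reproduces the
structure of a simulated data set of 21,000 recorded animals in eight
generations (2,100/3,150 progeny of 100/150 sires and 1,000/1,500 dams, 301
contemporary groups per generation, 32,000 SNPs, genotyping proportions
0/0/0/0/10/30/40/50%).

What the generator does *not* emulate: linkage and LD structure (loci are
unlinked, so genomic relationships are noisier at a given SNP count than on
a real genome), selection (matings are random, so no Bulmer effect or
genetic trend), mutation, genotyping error, and trait architectures with
few QTL.  Passing tests therefore demonstrate correctness of the estimation
machinery under the stated model — not robustness to model violations found
in field data.

Default trait values, chosen once as typical for production traits:
heritability 0.3 per trait with unit phenotypic variance, genetic
correlations $0.5^{|i-j|}$, residual correlations $0.3^{|i-j|}$,
contemporary-group standard deviation 0.5.

## Verification design

Every layer has an independent dense oracle: the tabular (recursive)
$\mathbf{A}$ against Henderson's rules; the conditional-distribution
construction of dense $\mathbf{H}$ against the sparse
$\mathbf{H}^{-1}$ assembly; dense inversion against the Takahashi subset;
and the $\mathbf{V}$/$\mathbf{P}$-form of the REML likelihood, a
finite-difference gradient, and the dense AI formula against the sparse MME
path.  These agree to near machine precision on instances up to a few
hundred equations.  Parameter recovery is checked by simulation: across
replicated synthetic data sets (about 2,000 recorded animals, two traits,
alternating pedigree-only and single-step), mean estimates of every
covariance element fall within two Monte-Carlo standard errors of the
generating values.

Equivalence of the two parameterisations is exercised on ten data sets
covering one to five traits, two sample sizes (roughly 200 and 2,000
records) and both relationship types.  The trait count is paired with the
sample size — up to two traits at the small size, three and five traits at
the large size — because a 3+-trait genetic covariance at 200 records with
heritability 0.3 frequently has its REML maximum on the boundary of the
parameter space (smallest genetic eigenvalue at zero), where "converged
estimates" are not defined; the likelihood-value and per-iterate-change
equivalences hold there regardless, and are asserted on every data set.
Family structure in the small design (20 sires, 60 dams per generation) was
likewise chosen so the genetic covariance is identified.

## Numerical choices and degenerate inputs

* Equation ordering: fixed effects first, then random terms, with traits
  (or components) within individual, keeping each Kronecker block
  contiguous.
* Identifiability: within each trait the first fixed factor keeps all
  levels; each later factor drops its first level.
* Positive-pivot failures during factorisation report the offending
  equation via the equation map (dense refactorisation is used to locate
  the pivot on systems small enough to densify).
* Ordering ties inside CHOLMOD are deterministic for a fixed input, and
  the structure reports of the command-line interface are byte-identical
  across runs with the same seed.
* Records with every trait missing are dropped at design time with a
  message; records with a missing factor level for an observed trait simply
  contribute no entry for that factor.
* Pedigrees may arrive in any order (a topological sort is applied);
  cycles and unknown parent identifiers are structural errors naming the
  animal involved.

## Problem sizes

The shipped tests and the acceptance script run the full machinery at up to
about 10,000 equations (2,000+ animals, five traits) and verify oracles on
instances up to 500 equations; these sizes exercise every code path —
including the dense genotyped block of single-step models — while keeping a
complete run in minutes on one core.  The same code drives larger problems
unchanged; per-iterate cost is then dominated by the sparse factorisation
and, under MV with genomic data, by the $\mathbf{H}^{-1}$-pattern trace
terms that the PC parameterisation avoids.

## Known limitations

Full-rank estimation only (no reduced-rank/factor-analytic fits); no
genetic groups or metafounders; no heterogeneous residual variances by
class; single records per trait per animal; missing genotype calls must be
handled upstream; timings are reported for information but never asserted —
relative costs of the two parameterisations are highly
implementation-specific, and this implementation's per-iterate profile is
dominated by R-level assembly at the shipped problem sizes.
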