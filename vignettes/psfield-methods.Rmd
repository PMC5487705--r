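---
title: "Methods: anisotropic 2D P-spline analysis of field trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anisotropic 2D P-spline analysis of field trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its statistical machinery: the
model and its assumptions, the numerical choices, what the simulator does and
does not emulate, and the design decisions taken where more than one
reasonable construction exists.  It states no empirical result that the test
suite or the acceptance script does not itself compute.

## 1. Model and assumptions

A single trial is a rectangular grid of plots with integer coordinates
$(r, c)$.  The phenotype model is

$$y = X\beta + X_s\beta_s + Z_s s + Z_r u_r + Z_c u_c + Z_g g + e,$$

with fixed intercept, check-variety and resolvable-block effects in $X\beta$;
a smooth spatial surface $f(r,c) = X_s\beta_s + Z_s s$; independent random
row and column effects; independent random genotype effects
$g \sim N(0, \sigma^2_g I)$ for the *test* entries (checks are fixed); and an
i.i.d. nugget $e \sim N(0, \sigma^2_e I)$.  Assumptions worth stating
explicitly: genotype effects are exchangeable (no pedigree or marker
relationship matrix), the surface is continuous across the whole field
(blocks shift the mean but do not break the surface), and missing plots are
ignorable for the likelihood.

### PS-ANOVA surface

Each coordinate gets a cubic B-spline basis on equally spaced knots.  "$n$
knots" means $n$ equally spaced knots spanning the coordinate range with the
endpoints included — $n-1$ segments and $n-1+\mathrm{degree}$ basis
functions.  This is the only reading under which 31 and 11 knots with cubic
splines and second-order penalties give exactly
$31+11+31+11+341 = 425$ penalized surface parameters, which a structural test
asserts.  Boundary handling is the standard equidistant extension by `degree`
extra knots per side, not clamped knots.

The order-2 difference penalty $D^\top D$ is eigendecomposed; the
two-dimensional null space (constant + linear) moves to the fixed part, and
the penalized part is rotated onto the eigenvectors with positive eigenvalue,
leaving a *diagonal* precision $\Lambda_+$ per direction.  We keep
$\Lambda_+$ as-is rather than rescaling to identity.  The five random surface
blocks are then: $Z_r$, $Z_c$, $Z_r$ scaled by the centered column covariate,
the centered row covariate times $Z_c$, and the row-wise Khatri–Rao product
$Z_r \odot Z_c$.  Their diagonal precisions are $\Lambda_{r+}$,
$\Lambda_{c+}$, $\Lambda_{r+}$, $\Lambda_{c+}$, and the Kronecker sum
$\Lambda_{r+} \otimes I + I \otimes \Lambda_{c+}$.  The Kronecker-sum choice
for the interaction block is a design decision (the PS-ANOVA construction),
not something the trial-analysis literature pins down uniquely; a rank test
verifies that the decomposition plus intercept spans exactly the full
tensor-product basis, so no surface is lost or invented.

Covariates entering $X_s$ are centered at the grid midpoint and scaled to
unit half-range.  The fit is invariant to this affine choice; to make the
invariance hold for the reported deviance too, the restricted likelihood is
normalized by $-\log|X^\top X|$ (a variance-independent constant; the
textbook form shifts by $2\log|\det T|$ under $X \to XT$).

### Default knot rule

"About one knot per two rows or columns": `floor(n/2) + 1` equally spaced
knots, capped at `n`.  This gives 39 knots for 77 rows, 11 for 20 columns,
and 31/11 at the 60 × 20 scale used in the recovery suite.  Knot counts are
deliberately generous; a test verifies that doubling them changes the fitted
surface by less than 5% relative RMS, so optimizing them is not worthwhile.

## 2. REML by effective-dimension fixed point

Smoothing parameters are variance ratios
$\lambda_k = \sigma^2_e/\sigma^2_k$, estimated by REML with Schall/Harville
fixed-point updates: solve the mixed-model equations at the current
components, then

$$\sigma^2_k \leftarrow \frac{\tilde u_k^\top P_k \tilde u_k}{ED_k},
\qquad
\sigma^2_e \leftarrow \frac{\hat e^\top \hat e}{n - ED_\beta - \sum_k ED_k},
\qquad
ED_k = q_k - \lambda_k\,\mathrm{tr}(P_k C^{kk}),$$

where $C^{kk}$ is block $k$ of the inverse coefficient matrix.  A dense
hat-matrix oracle and a brute-force restricted-likelihood grid search verify,
on small instances, that the EDs are hat-matrix traces and that the fixed
point is the REML optimum.

**Numerical choices.**

* *Initialization*: every component starts at $\mathrm{var}(y)/(K+1)$ for
  $K$ random blocks.
* *Floor*: components are floored at $10^{-10}\,\mathrm{var}(y)$; a floored
  component reports ED 0 and its $\lambda$ as `NA`.
* *Degenerate components*: when a component's ED falls below $10^{-3}$ and
  keeps shrinking for three iterations it is snapped to the floor.  Without
  this, a vanishing component's ED decays geometrically (observed ratios
  ≈ 0.998/iteration) along a direction in which the deviance is flat to
  machine precision, stalling the iteration for thousands of rounds with no
  change in the fit.
* *Convergence*: maximum relative change over all EDs **and** relative
  deviance change below the tolerance (default $10^{-8}$), **or** five
  consecutive iterations with the deviance change below tolerance.  The
  plateau clause exists for the same flat-ridge reason; on such a ridge the
  ED-only criterion is ill-posed while the likelihood is converged.  This is
  a deliberate deviation from a pure ED criterion and is recorded as such.
* *Linear algebra*: one dense Cholesky of the coefficient matrix per
  iteration, with the genotype block (diagonal cross-product, often ~1000
  columns) absorbed via its Schur complement; all traces are exact, no
  stochastic estimators.
* *Aliasing*: rank-deficient fixed parts are repaired by pivoted QR with the
  dropped columns reported.

Non-convergence within `max_iter` yields a flagged result with the full
iteration trace, never an exception.

## 3. Heritability

$H^2 = ED_g/(n_g - l)$ with $n_g$ the number of test genotypes carrying at
least one observed plot.  The headline value uses $l = 0$, under which it is
*algebraically identical* to the Cullis/Welham form
$1 - \overline{\mathrm{PEV}}/\sigma^2_g$ for independent genotype effects —
the suite checks agreement to $10^{-6}$ on every converged fit.  Whether the
reference analyses used $l = 0$ or a computed $l$ is not stated anywhere we
could verify, so both are reported: `heritability()` also counts the zero
eigenvalues of the genotype hat matrix (cutoff $10^{-10}\times$ the largest
eigenvalue) when `compute_l = TRUE`.  PEV$_i$ is $\sigma^2_e$ times the
genotype-block diagonal of the inverse coefficient matrix, averaged over test
genotypes only.

## 4. What the simulator emulates — and what it does not

`sim_params()` defaults describe a large early-generation sorghum-style
trial: 55 × 28 grid (1540 plots), 1136 test genotypes with 30% duplicated,
two resolvable blocks formed by the row-wise halves of the field, ten check
varieties filling the remaining plots, 10% of plots missing completely at
random (real trials ranged 3–29%), grain-yield-like scale (mean 4 t/ha,
$\sigma^2_g = \sigma^2_e = 0.2$, i.e. single-plot heritability 0.5 before
trend), and a smooth trend whose range equals the nugget SD.  Where no value
was stated anywhere, the choice is made once here: block shift 0.2 t/ha,
row/column effect variances 0.05, check offsets equally spaced across ±1
genetic SD.

Deliberate simplifications: replicate placement is *constrained
randomization* (once per half), not the optimal-design search used for real
p-rep layouts — no analysis code depends on placement optimality; blocks are
row-wise halves (orientation is a parameter); missingness is completely at
random; there is no multi-trait or multi-environment genetic structure beyond
the bivariate generator used to test the between-environment correlation
metric.  An AR1×AR1 Gaussian field (`ar1_field()`) is provided as a *data
generator only* — the package never fits autoregressive residuals.
Consequently, a green recovery test establishes that the estimator recovers
the generating components under smooth trends plus i.i.d. noise; it does not
establish performance under spatially correlated nuggets, non-ignorable
missingness, or adversarial layouts.

One stated-world correction: the recovery suite's nominal "60 × 20 grid with
1000 genotypes at $p=0.30$" is arithmetically infeasible (1300 test plots on
a 1200-plot grid), so 880 genotypes are used with everything else unchanged.

## 5. Known limitations

* Only order-2 penalties are exercised against reference settings; other
  orders run but are untested beyond basic properties.
* Variance components come without standard errors.
* The surface is continuous across blocks; a per-block surface is not
  offered.
* Genotype relationship matrices (pedigree/markers) are out of scope, as is
  AR1×AR1 *fitting* and any sequential spatial model search.
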