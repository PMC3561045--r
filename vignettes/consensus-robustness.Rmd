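---
title: "Consensus robustness of nearest-neighbour flock networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus robustness of nearest-neighbour flock networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(flocknet)
```

## The model

A flock of $N$ birds tries to maintain consensus on a scalar state $x_i$
(for example a component of the heading direction). Each bird senses only
its $m$ nearest neighbours, and all sensed information is corrupted by
noise. The package analyses the linear noisy consensus dynamics

$$\dot x = -L x + \nu\,\xi,$$

where $\xi$ is standard white noise of intensity $\nu$ and $L$ is the
graph Laplacian of the **directed sensing graph**: an edge $i \to j$ means
"bird $i$ senses bird $j$". Row $i$ of $-L$ averages bird $i$'s state
toward its $m$ nearest neighbours with weights $a_{ij} \ge 0$. Weights
are normalised so that each bird's total attention
$\sum_j a_{ij} = 1$; this makes results comparable across $m$ and
weighting schemes, because adding neighbours redistributes a fixed
attention budget instead of adding control effort.

Consensus itself (the direction the flock settles on) is unobservable to
this analysis; what matters is the **disagreement**, the component of $x$
orthogonal to the consensus line $\mathrm{span}(\mathbf{1})$. Writing
$y = Qx$ with $Q$ an $(N-1)\times N$ matrix of orthonormal rows all
orthogonal to $\mathbf{1}$, the disagreement obeys
$\dot y = -\bar L y + \nu Q\xi$ with reduced Laplacian
$\bar L = Q L Q^\top$.

### The robustness metric

If $-\bar L$ is Hurwitz, the disagreement reaches a stationary
distribution whose total variance is the squared $H_2$ norm of the
reduced system. It is obtained from the Lyapunov equation

$$\bar L \Sigma + \Sigma \bar L^\top = I, \qquad
  \lVert H \rVert_2^2 = \nu^2\,\mathrm{tr}\,\Sigma .$$

The package reports:

* `nodal_disagreement` $= \nu\sqrt{\mathrm{tr}\,\Sigma}/\sqrt N$ — the
  root-mean-square per-bird deviation from consensus;
* `nodal_robustness` $= \sqrt N / (\nu\sqrt{\mathrm{tr}\,\Sigma})$ — its
  reciprocal, so larger is better; defined as exactly `0` when consensus
  is infeasible;
* `robustness_per_neighbor` — nodal robustness divided by $m$, the
  benefit per unit of sensing cost. Its maximiser over $m$ is `m_star`,
  and the `band_90` interval collects all $m$ whose value is within 90%
  of the peak;
* `convergence_speed` — the smallest real part of the eigenvalues of
  $\bar L$, normalised by $N/(N-1)$ so the all-to-all equal-weight
  network scores exactly 1.

Two closed forms anchor the implementation and are verified in the test
suite: the equal-weight complete graph has nodal robustness
$\sqrt 2\, N/(N-1)$ and normalised speed exactly 1, and the 6-cycle with
half weights on both ring neighbours has
$\mathrm{tr}\,\Sigma = 35/12$.

### Feasibility

Noise makes exact consensus impossible, but *bounded* disagreement
requires that $-\bar L$ be Hurwitz. This holds if and only if the
condensation of the sensing graph into strongly connected components has
exactly one sink — intuitively, one group of mutually-informed birds that
everyone else (directly or indirectly) listens to. The package uses this
combinatorial test (`is_consensus_feasible()`, via **igraph**) in hot
loops because it is much cheaper than an eigendecomposition, and exposes
the spectral test (`is_hurwitz_stable()`) independently; their agreement
is property-tested on random digraphs rather than assumed.

## Flock geometry

Flock shape is summarised by the equivalent inertia ellipsoid: the
eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$ of the position
covariance (computed with $1/N$ normalisation and equal mass per bird)
give semi-axes $\sqrt{5\lambda_i}$ — those of the uniform solid
ellipsoid with the same second moments. Only ratios are reported:
**thickness** $= \sqrt{\lambda_3/\lambda_1}$ and
**width** $= \sqrt{\lambda_2/\lambda_1}$, both in $[0,1]$ and invariant
to rotation, translation and scale.

One known limitation: thickness is a ratio of *sorted sample*
eigenvalues. When the population eigenvalues are nearly tied (thickness
target near 1), sorting biases the largest sample eigenvalue up and the
smallest down, so the recovered thickness of a generated flock is biased
below its target — about $-0.05$ at target 1.0 with $n = 1200$ birds,
and about $-0.02$ at target 0.9 (measured in the acceptance suite). For
targets $\le 0.8$ the bias is within $\pm 0.02$. This is a property of
the estimator, not a bug; users comparing near-isotropic flocks should
expect it.

## Synthetic flock generators

`generate_flock()` fills an axis-aligned box $(L_x \ge L_y \ge L_z)$
with points; `box_for_thickness(t, width_ratio)` picks the box
$(1, w, t)$ whose uniform fill has the requested thickness ratio, since
a uniform side $s$ contributes variance $s^2/12$. Three distributions
span a disorder axis:

* **`uniform`** — independent uniform draws; the most disordered.
* **`halton`** — a quasi-random low-discrepancy sequence (radical
  inverses in bases 2, 3, 5); more even than uniform.
* **`perturbed_grid`** — a regular lattice (counts per axis proportional
  to box sides) with Gaussian jitter of standard deviation
  `grid_noise_sd` × the geometric-mean lattice spacing; the most
  ordered at small noise.

These emulate only the *positional statistics* of flocks of controlled
shape and ordering. They do not emulate motion, alignment, density
gradients from border effects, or any behavioural rule — positions are a
static snapshot, which is all the $H_2$ analysis consumes.

Defaults and their rationale:

* `n_birds = 1200`: a mid-sized flock, large enough for stable shape
  statistics while keeping dense-Laplacian Lyapunov solves tractable.
* `grid_noise_sd = 0.3`: large enough that the perturbed grid is not a
  degenerate lattice (which would produce pathological tied nearest
  neighbours) yet still measurably more ordered than uniform. At 0.3 the
  nearest-neighbour-distance coefficient of variation sits close to
  Halton's; the strict ordering perturbed grid < Halton < uniform holds
  clearly at small noise (≈ 0.1), which is how the test suite checks it.
* `width_ratio = 1` (square cross-section): sweeps in this package vary
  thickness only; width is exposed for sensitivity runs but held fixed
  by default because the robustness results are driven by the smallest
  dimension.
* Halton replicate decorrelation uses a seed-keyed Cranley–Patterson
  rotation (a uniform shift of each coordinate modulo 1), which
  preserves the low-discrepancy structure while making replicates
  distinct. Digit scrambling would serve the same purpose; the rotation
  was chosen for simplicity and exact reproducibility.
* Replicate $i$ of an ensemble uses seed `seed + i`, so ensembles are
  reproducible and extendable without re-generating earlier replicates.
  Generation never disturbs the session RNG (`withr::with_seed`).

## Weighting schemes

Three ways to split the unit attention budget across the $m$ neighbours:

* `equal` — $1/m$ each;
* `inverse_distance` — proportional to $1/d_{ij}$, normalised;
* `order_linear` — decaying linearly in neighbour rank,
  $a_{(k)} \propto m + 1 - k$.

Equal weighting is the default; on uniform synthetic flocks it yields
the highest mean robustness of the three (this ordering is computed in
the acceptance suite, not assumed).

## Numerical choices

* **Lyapunov solves** use LAPACK's Bartels–Stewart algorithm via
  `arma::sylvester` (RcppArmadillo) on the dense $(N-1)$-dimensional
  reduced Laplacian; the solution is symmetrised and its residual
  checked (relative residual above $10^{-6}$ raises an error rather than
  returning a silently wrong trace).
* **The projector $Q$** is built from the Householder reflection mapping
  $e_1$ to $\mathbf 1/\sqrt N$; rows 2..$N$ of the reflector form $Q$.
  This is deterministic and exactly orthonormal. The $H_2$ value is
  invariant to which orthonormal completion is used; the test suite
  checks this against an independent QR-based completion.
* **Nearest neighbours** are found by brute-force distance computation
  with ties broken by ascending bird index, which makes neighbour sets
  for smaller $m$ exact prefixes of the ordering for larger $m$;
  `robustness_curve()` exploits this to do one neighbour search per
  flock. Coincident positions are rejected (nearest neighbours would be
  ill-defined).
* **Eigenvalues** of the 3×3 covariance and of $\bar L$ use base R's
  LAPACK-backed `eigen()`; stability tolerance is relative
  ($10^{-9}$ × spectral radius).

## Open design decisions and limitations

* The disorder axis is one-dimensional here (three generators); real
  flocks mix density gradients, anisotropic ordering and motion.
* Scalar dynamics per bird: the analysis treats each spatial component
  independently, which is exact for the linear model but ignores any
  coupling between components.
* The noise intensity $\nu$ only rescales robustness
  ($\propto 1/\nu$); all comparative results are $\nu$-independent.
* Ensemble experiments at reduced scale ($n = 300$ birds, 20 replicates)
  are used throughout the test and acceptance machinery to stay within
  desktop runtimes; the full-scale defaults ($n = 1200$, 100 replicates)
  are available to users with more time.
* Dense linear algebra limits practical flock sizes to a few thousand
  birds per Lyapunov solve; sparse iterative methods are out of scope.
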