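---
title: "Fidelity augmentation of coarse-mesh drug-transport simulations"
author: "meshlift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fidelity augmentation of coarse-mesh drug-transport simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-fidelity finite-element simulation of endovascular drug delivery is
expensive: resolving arterial drug transport on a finely refined mesh
costs orders of magnitude more than a coarse solve, yet the coarse solve
already contains most of the information. `meshlift` implements a
fidelity-augmentation framework around a concrete physiological model —
drug transfer from an inflated drug-coated balloon into the arterial
wall — in which a supervised learner is trained to map coarse-mesh
solutions to refined-mesh solutions, so that refined-quality fields can
be estimated at a fraction of the cost of solving on the refined mesh.

The package has two halves:

* a **physics side**: a P1 finite-element solver for transient
  free/bound drug transport in an annular arterial cross-section, on a
  hierarchy of nested, longest-edge-bisected triangular meshes;
* a **learning side**: an ordinary-Kriging (Gaussian-process) surrogate
  with product power-exponential correlation, fitted by concentrated
  maximum likelihood via the DIRECT global optimizer on
  nearest-neighbour features of the coarse solution, evaluated by
  k-fold, shuffled cross-validation and by RMSE references between
  refinement levels.

## The transport model

The tissue occupies the annulus $R \le r \le R + W$ with lumen radius
$R = 3\,$mm and wall thickness $W = 0.5\,$mm. Free drug $C$ and bound
drug $B$ (both mol m$^{-3}$; numerically equal to mmol l$^{-1}$) obey

$$\frac{\partial C}{\partial t} = D_w \nabla^2 C
  - k_a C (B_M - B) + k_d B, \qquad
  \frac{\partial B}{\partial t} = k_a C (B_M - B) - k_d B,$$

reversible saturable binding to tissue sites of capacity $B_M$; bound
drug does not diffuse. Defaults are the zotarolimus values:
$D_w = 1.712\times10^{-11}$ m$^2$s$^{-1}$, $B_M = 0.356$ mol m$^{-3}$,
Damköhler number $Da = 5\times10^{4}$, equilibrium dissociation constant
$K_d = 0.0326$ mol m$^{-3}$, with the rates derived as
$k_a = D_w Da/(B_M W^2)$ and $k_d = k_a K_d$. Boundary conditions: a
perfect sink ($C = 0$) on the perivascular (outer) circle, zero flux for
$B$ everywhere, and a transient release flux on the mural (inner)
circle while the balloon is inflated ($t \le t_0 = 30$ s):

$$J_b(t) = \frac{A_1 k_1 \delta_c}{Z_{MW}}\, e^{-k_1 t},$$

with release-kinetics constants $A_1 = 23.95$ kg m$^{-3}$,
$k_1 = 0.009208$ s$^{-1}$, molecular weight $Z_{MW} = 966.21$ g
mol$^{-1}$. The unit analysis of these constants requires a geometric
factor with dimension of length — the balloon coating volume per unit
surface area $\delta_c$ — which we expose as `coatingThickness` with a
default of 10&nbsp;µm, a typical coating thickness for this device
class. The closed-form integral of $J_b$
(`balloonReleasedMass`) is used as an internal oracle for the flux
implementation and for exact mass accounting. Fields are extracted at
1&nbsp;h after the onset of inflation.

Discretization is P1 triangles with a lumped mass matrix; time
integration is the variable-order (1–5), variable-step BDF method of
`deSolve::lsodes` with user-supplied Jacobian sparsity, at relative and
absolute tolerances of $10^{-9}$ and $10^{-6}$. Reaction terms are
integrated implicitly together with diffusion (no operator splitting),
and negative concentrations are never clipped — negativity beyond
tolerance is a test failure, not something to mask. A discrete mass
balance (tissue content vs cumulative mural influx minus perivascular
outflow) holds to about $10^{-5}$ relative on the default problem and
is asserted at 0.1%.

## Meshing and refinement

No triangulation library is assumed: `buildAnnulusMesh` generates rings
of nodes criss-cross triangulated into the annulus, with two sources of
seed-deterministic size variability — random radial layer thicknesses
and per-node jitter — so the element sizes vary by a factor of several,
spatially uncorrelated with position, as in a generic Delaunay mesh of
the kind the reference simulations used. This variability matters
scientifically, not just cosmetically: the surrogate's distance
features carry information only when the training mesh exhibits
element-size variation. Two designs were tried and rejected during
development: a perfectly uniform structured mesh (distance features
become constants, so the learned map cannot adapt the correction scale
when deployed on a denser mesh) and a radially graded mesh (element
size then correlates with solution curvature, so size and curvature
effects are confounded and the learned relation inverts under
refinement). Boundary nodes are never jittered off their circles.

`refineLongestEdge` bisects the longest edge of every element, with
Rivara-style closure bisections until the mesh is conforming. Ties
between equal-length edges break lexicographically by node indices, so
builds are deterministic. All parent nodes persist at identical
coordinates and indices — node sets are *nested* across levels, which
makes every cross-level comparison in the package exact (interpolation
free). New midpoints on a curved boundary edge are projected to the
exact circle by default (`project = TRUE`), which stops the geometric
error of the polygonal boundary from compounding across levels; with
`project = FALSE` the piecewise-linear boundary, and hence the total
mesh area, is preserved to machine precision. Empirically the minimum
element angle after three refinements stays above half the level-0
minimum, the known quality bound for longest-edge bisection.

## Features and the surrogate

For each node, the feature vector of length $q = 2J+1$ is
$[d_{i1}, \dots, d_{iJ},\; y^0(x_{j_1}), \dots, y^0(x_{jJ}),\;
y^0(x_i)]$: the $J$ nearest-neighbour distances sorted ascending, the
coarse solution at those neighbours, and the coarse solution at the
node itself. Supported metrics are cityblock (L1, in the Cartesian
frame of mesh generation), Euclidean, and Mahalanobis (coordinates
whitened by their 2×2 sample covariance). A node is never its own
neighbour. Distances are in raw metres and solution features in raw
mol m$^{-3}$; an optional standardization switch (off by default)
z-scores the distance block.

The surrogate is ordinary Kriging with constant trend $\beta$ and

$$R(x, x') = \prod_{j=1}^{q} \exp(-\theta_j |x_j - x'_j|^{p_j}),
  \qquad p_j = 2,$$

so the modelled function is smooth. $\beta$ and the process variance
$\sigma_z^2$ are profiled out in closed form, and the concentrated
negative log-likelihood
$\tfrac{l}{2}\log\hat\sigma^2(\theta) + \tfrac12 \log\det R(\theta)$
is minimized over $\log_{10}\theta \in [-6, 4]$ per dimension by the
DIRECT global optimizer (implemented in the package; deterministic,
derivative-free, 2000-evaluation default budget). All linear algebra
goes through the upper Cholesky factor $A$ with $A'A = R$; the solve
vector $R^{-1}(y - \mathbf{1}\beta)$ is cached so posterior means are
vector–vector products. A nugget starting at $10^{-10}$ escalates
tenfold on Cholesky failure up to $10^{-4}$; near-duplicate neighbour
features make this necessary in practice. Fitting all $q = 2J+1$
correlation rates independently with DIRECT is intractable at $J = 50$,
so the default ties them into three groups (distances, neighbour
solutions, own solution); full anisotropic and isotropic modes exist.
Constant training outputs short-circuit to a constant predictor with
zero variance.

## The experiment and its evaluation

`runExperiment` executes the full protocol: mesh the annulus, refine
three times, solve the transport problem at every level, build features
at levels 0 and 1, train the level-0-features → level-1-solution
surrogate, and evaluate two distinct quantities per (output kind,
metric, J) cell:

* the **cross-validated RMSE** (k = 5 folds, s = 10 shuffles by
  default; shuffle $i$ seeds the partition with `seed` $+ i$; rows are
  put in canonical coordinate order first so results are independent of
  node storage order), and
* the **deployed RMSE**: a model refit on all level-0→1 pairs, applied
  to the level-1 features, scored against the level-3 truth at the
  level-1 node set.

They are reported side by side with the reference discretization
errors `rmse03` (level 0 vs level 3 over level-0 nodes) and `rmse13`
(level 1 vs 3 over level-1 nodes). All RMSEs are computed over the
coarser member's node set through the exact nesting maps.

### Problem sizes

The documented experiment scale is a level-0 mesh of about 600 elements
(about 7000 at level 3), the cityblock/Euclidean/Mahalanobis metrics,
$J \in \{10, 25, 50\}$, 3 shuffles, and 300-evaluation DIRECT budgets;
this runs in about two minutes. The reference discretization errors are
additionally computed at the printed baseline density of ~5302
elements (~42000 at level 3), which takes about a minute of solver
time and lands all four reference RMSEs within a factor of about three
of the reference values, with the expected ordering
`rmse13 < rmse03` for both drug forms.

## A known limitation, and what the tests do and do not show

With exact nested node matching and tight solver tolerances, the
discretization-error fields of successive refinement levels are nearly
uncorrelated node-by-node (measured correlation ≈ 0.1–0.25): P1 nodal
errors are dominated by node-local geometry effects that change when
the surrounding elements are bisected. In this regime a surrogate
trained on the level-0→1 correction and deployed on level-1 features
effectively re-applies a correction that no longer matches the
remaining level-1→3 gap, and its deployed RMSE lands near
$\sqrt{\|\delta_{01}\|^2 + \|\delta_{13}\|^2}$ — *above* `rmse13`
rather than below it. An oracle sweep over the grouped-θ family
(including heavy-nugget smoothing the likelihood itself would never
select) reaches at best ≈ 0.9 × `rmse13` here. The cross-validated
RMSE, by contrast, behaves as expected and is comparable to `rmse13`
at this scale. Reference values whose level-0↔3 and level-1↔3 RMSEs
are nearly equal indicate comparisons dominated by a level-independent
mismatch floor (for example interpolation or profile extraction),
which smooth surrogate output beats easily; exact nesting removes that
floor by construction. The corresponding acceptance test asserts the
deployed-beats-`rmse13` property as specified and is expected to fail
under this package's exact-matching design; it is retained, failing,
as an honest record rather than weakened.

The synthetic-data generator (`sampleGP`, `analyticProfile`,
`analyticField`) draws from the surrogate's own model family and from
closed-form diffusion/binding solutions. Passing the GP tests shows
the estimator recovers the truth *within its model class* (correct
specification); it says nothing about kernel misspecification on real
fields. The analytic closure test (same field at every level) isolates
pure learning error: the cross-validated error is below $10^{-6}$ of
the field scale, while the deployed error is bounded by kriging
interpolation across the coarse level's value gaps (about $10^{-3}$ of
scale at the 200-element fixture) — an intrinsic resolution limit, not
an implementation defect.

## Numerical choices

* Annulus mesh: counts within ±20% of the requested target; jitter
  backs off automatically (halving, deterministically) if a draw would
  invert an element.
* Longest-edge ties: lexicographic (min-index, max-index) edge wins.
* BDF work-array sizing: estimated from the Jacobian sparsity and
  escalated fourfold on rejection.
* Cross-validation fold sizes differ by at most one; every shuffle is
  independently seeded and recorded.
* DIRECT is deterministic given bounds and budget; every stochastic
  test in the package fixes its seed, and two runs of the same
  configuration produce byte-identical reports.
* Mahalanobis whitening fails loudly (singular covariance) on
  degenerate node sets rather than regularizing silently.

## Reproducing the numbers

`scripts/acceptance.R --seed 1 --out results/acceptance.json`
recomputes, from scratch: the four reference RMSEs at the printed
baseline density, the same four at the reduced scale, and the
cross-validated and deployed surrogate RMSEs for the cityblock metric
at $J \in \{10, 25, 50\}$ for both drug forms. The test suite under
`tests/testthat/` verifies each module against independent oracles
(closed forms, brute-force searches, dense linear algebra) and the
acceptance properties above.
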