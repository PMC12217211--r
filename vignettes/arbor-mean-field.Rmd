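---
title: "A mean-field model of stochastic dendritic arbor growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mean-field model of stochastic dendritic arbor growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arborfield)
```

## The model

Class IV dendritic arborization neurons of *Drosophila* larvae build dense,
quasi-planar dendritic arbors by a strikingly simple local mechanism: new
branches nucleate laterally along existing branches, branch tips switch
stochastically among growing (G), shrinking (S) and paused (P) states — the
dendritic analogue of microtubule dynamic instability — and a growing tip
that touches another branch retracts and disappears. `arborfield`
implements a mean-field theory of this process together with its stochastic
counterpart, and asks how far such purely local, memoryless rules go in
explaining arbor-scale geometry: branch-length distributions, number and
length densities, mesh size, branch orientation, and the speed of arbor
expansion.

The state of the theory is the branch density $n_X(r, l, \theta, t)$ of
terminal branches of length $l$ and radial orientation $\theta$ at radial
position $r$, for each tip state $X \in \{G, S, P\}$. Its dynamics combines

* Markovian tip-state transitions with the six measured rates
  $k_{GS}, k_{GP}, k_{SG}, k_{SP}, k_{PG}, k_{PS}$ (min$^{-1}$),
* advection in length at the tip speeds $v_G$ and $-v_S$ ($\mu$m/min),
* nucleation proportional to the local total length density, at rate
  $k_b$ (min$^{-1}\mu$m$^{-1}$), with new branches born growing at zero
  length and isotropic orientation,
* a zero-length boundary condition in which a fraction $\beta \approx 0.2$
  of branches that shrink to zero length immediately regrow
  ("rebranching") while the rest disappear,
* collision-based elimination of growing branches at rate
  $K_{\mathrm{col}} = [\alpha \bar v \rho + \alpha^2 \gamma D \rho^2]\,
  N_T/N_G$, the density-dependent negative feedback that keeps the arbor
  finite, and
* spatial transport of branch midpoints at half the tip speed,
  $\tfrac{v}{2}(\cos\theta\,\partial_r - \sin\theta\,\tfrac1r
  \partial_\theta)$.

Because branching is modelled as nucleation, the theory carries no tree
topology: the arbor is a weakly interacting gas of directed line segments.
Internal branches are incorporated by the doubling convention
$N_{tot} = 2N_T$, $\rho_{tot} = 2\rho_T$, motivated by the observed
near-equality of terminal and internal branch numbers and lengths.

Two tip-level summary statistics drive everything macroscopic: the drift
velocity $\bar v = P_G v_G - P_S v_S$ and the Green-Kubo diffusion
coefficient $D$, the time integral of the stationary velocity
autocorrelation of the three-state chain. `diffusion_coefficient()`
evaluates $D$ spectrally from the transition-rate matrix and falls back to
direct numerical integration of the autocorrelation when the two decaying
modes are degenerate or complex; the two routes agree to $10^{-3}$
relative on all packaged parameter sets.

```{r kinetics}
p <- table1_params("48h")
drift_velocity(p$kinetics)
diffusion_coefficient(p$kinetics)
```

## Analytic steady states and fronts

In the homogeneous, isotropic centre of the arbor the length-resolved
balance collapses, after eliminating the paused state, to a linear 2 x 2
system in $l$ whose decaying eigenvalue $-1/\bar\ell$ forces exponential
branch-length distributions. The mean length solves a cubic fixed-point
equation and the density follows from a quadratic in $\rho_{tot}$ whose
coefficients are the collision prefactors; `solve_three_state()` returns
both, plus the zero-length boundary densities, and verifies the eigenvalue
condition to $10^{-9}$. The one-state limit (fast switching, drift only)
gives the closed forms $\bar\ell = \sqrt{\bar v / 2k_b}$,
$N = \alpha_1 \rho^2$ and the relaxation time
$\tau = 1/(2\sqrt{k_b \bar v})$ — about 28, 76 and 112 minutes at the
three packaged ages, which is why the arbor centre can be treated as being
in quasi-steady state throughout days-long development.

```{r steady}
solve_three_state(p$kinetics, p$prefactors)
```

For the expanding edge, an exponential front ansatz
$e^{-z/\lambda}$ in the co-moving frame $z = r - ct$ (dropping the
collision term, internal branches, and the $1/r$ angular transport, all
subdominant at the front) leaves a one-parameter family of admissible
$(c, \lambda)$ pairs. The selected, marginally stable "pulled" front is
the minimum of $c$ along that curve; `marginal_front()` finds it by an
outer search over $\lambda$ with an inner bracketed root solve for $c$ at
each $\lambda$, which is more robust near the singular minimum than a
joint optimizer. The admissibility boundary (where the angular-length
integral of the ansatz diverges) is detected analytically and reported as
an explicit flag rather than a `NaN`. In the one-state limit the front
degenerates to $c_m = \bar v/2$, $\lambda_m = 0$: expansion by persistent
radial elongation only. Length fluctuations are what make real fronts
faster — at the 48-hour parameters the selected speed is roughly four
times the zero-diffusion value, and expansion survives even at zero (or
negative) drift.

```{r front}
marginal_front(p$kinetics)
```

The phase diagram over $(\bar v, D)$ is realized by holding the six
transition rates fixed and inverting effective tip speeds
(`invert_velocities()`): occupancies do not depend on speeds, so the drift
target is linear in $(v_G, v_S)$ and the diffusion target reduces to a
one-dimensional root solve. This inversion reproduces the measured point
exactly by construction; it is one consistent realization of the axes, not
the only possible one.

## The directed-rod simulator

`sim_config()`/`run_periodic()`/`run_expanding()` drive a Monte-Carlo
ensemble of directed rods (Rcpp core): fixed time step, transition
probability $1 - e^{-k_{tot}\Delta t}$, length updates $v_X \Delta t$,
debranching with rebranching probability $\beta$ at zero length, whole-rod
removal when a growing tip's swept segment crosses any other rod
(uniform-grid spatial hash, minimum-image convention in the periodic box),
and nucleation with probability $1 - e^{-2 l_i k_b \Delta t}$ per rod. The
factor 2 in the nucleation exponent is the simulator's form of the
internal-branch correction: every rod stands for a terminal branch plus an
internal partner of similar length that also hosts nucleation, and with it
the rod ensemble's steady state is the exact stochastic counterpart of the
doubled mean-field equations (`internal_branch_correction = FALSE`
restores the strict terminal-only variant, which is equivalent to halving
$k_b$). Event ordering is fixed — transitions, motion, debranching,
collisions, branching — and a single seeded generator makes runs
reproducible.

The simulator is also where the collision prefactors come from:
`measure_collision_rate()` plus `fit_collision_prefactors()` fit
$K = \alpha \bar v \rho + \alpha^2 \gamma D \rho^2$ across a
branching-rate sweep. At the packaged parameter sets the simulator and the
analytic solution agree on density to a few percent; the mean branch
length runs ~5% long in the simulation, a real (and expected) correlation
effect — survivors of collision-based pruning preferentially sit in
locally sparse neighbourhoods, which the mean-field closure ignores.

## The moment solver

`pde_solve()` integrates the 0th and 1st length-moments of the density
equations on a polar grid (default 200 radial cells over $(0, 100]$
$\mu$m, 100 angular cells, $\Delta t = 0.05$ min, backward Euler via
fixed-point iteration). The moment reduction needs the zero-length
densities that the moments do not carry; they are closed with the local
exponential length distribution per state, $n_X(0) = N_X^2/\rho_X$ (with
the local mean length floored at 0.01 $\mu$m). The closure is exact at
the analytic steady state — the discrete right-hand side vanishes there to
machine precision, which is the test that validates it. Transport uses
first-order upwind differences; the $1/r$ angular-transport coefficient is
regularized over the three innermost rings, where the solution is
isotropic and the term is otherwise numerically stiff. Negative values
created by the discretization are clipped to zero and the clipped mass is
logged.

Two bookkeeping regimes are exposed through `nucleation_doubling`. With
the default, the birth flux doubles along with the fields, and the
homogeneous bulk is an exact fixed point of the doubled analytic steady
state (machine-precision residual). The front theory, however, omits
internal branches at the leading edge, so front runs use the verbatim
single-rate source. Front extraction (`extract_front()`: 10%-of-central
contour for position, 25%-tail exponential fit for the decay length, both
mirroring how the experimental profiles are measured) then faces two
competing numerical effects that a refinement study makes explicit:
first-order upwind diffusion speeds the pulled front up linearly in
$\Delta r$, while the two-moment closure itself selects a wave some ten
percent slower than the length-resolved marginal-stability speed in the
continuum limit. At the reference half-micron radial mesh the two biases
largely cancel, and the extracted speed lands within a few percent of the
traveling-wave solver; the decay length converges monotonically under
refinement and is read from a refined mesh. The cross-checks in the test
suite run on reduced grids (50-240 radial cells, 8-32 angular cells, a few
hundred simulated minutes), which keeps each within minutes on one core
while preserving this convergence behaviour.

## Mesh size and morphometry

`mesh_size()` estimates the median hole size of any planar segment
network: the diameter $M$ at which a randomly placed circle has a 50%
chance of touching the network. All trial diameters share one set of 5000
random centers (common random numbers), so the empirical hit curve is
monotone by construction and $M$ is simply twice the median
center-to-segment distance; centers are drawn in the window shrunk by half
the largest trial diameter to avoid edge bias, or with wrapped distances
for periodic rod-simulation snapshots. Benchmarks with closed forms
(`analytic_mesh()`): all regular tilings share mesh/sparsity ratio
$2 - \sqrt 2 \approx 0.59$ (derived from the inradius relation
$M = 2a(1 - 1/\sqrt2)$), equally spaced lines give $1/2$, exponentially
spaced lines $\ln 2$. Voronoi/Delaunay benchmarks are generated from an
in-package Bowyer-Watson triangulation, property-tested against the
empty-circumcircle criterion.

The morphometry functions re-implement, on skeletons (SWC or segment
lists), the measurements used on real arbors: branch decomposition and
terminal/internal classification, histogram-based exponential length fits
that exclude the first bin (depressed by detection limits in real
skeletons), radial angles from a 1 $\mu$m tangent window at the branch
midpoint (counterclockwise positive, outward radial = 0, tangent oriented
distally), $\sqrt{12} R_g$ widths, 5%-trimmed central densities, 10%-point
aligned front profiles with 25%-tail decay fits, and a rebranching
probability estimated by matching debranching events to subsequent branch
appearances within 0.5 $\mu$m and 20 min.

## Synthetic data, and what passing tests show

The generators in `exp_tree()`, `traveling_profile()` and the simulator
itself provide every fixture the test-suite needs, with known ground
truth: exponential branch lengths of known mean and exactly labelled
branch types, logistic fronts of exact speed and decay length, and event
logs with configured $\beta$. They emulate the statistical structure of
real skeletons (branching topology, length distributions, radial
geometry) but not their imaging artefacts — no pixelation, gaps,
segmentation errors or z-projection distortion — so parameter-recovery
tests certify the estimators, not the upstream image processing. The
defaults of the generators and simulations are the measured parameter
sets packaged in `table1_params()`; these ship at their published
precision, and two derived entries do not re-derive from the printed
inputs (the 24-hour diffusion coefficient differs by 0.2%, consistent
with input rounding; the 96-hour diffusion entry is inconsistent with its
own transition rates, which the package treats as reference data only and
never uses in computation).

## Numerical choices and limitations

* Cubic mean-length equation solved by `polyroot` (companion matrix);
  positive real root selected with imaginary tolerance $10^{-10}$.
* Green-Kubo degeneracy threshold $|\lambda_1 - \lambda_2| <
  10^{-10}\max$; below it the autocorrelation is integrated by RK4 +
  trapezoid over $40/\lambda_{\min}$.
* Front search window $\lambda \in (0.01, 50)$ $\mu$m, 200-point log
  scan, root tolerance $10^{-12}$.
* Simulator default $\Delta t = 0.05$ min (matches the moment solver);
  halving it from there moves steady-state densities by about 1%. The
  one-state collision sweeps use $\Delta t = 0.1$ min at $\bar v = 0.027$
  $\mu$m/min, where the per-step tip displacement is still far below the
  mesh size.
* The model is two-dimensional by construction: collision feedback as
  implemented has vanishing rate for infinitely thin lines in 3-D. The
  theory also omits tree topology, so topology-dependent statistics
  (Strahler orders, subtree correlations) are outside its scope, and the
  front analysis drops the collision term, making it a leading-edge
  (pulled-front) approximation.
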