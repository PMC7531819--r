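---
title: "Non-equilibrium landscape and flux analysis of a working-memory circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-equilibrium landscape and flux analysis of a working-memory circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmflux)
```

## The model

`wmflux` analyzes the reduced two-variable circuit model of working memory:
two selective excitatory populations, each summarized by its average NMDA
synaptic gating variable $S_i \in [0, 1]$, with self-excitation $J_+$ and
effective mutual inhibition $J_-$ (a linearized interneuron pool). The
deterministic dynamics are

$$\frac{dS_i}{dt} = -\frac{S_i}{\tau_S} + (1 - S_i)\,\gamma\, f(I_{i,tot}),
\qquad
f(I) = \frac{aI - b}{1 - e^{-d(aI - b)}},$$

with total currents $I_{1,tot} = J_{11} S_1 - J_{12} S_2 + I_0 + I_{ext,1}$
(and symmetrically for population 2). Stochastic trials add Gaussian
fluctuations to the current drive, $dI/dt = F_I(I) + \zeta$ with
$\langle\zeta(t)\,\zeta(t')\rangle = 2D\,\delta(t - t')$, i.e. the noise is
isotropic in the current plane and acquires the constant anisotropic
covariance $2D\,M^{-1}M^{-T}$ in the gating plane, where
$M = [[J_{11}, -J_{12}], [-J_{21}, J_{22}]]$ is the coupling matrix.

Global, trajectory-free characterization comes from the stationary
Fokker–Planck equation. Its solution $P_{ss}$ defines the potential
landscape $U = -\ln P_{ss}$, whose minima are the attractors: the resting
state $r$ (both populations at low activity), the two selective memory
states $m_1$, $m_2$, and — for strong enough self-excitation — the
intermediate state $m_3$ with both populations active. Because detailed
balance is broken, the steady state also carries a non-vanishing
probability flux $J_{ss} = F P_{ss} - D\nabla P_{ss}$, and the drift
decomposes as $F = J_{ss}/P_{ss} - D\nabla U$. The dissipation needed to
maintain this non-equilibrium steady state is the entropy production rate
$\mathrm{epr} = \int (J\cdot D^{-1}\cdot J)/P\, dx$ (temperature set to 1,
so the free-energy dissipation rate and epr coincide at steady state; the
transient free-energy balance is out of scope).

Robustness and flexibility are kinetic quantities: the mean first passage
time (MFPT) field $\tau$ solves the backward problem
$F\cdot\nabla\tau + D:\nabla\nabla\tau = -1$ with $\tau = 0$ on an
absorbing disk around the destination attractor and reflecting outer
boundaries. $\tau$ (no stimulus) measures robustness of a memory state
against random fluctuations; $\tau'$ (0.02 nA distractor to the other
population) measures flexibility to a new stimulus.

## Parameters, units, and two readings of printed constants

Internally everything is in seconds, Hz and nA: $a = 270$ Hz/nA, $b = 108$
Hz, $d = 0.154$ s, $\tau_S = 0.1$ s, $I_0 = 0.31$ nA, baseline
$J_+ = 0.30$ nA and $J_- = 0.05$ nA, stimulus amplitude 0.02 nA.
Two constants of the standard parameterization circulate in forms that are
dimensionally inconsistent with this convention, and the package fixes both
by requiring the model to reproduce its own documented structure:

* **The kinetic coefficient $\gamma$** multiplies a rate in Hz, so it must
  be dimensionless; a value "60 ms" cannot enter the gating equation as
  written. `wmflux` ships $\gamma = 0.60$: with it the baseline couplings
  yield exactly three attractors and the intermediate state emerges at
  $J_+ = 0.350$ nA (at $J_- = 0.05$ nA), the two structural anchors of the
  model. The common alternative $\gamma = 0.641$ also gives three baseline
  attractors but moves the emergence threshold to 0.340 nA. $\gamma$ remains
  a configurable parameter.
* **The noise coefficient $D$** is quoted as $1.4\times10^{-5}$ without
  units. Read per second, the stationary density would span more than 700
  log-units — the memory basins would carry relative weight below
  $e^{-700}$, no finite-precision landscape could represent them, and
  noise-driven escapes would never occur on trial timescales. Read per
  millisecond (the natural unit given $\tau_S = 100$ ms), it equals
  $1.4\times10^{-2}$ nA$^2$/s, which produces three basins of comparable
  depth and escape times of order seconds. The package default is therefore
  `D = 1.4e-2` in its seconds convention.

## Numerical methods

**Stationary solver.** A conservative cell-centered finite-volume scheme on
a uniform grid (default $200\times200$; most examples and tests use
$100\times100$, which changes barriers and MFPTs by about 1–2%).
Advective–diffusive face fluxes use exponential fitting
(Scharfetter–Gummel weights $B(z) = z/(e^z-1)$), which is positivity-
preserving and exact for locally linear drift; the off-diagonal tensor
entries of the gating frame enter as centered tangential-gradient
corrections on each face. Boundary faces carry no flux (reflecting).
The one-dimensional null space of the discrete operator is found by a
short implicit time-march from the uniform density followed by a direct
sparse solve anchored at the density maximum, with continued implicit
marching as a fallback; typical stationary residuals are $10^{-12}$ of
probability mass per second. Densities are clamped at zero and
renormalized (the clamped fraction is recorded; it is zero in the
isotropic frame and below $10^{-6}$ with cross terms).

**Two coordinate frames.** The default solve is on the gating square with
the transformed tensor $D\,M^{-1}M^{-T}$. As a cross-check the same
problem can be solved in the current plane, where the noise is isotropic;
there the physical domain is the parallelogram image of the gating square,
realized as an interior mask on the bounding-box grid (faces crossing the
mask boundary carry no flux). `landscape_to_gating()` pulls a
current-frame solution back through the exact affine change of variables.
The two routes agree: the potential difference is constant to median
$3\times10^{-4}$ (99th percentile below 0.01 over cells holding the bulk
of the probability; isolated staircase-boundary cells deviate more), and
the entropy production rates agree within 1% at $200^2$.

**Potential and barriers.** $U = -\ln P_{ss}$ is taken on cell masses;
cells below a relative density floor ($10^{-12}\times\max P_{ss}$ by
default) are masked and excluded from analysis. The saddle between two
basins is found by flooding cells in order of increasing $U$ with a
union–find over 4-neighbor connectivity: the cell whose activation first
connects the two minima is the barrier top (the minimax path elevation;
verified against exhaustive sublevel-set search). Barrier height is
$U_{saddle} - U_{min}$ of the source attractor.

**Fixed points and taxonomy.** Roots of the drift are polished by damped
Newton iteration (analytic Jacobian) from a $25\times25$ seed lattice, with
duplicates merged within $10^{-4}$; stability comes from the Jacobian
eigenvalues. Labels use an adaptive threshold — "high" means a gating value
above the midpoint of the range spanned by the stable points, falling back
to 0.35 when all stable points cluster — so the taxonomy follows each
parameter set rather than fixed magic numbers. The intermediate-state
emergence threshold is judged from the deterministic fixed points (a stable
both-high state), with the landscape maxima as a cross-check; at the
working noise level density peaks sit within about 0.03 gating units of
the fixed points (finite-noise shift), not within one grid cell.

**MFPT.** The backward operator is the transpose of the forward
finite-volume operator, which makes the discrete $\tau$ the exact mean
absorption time of the forward Markov chain — forward solver, backward
solver and Monte-Carlo simulation are consistent by construction.
Absorbing sets are disks of radius 0.02 gating units around the
destination attractor, shared with the trial simulator. The destination
convention follows the study design: escape from $m_1$ goes to $r$ before
the intermediate state exists and to $m_3$ after; for $\tau'$ under the
distractor with no $m_3$, the destination is $m_2$ (the attractor the
distractor makes dominant) — a convention the interface reports alongside
every number. Note that at the working noise the absorbing radius is not
fully in the barrier-dominated regime: halving it moves $\tau$ by about
10% (about 8% at half the noise).

**Langevin trials.** Euler–Maruyama in current space (default
$dt = 10^{-4}$ s) with the state mapped back through $M^{-1}$ each step.
At the edges of the gating square the state is mirror-reflected *in
current coordinates* — equivalently, obliquely along the conormal
direction $D\,n$ in gating coordinates. This is the reflection whose
stationary law matches the zero-flux boundary of the grid solver;
naive per-coordinate mirroring with correlated noise systematically
shortens escape times by tens of percent. Passage times exceeding the
horizon ($10^4\,\tau_S$ by default) are reported as censored, never
averaged in. Transition-path densities histogram only the switching
segments of trials — from the last exit of the start disk to the first
entry of the destination disk.

**Entropy production.** The grid integral sums
$(J\cdot D^{-1}\cdot J)/P$ over unfloored cells and always reports the
excluded probability mass. An independent trajectory estimator integrates
$(J_{ss}/P_{ss})\cdot D^{-1}\circ dx$ at Stratonovich midpoints along a
long simulated trajectory; grid and trajectory estimates agree within a
few percent over 300 s of simulated time.

## What the defaults reproduce — and two honest discrepancies

With the shipped defaults the package reproduces the core structure of the
stability–flexibility–energy tradeoff: exactly three attractors at
baseline; emergence of $m_3$ at $J_+ = 0.350$ nA, delayed to 0.360 and
0.365 nA at $J_- = 0.055$ and 0.06 nA; barrier heights and $\tau$ rising
steeply with $J_+$ (about 0.1 to 4.2 units and 1.6 s to 46 s across
$J_+ = 0.30$–0.345 nA at $J_- = 0.05$ nA) and falling after the
intermediate state appears; $\tau' < \tau$ throughout; entropy production
strictly increasing in both couplings, with and without the distractor;
D1 modulation (both couplings scaled by a sigmoid of the receptor
activation, calibrated to 1 at $D_1 = 1$) strengthening robustness at
higher activation; and distractor-driven switching paths funneled through
the $m_3$ neighborhood (an order of magnitude more occupancy at
$J_+ = 0.36$ than at 0.30).

Two orderings do *not* reproduce under the printed parameters, and the
package reports them as computed rather than forcing them. First, in the
common-destination regime ($J_+$ below the emergence threshold) the
no-stimulus $\tau$ and its barrier *decrease* by a few percent as $J_-$
rises from 0.05 to 0.06 nA — confirmed by Monte-Carlo simulation and under
several noise conventions, so it is a property of the drift itself; the
expected ordering does hold across the emergence band (where delayed $m_3$
emergence keeps the higher-$J_-$ circuit in its long-$\tau$ regime) and in
the distractor scenario, which is where the effect is visually dominant in
sweep figures. Second, at matched $\tau'$ the configuration with the
intermediate state present shows smaller, not larger, $\tau$ here. Both
are flagged by `tradeoff_report()` verdicts.

Two further regime limits are worth knowing. The memory states disappear
through a saddle-node near $J_+ \approx 0.295$ nA (at proportionally
scaled $J_-$), so D1 activation levels below about 0.9 abolish the
working-memory attractors altogether and yield `NA` records. And at the
working noise level ($\sigma \approx 0.18$ in gating units) the system is
not in the weak-noise asymptotic regime: density maxima shift visibly from
the deterministic fixed points, and disk-radius conventions matter at the
10% level for MFPTs.

## What the synthetic trials do and do not emulate

The Langevin module generates exactly the data the analysis pipeline
consumes: seeded single trials with resting/loading/maintenance phases,
first-passage samples, occupancy histograms and switching-path densities,
all from the same drift and noise model the grid solvers discretize. They
emulate stationary, Gaussian, current-space fluctuations of a homogeneous
mean-field circuit. They do not emulate spiking statistics, colored or
state-dependent noise, synaptic short-term plasticity, heterogeneity
across neurons, or measurement noise — so green tests certify the
landscape–flux machinery on this reduced model, not the behavior of a
biological network beyond the mean-field reduction.

## Problem sizes used in the shipped tests

Unit tests run the solvers at $60^2$–$200^2$; the sweep-based checks use
$100^2$ with $J_+$ from 0.30 to 0.37 nA in 0.005 nA steps and
$J_- \in \{0.05, 0.055, 0.06\}$ nA; Monte-Carlo cross-checks use 250–1000
trials at $dt = 10^{-4}$ s. These sizes keep the grid-refinement error in
barriers and MFPTs at the 1–2% level, which is the tolerance the
cross-validation tests assert.
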