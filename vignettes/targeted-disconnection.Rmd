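---
title: "Targeted virtual disconnection of epileptic brain networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted virtual disconnection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epilesion)
```

## The dynamical model

Every brain region of an N-region parcellation is modelled as a
two-dimensional Epileptor, the planar reduction of the five-dimensional
Epileptor neural mass. One fast variable $x_i$ captures the electrographic
state — a stable node for the healthy condition, fast oscillatory activity
for the ictal state — and one slow "permittivity" variable $z_i$ carries the
region through interictal and ictal phases autonomously:

$$\dot x_i = -x_i^3 - 2x_i^2 + 1 - z_i + I$$
$$\dot z_i = \frac{1}{\tau}\Big[4(x_i - x_{0,i}) - z_i - \sum_{j=1}^{N} K_{ij}(x_j - x_i)\Big]$$

All quantities are dimensionless; one model time unit corresponds loosely to
the fast electrographic timescale, and the slow dynamics are slower by the
factor $\tau$. $K$ is the structural connectivity matrix: symmetric,
non-negative, zero diagonal, rescaled so its maximum entry is one. The linear
difference coupling acts on the slow variable: sustained depolarization of a
neighbour lowers $z_i$, which is what recruits a region into seizing.

The fast subsystem is bistable. For a fixed $z$, the cubic nullcline
$z = -x^3 - 2x^2 + 1 + I$ has a stable healthy branch at $x < -4/3$ and an
oscillatory/depolarized branch around $x \gtrsim 0$, with a fold at
$x = -4/3$. The per-region excitability $x_{0,i}$ positions the slow
nullcline: eliminating $z$ at equilibrium gives the cubic
$x^3 + 2x^2 + 4x - (1 + I + 4x_0) = 0$, which has exactly one real root
(its derivative $3x^2 + 4x + 4$ is strictly positive). The root crosses the
fold at

$$x_0^{*} = -\tfrac{4}{3} + \tfrac{1}{4}\Big[(-\tfrac43)^3 + 2(-\tfrac43)^2 - (1+I)\Big]
          \;=\; -2.06204 \ \text{at}\ I = 3.1 ,$$

so a region with $x_0 > x_0^{*}$ has no stable equilibrium and seizes
autonomously, with inter-seizure intervals of order $\tau$. The package
labels a region epileptogenic when $x_0$ exceeds the critical constant
$x_c$. Two conventions circulate for the sign of that comparison; we adopt
*EZ iff $x_0 > x_c$*, the one consistent with the bifurcation structure
above. The labelling constant defaults to $x_c = -2.1$, which sits $0.038$
below the analytic threshold $-2.06204$; we keep the two deliberately
distinct (one is a clinical labelling convention, the other a property of
the vector field) and document rather than reconcile the gap. The
two-level assignment used throughout — EZ at $x_0 = -1.6$, all other regions
at $x_0 = -2.2$ — places healthy regions close enough to the fold that
strong input can recruit them, which is the regime of interest. No third
level is needed for the propagation zone: recruitment emerges from the
dynamics.

There is no stochastic input anywhere; the system is autonomous and every
trajectory is a deterministic function of the initial state. The default
initial condition is the healthy-branch fixed point of the all-healthy
system (every $x_0$ clamped at the healthy reference $-2.2$), from which EZ
regions drift into their first seizure through their own slow dynamics.

## Linear stability analysis and PZ prediction

The network fixed point solves, per region,
$4(x_i - x_{0,i}) - z_i(x_i) - \sum_j K_{ij}(x_j - x_i) = 0$ with
$z_i(x_i) = -x_i^3 - 2x_i^2 + 1 + I$. We use a damped Newton iteration
started from the uncoupled roots; the Jacobian of this reduced system,
$\mathrm{diag}(4 + 3x_i^2 + 4x_i + s_i) - K$ with $s_i = \sum_j K_{ij}$, is
assembled exactly. Convergence (max-norm residual below $10^{-12}$, usually
in 4–6 iterations) is reported explicitly; downstream analyses refuse
unconverged fixed points rather than propagate a silent wrong answer.

The $2N \times 2N$ Jacobian of the full system at the fixed point has the
block structure

* x-rows: $\partial \dot x_i/\partial x_i = -3\bar x_i^2 - 4\bar x_i$,
  $\partial \dot x_i/\partial z_i = -1$;
* z-rows: $\partial \dot z_i/\partial x_i = (4 + s_i)/\tau$,
  $\partial \dot z_i/\partial x_j = -K_{ij}/\tau$,
  $\partial \dot z_i/\partial z_i = -1/\tau$.

Positive-real-part eigenvalues signal that the fixed point repels — the
seizure can propagate — and the eigenvector of the largest eigenvalue points
along the most unstable directions. Node scores are the moduli of the
eigenvector's x-block components (the z-components are $O(1/\tau)$-suppressed
and the fast variable carries the instability); the modulus also makes the
scores invariant under the eigenvector's arbitrary complex phase, so for a
complex pair either member gives the same scores. The predicted PZ is the
set of non-EZ regions whose score is "considerably large". Whether that
threshold should be absolute or relative to the largest non-EZ score is
genuinely open; both modes are implemented, with the absolute mode
(`eps_loc = 1e-5` on the unit-norm eigenvector) as default because the
delocalization scale of interest is an absolute one — on an average-like,
dense connectome many components sit above $10^{-5}$ and the prediction is
flagged as delocalized rather than silently truncated.

An independent dynamical cross-check is provided by `max_lyapunov()`: tangent
dynamics are integrated along the trajectory with periodic renormalization;
at a stable fixed point the average log growth rate reproduces the leading
eigenvalue's real part, and during propagation the time-averaged tangent
profile localizes on the same regions as the eigenvector scores.

## Lesioning strategies and containment

Virtual ablation of a link zeroes the symmetric entry pair $(i,j)$/$(j,i)$.
(A phrase like "removing the row and column" would describe deleting a
region; everything here is link-level surgery, consistent with per-link
lesion counting.)

Containment is decided by *simulation*, not by the eigenspectrum: after a
successful disconnection the EZ still seizes, so positive eigenvalues
persist; what matters is that no region outside the EZ is ever recruited
over the horizon (an "asymptomatic seizure"). The containment test watches
all non-EZ regions and terminates the integration at the first upward
crossing of the seizure-onset threshold, which makes failed tests cheap; a
contained verdict requires the full horizon.

Five strategies are implemented (`plan_lesions()`):

* **full_disconnection** — every positive-weight EZ-incident link at once;
  the standard-resection analogue and an upper bound by construction.
* **random** — seeded random EZ-incident cuts, one at a time with a
  containment test after each, averaged over 5 realizations (per-replicate
  seeds derived from the master seed).
* **strongest_ez** — EZ-incident links in descending weight order until
  containment.
* **strongest_macroarea** — links incident to the EZ ∪ predicted-PZ
  macro-area in descending weight order. We read "links outgoing the
  macro-area" as *incident to* it, by analogy with "links outgoing the EZ":
  under the alternative exactly-one-endpoint reading the strategy could
  never cut an EZ–PZ link and could never contain a seizure recruited
  inside the macro-area, and the forced single-link network (where every
  strategy must need exactly one cut) would be unsolvable. The macro-area
  uses the LSA-predicted PZ, since a clinical PZ does not exist for
  synthetic data.
* **lsa** — iterate fixed point → Jacobian → leading eigenvector; the target
  is the highest-scoring non-EZ region still linked to the EZ, and the cut
  is the largest-weight (EZ, target) link (the multi-node-EZ rule; with one
  EZ node it reduces to cutting its link to the top-scoring region).
  Containment is tested whenever the predicted PZ is empty, and every 5 cuts
  regardless, trading a possible small overshoot in the count for far fewer
  full-horizon simulations.

Ties are always broken towards smaller region indices, so every plan is
reproducible. Plans carry the per-step eigenspectrum summary (number of
positive eigenvalues, predicted-PZ size), a `capped` flag when the candidate
set or the cap (default 20) is exhausted before containment, and replay
idempotently on a fresh connectome.

## Synthetic connectomes and the planted ground truth

Real patient connectomes are not redistributable, so the package generates
its own study material:

* `generate_modular()` — a stochastic block model with lognormal weights
  (defaults: N = 30, 3 equal modules, within/between edge probabilities
  0.8/0.05, log-mean 0, log-sd 1, max-normalized). The lognormal choice
  mimics the heavy-tailed distribution of tractography track counts.
* `generate_planted()` — one EZ region with `n_strong` strong links (weights
  0.85–1.0, distinct so the eigenvector ranking is well defined) to
  designated PZ regions, plus weak background links everywhere else capped
  at **0.02** on the strong-link scale.

The weak-weight ceiling is a calibrated constant. A healthy region at
$x_0 = -2.2$ destabilizes when its summed input from seizing neighbours
shifts its effective excitability past $-2.062$, i.e. when
$\sum_j K_{ij}(x_j - x_i)/4 \gtrsim 0.14$, which with depolarization swings
of $\lesssim 1.8$ requires summed weights of roughly $0.3$. With the ceiling
at 0.02 and at most a handful of simultaneously seizing neighbours the
worst-case background drive stays a factor of ~3 below that, so recruitment
can only pass through the planted links — an unambiguous ground truth. The
same ceiling keeps the background eigenvector scores (~$10^{-5.2}$ and
below) cleanly separated from planted scores (~$3\times10^{-4}$) around the
$10^{-5}$ localization threshold.

What the generator does *not* emulate: spatial embedding and
distance-dependent connection probability, hemispheric symmetry, rich-club
organisation, and realistic weight–topology correlations of DTI connectomes.
Passing the planted-recovery and strategy-ordering tests therefore shows the
machinery is correct and the LSA plan is minimal *when ground truth exists
and is separable*; it does not certify prediction quality on real patient
matrices, where the PZ is delocalized to a degree these fixtures do not
reproduce.

## Numerical choices

* **Integrator.** Adaptive embedded Runge–Kutta 5(4) (Cash–Karp) in
  compiled code, relative/absolute tolerances $10^{-8}$, Hairer-style RMS
  error norm, maximum step 25 time units, cubic-Hermite output sampling.
  The slow–fast ratio $\tau = 2857$ suggests stiffness, but the fast
  relaxation rates are $O(1)$ ($|-3\bar x^2 - 4\bar x| \lesssim 9$ even
  transiently), so an explicit adaptive method is accurate and fast here;
  the step size is limited by the genuine $O(1)$-frequency ictal
  oscillations, not by stability. A fixed-step RK4 (dt ≤ 0.05) and
  `deSolve::lsoda` are provided as cross-check back-ends and agree with the
  default to $10^{-3}$ on seizure trajectories.
* **Event detection.** Hysteresis thresholds $\theta_{on} = 0$,
  $\theta_{off} = -1$, minimum duration 5 time units. Healthy equilibria
  satisfy $x < -4/3$ while ictal activity visits $x > 0$, so the fold
  structure separates the states unambiguously and the detection is
  threshold-insensitive over a wide band.
* **Horizons.** Default simulation horizon $10\tau$ (= 28 570), long enough
  for several seizure cycles; the first EZ seizure starts within ~100 time
  units of the healthy start and recruitment follows within a few hundred.
  Containment checks reuse the same horizon.
* **Eigen-analysis.** Full dense decomposition (`eigen`); eigenvalues sorted
  by descending real part; `eps_pos = 1e-8` distinguishes genuinely positive
  real parts from round-off.
* **Degenerate inputs.** All-zero matrices are rejected at normalization;
  isolated EZ regions contain trivially with zero lesions; empty rasters and
  empty PZ predictions are valid values, not errors; zero-variance metrics
  yield `NA` correlations; solver non-convergence and integration failures
  raise explicit errors with the failure time.
* **Graph distances.** Shortest-path measures use $d = 1/w$ over
  positive-weight links, so stronger connections are shorter — the standard
  convention for connectivity matrices. (Summing raw weights as "lengths"
  would make strong connections long and invert the integration
  interpretation.) Degree and clustering are computed on the binarized
  adjacency; a weighted (Barrat) clustering variant is available behind a
  flag. Disconnected pairs contribute zero to efficiency and are excluded
  from closeness averaging.

## Study sizes used by the tests and the acceptance script

Planted ensembles use N = 30 with 1–4 planted links (20 scenarios for
recovery/overlap properties, 50 for the strategy comparison); the EZ sweep
and correlations use the 30-region modular generator defaults; Jacobian
finite-difference checks use 20 random instances with N ≤ 10. These sizes
were chosen so each property is exercised on ensembles large enough for the
stated rates while the whole suite completes in minutes.

## Known limitations

* The analysis is restricted to the 2-D Epileptor reduction: no
  high-frequency ictal discharges, no SEEG forward (gain) modelling, no
  tractography preprocessing. Inputs are ready-made connectivity matrices.
* The EZ-sweep correlation between lesions-needed and *binary clustering* is
  not positive on the homogeneous modular generator, although the other five
  metrics correlate positively and robustly. In a stochastic block model,
  local clustering is roughly the within-module density for module-bound
  regions and *decreases* for regions with many cross-module links — which
  are exactly the regions needing more cuts. The positive clustering
  relationship reported for real connectomes reflects hubs embedded in dense
  cliques, a weight–topology correlation a single global within-module
  density cannot express. We report the negative sign rather than
  re-parameterize the generator around it.
* Multi-node-EZ lesion targeting (cut the largest-weight EZ–target link) is
  a reasonable but untested-in-clinic generalisation; the systematic sweep
  places single-node EZs only.
* `strongest_macroarea` depends on the PZ definition; with the LSA-predicted
  PZ it inherits any delocalization of the eigenvector.
* Containment is relative to the simulation horizon; recruitment that would
  first occur after $10\tau$ is not ruled out, though the slow dynamics
  relax well within that window in all ensembles examined.
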