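---
title: "Models and numerical choices in oildrop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in oildrop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oildrop)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters and why their defaults
are what they are, and the numerical decisions that were genuinely open.

## 1. The fuzzy-oil-drop model

A soluble globular protein folding in water tends to bury hydrophobic side
chains centrally and expose polar ones — the idealized end state is a
spherical micelle.  The model expresses that ideal as a 3D Gaussian density
over the molecule: per-residue *theoretical* hydrophobicity
$T_i \propto \exp(-x_i^2/2\sigma_x^2)\exp(-y_i^2/2\sigma_y^2)\exp(-z_i^2/2\sigma_z^2)$,
evaluated at each residue's effective point and normalized to sum to one.

**Effective points.** Each residue is reduced to the arithmetic mean of its
side-chain heavy atoms; glycine and truncated residues fall back to the
C-alpha (with a warning for the latter).  Only altloc `" "`/`"A"` atoms are
read, insertion codes are kept as part of residue identity, and residue
order follows file order — chain topology, not numeric sorting.

**Canonical frame.** Before evaluating the Gaussian the points are centred
at their centroid and rotated onto the covariance principal axes (largest
variance on x, proper rotation only).  All downstream statistics are
therefore invariant under rigid motion of the input, which the test suite
asserts to 1e-9.  Point sets that are coincident or collinear have no
defined frame and are rejected.

**Axis sigmas.** The model itself does not fix $\sigma$; the package uses
the 3-sigma convention $\sigma_a = \max_i |a_i| / 3$ per axis $a$, so the
Gaussian effectively vanishes at the outermost residue.  `compute_T()`
accepts explicit sigmas for sensitivity analysis.

**Observed distribution.** $O_i \propto \sum_{j \ne i,\ r_{ij} \le c}
(H_i + H_j)\, g(r_{ij}/c)$ with the smooth contact-decay polynomial
$g(u) = 1 - \tfrac12(7u^2 - 9u^4 + 5u^6 - u^8)$, $g(0)=1$, $g(1)=0$.  The
self term $j = i$ is excluded — including it would only add a constant
$H_i\,g(0)$ rescaling per residue and blur the interaction signal.  The
cutoff defaults to 9 Å, the conventional inter-residue hydrophobic
interaction range; it is a plain argument everywhere.  Intrinsic
hydrophobicities $H_i$ come from a named residue scale rescaled linearly to
[0, 1] (Kyte–Doolittle shipped as default); the scale is swappable and its
name is recorded in every result, because results are only comparable within
one scale.

**The order parameter.** With $R$ the uniform distribution,
$RD = D(O\|T) / (D(O\|T) + D(O\|R))$, divergences in log base 2.  $RD = 0$
iff $O = T$ (perfect micelle-like ordering); $RD \to 1$ as $O$ approaches
the unordered reference.  The degenerate case $O = T = R$ returns 0 by
convention.  Exact zeros in a profile (possible when a residue's only
neighbours sit exactly at the cutoff) are floored at 1e-12 and renormalized
before divergences, preventing spurious infinities while perturbing sums by
far less than the 1e-9 normalization tolerance the tests assert.

**The environment parameter.** Non-aqueous surroundings are expressed by
the inverted field $TM \propto \max(T) - T$ and the mixed target
$M(K) \propto T + K(TM - T)$, clipped below at zero and renormalized.
$K = 0$ is pure water, $K = 1$ is the fully inverted (membrane-like) field,
and larger $K$ extrapolates beyond it — $K$ has no upper bound in principle.
`fit_K()` minimizes $D(O\|M(K))$ on a coarse grid (0 to 2, step 0.01)
followed by one refinement pass at step 0.001 around the coarse optimum,
ties toward smaller K.  The default cap of 2 is a search bound, not a model
bound: pass `k_max` to extend it.  Parameter-recovery tests plant
$K^* \in \{0, 0.2, 0.6, 1.0, 1.5\}$ and require recovery within one
refinement step.

**Residue classification.** With $d_i = T_i - O_i$ and
$\tau = f \cdot \max_i |d_i|$, residue $i$ is *deficit* when $d_i \ge \tau$
(a candidate cavity), *excess* when $-d_i \ge \tau$ (a hydrophobic surface
patch), else *accordant*.  The comparison is inclusive so that at $f = 1$
exactly the maximal-deviation residue is flagged; $O = T$ gives all
accordant (no threshold exists to exceed).  The fraction $f$ defaults to
0.5 — a deliberate, documented choice: no published numeric criterion
exists for the red/blue flagging convention, so the threshold is explicit
and swappable.

**Eliminate and recompute.** Removing flagged residues and rerunning the
whole pipeline (re-orientation included) tests whether the remainder of the
chain is micelle-like; the removed indices are recorded in the result.  At
least three residues must remain.

### What the synthetic generator does and does not show

`gen_structure()` samples points from an anisotropic Gaussian (default
sigmas 12, 10, 8 Å — a small-protein-sized ellipsoid in which the 9 Å
cutoff gives a well-connected contact graph at the default n = 200) and
assigns hydrophobicity directly from the Gaussian field at each point,
bypassing the residue scale so the ground truth is scale-independent.
`ideal_micelle` fixtures analyse to small RD, `inverted` fixtures (the
field negated) to large RD, and `planted_outliers` flips h to 1 − h for
randomly chosen residues.

Two honest caveats, both visible in the package's own property tests.
First, even for an ideal fixture O is not exactly T: the contact sum
convolves hydrophobicity with local point density, so O is slightly
over-peaked and baseline RD sits near 0.15–0.2 rather than 0.  Because of
that bias, flipping a *single* residue can nudge O toward T and lower RD;
the ideal-below-planted ordering is only reliable once the discordant set is
large enough to dominate the smoothing, so the property test plants 20
outliers in 200 residues (checked across 10 seeds).  The
eliminate-and-recompute test instead plants three extreme outliers (h = 1)
on the surface of an ideal fixture — chosen away from the extent-defining
points so the 3-sigma rule is undisturbed — where elimination demonstrably
lowers RD.  Second, RD mixed along $O(\lambda) = (1-\lambda)O + \lambda T$
is monotone non-increasing for observed-like profiles (multiplicative
log-normal perturbations of T, the regime the tests sample), but the
two-divergence ratio is provably non-monotone for near-uniform O far from
T: the denominator term $D(O\|R)$ can fall faster than $D(O\|T)$ early in
the path.  The monotonicity test therefore states its instance family
explicitly.

The fixtures are points with hydrophobicity, nothing more: no bond
geometry, no steric exclusion, no sequence realism.  Passing tests show the
estimator chain is correct and invariant, not that any biological protein
scores a particular RD.

## 2. The negative-feedback loop model

The verbal picture — receptor senses product, above a sensitivity threshold
it inhibits the effector, concentrations oscillate within a normal band —
fixes no equations.  The package's realization is an explicitly discrete
synchronous update with an inhibition delay.  Per step $t$, for each loop:

1. effective rate $v'$ and sensitivity $S'$ are the base values scaled by
   $1 + \mathrm{gain} \cdot C_s(t)/S_s$ for each incoming coupling on the
   matching channel (effector or receptor), the source's own sensitivity
   $S_s$ providing the concentration normalization so gains are
   dimensionless;
2. activity $A(t) = 0$ iff the concentration $d$ steps earlier exceeded
   $S'$ strictly (boundary equality keeps the effector active — a fixed,
   documented tie rule); before any history exists the initial activity
   flag is used;
3. $C(t+1) = C(t) + v'A(t) - \delta\,C(t)$, floored at 0.

The delay is what makes this oscillate: a zero-delay threshold switch
chatters at the boundary instead of producing the sinusoid-like relaxation
cycles the model is meant to exhibit.  With decay $\delta > 0$ and finite
sensitivity the trajectory is bounded by roughly $v'_{max}/\delta$; both
properties are asserted over randomized configurations.  The model is
deterministic — the `seed` argument is recorded for provenance and reserved
for future noise terms.

Defaults per loop: $v = 1.0$ product units/step, $\delta = 0.1$ per step,
$S = 5.0$ units, delay 3 steps, $C_0 = 0$.  These give sustained
oscillations (tests require at least 4 mean-crossings per 500 steps) at a
period long enough to measure cleanly.  Systems are capped at three loops
by default, matching the intended scope of small coupled-unit experiments;
`allow_large = TRUE` lifts the cap for library use.

`measure_oscillation()` reports min/max/amplitude over a post-burn-in
window and the period as the mean interval between upward crossings of the
window mean — robust to the asymmetric rise/decay shape of relaxation
oscillations, and defined (period `NA`, frequency 0) for windows that never
cross.  `check_range()` applies inclusive bounds; leaving the reference
band is the model's notion of pathology.  Disturbance experiments rerun the
identical system with one parameter scaled and juxtapose per-loop summaries;
the directional claim the tests pin down is that speeding an upstream
effector does not slow an effector-coupled downstream loop.

Simulation sizes in the tests (500 steps, burn-in 100) are the package's
documented defaults: long enough that 25–40 cycles fall in the analysis
window, short enough to keep every simulation instantaneous.

## 3. The specificity-repetition planner

$k$ independent attempts, each succeeding with probability $p$, reach the
objective at least once with probability $1-(1-p)^k$; the smallest
sufficient $k$ is $\lceil \log(1-t)/\log(1-p) \rceil$, verified by direct
evaluation at $k$ and $k-1$ to guard the ceiling against floating-point
error.  The energy model is a declared stand-in, isolated in
`plan_energy()` and swappable: each attempt costs `base_cost` plus
`specificity_cost` per bit of coding burden $b(p) = -\log_2(1-p)$ — the
simplest information-theoretic link, under which each added independent
recognition element halves the per-attempt failure probability.  $p = 1$
has infinite burden and is rejected.  Energy is linear in $k$ and in
$b(p)$; both coefficients are user inputs, and the optimizer is an
exhaustive scan over the p grid with ties broken toward smaller $k$ then
smaller $p$, tested against full (p, k) enumeration.  Attempts are assumed
independent and identically distributed; correlated attempts (e.g. clonal
antibody families) are out of scope.

## 4. Degenerate inputs and error policy

Every engine rejects, with a plain-language error rather than a numeric
surprise: structures with fewer than 3 residues or a degenerate geometry;
point sets with no inter-residue contact anywhere within the cutoff;
constant T (inverted field undefined); negative K; divergences with
$P_i > 0$ where $Q_i = 0$; couplings that drive a rate or sensitivity
negative; ranges with low > high; infeasible (p, k) queries.  The
command-line drivers map every error to a nonzero exit status with the
message on stderr.

## 5. Known limitations

* The FOD results are scale-relative; no claim of numeric identity with any
  particular server or publication is made, and the per-residue flagging
  threshold is a convention, not a measurement.
* The loop simulator is a minimal discrete realization of a verbal model;
  period and amplitude values are properties of this realization, not of
  any biological system.
* The energy functional of the planner is an explicit modelling choice;
  only the probability layer ($1-(1-p)^k$) is assumption-free.
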