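---
title: "Semiflexible polymer adsorption: model, engine and observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semiflexible polymer adsorption: model, engine and observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The physical model

`polyadsorb` simulates a single coarse-grained semiflexible polymer — a
chain of $N+1$ spherical beads — near an infinite attractive wall at
$z = 0$. Energies are measured in $k_B T$ and lengths in units of the
maximum bond extension $l_{max}$. Four terms make up the Hamiltonian:

**Bonds.** Consecutive beads are connected by the finitely extendable
nonlinear elastic (FENE) potential
$$U_{FENE}(l) = -\tfrac{1}{2} k r_0^2 \ln\!\big[1 - ((l - l_0)/r_0)^2\big],$$
with $l_{min} = 0.4 < l_0 = 0.7 < l_{max} = 1.0$, $r_0 = 0.3$ and
$k = 20$. The potential is harmonic with stiffness $k$ near $l_0$ and
diverges at the range limits, so bond lengths can never leave
$(l_{min}, l_{max})$ — combined with excluded volume this prevents chain
crossing. We adopt the expansion-about-$l_0$ form with the $1/2$
prefactor, the standard convention in the bead-spring literature, which
makes $k$ the harmonic spring constant.

**Excluded volume.** All non-bonded bead pairs ($|i-j| > 1$) interact
through a Morse potential
$\varepsilon (e^{-2\alpha(r - r_{min})} - 2 e^{-\alpha(r - r_{min})})$
with $\alpha = 24$, $r_{min} = 0.8$, $\varepsilon = 1$. The large
steepness makes the tail negligible beyond unit length
($|U| \approx 0.016$ at $r = 1$), so the pair term is truncated to
exactly zero at $r \ge 1$ — applied identically in full and incremental
energy evaluation, which keeps the sampled distribution well defined.
The truncation error for a typical conformation is bounded by the number
of pairs in $[1, 2)$ times $0.016\,k_BT$; the test suite asserts this
rigorous bound rather than a heuristic fraction of it, because compact
conformations can place several pairs just beyond the cutoff.

**Stiffness.** Each interior bead contributes $U_b = b\,(1 + \cos\theta)$
where $\theta$ is the interior angle between its two bonds: zero for a
straight arrangement, $2b$ for a complete fold-back. In code this is
evaluated as $b\,(1 - \cos\varphi)$ with $\varphi$ the angle between
successive bond *vectors* — algebraically identical and free of the
interior-angle sign ambiguity. The bending energy $b$ (in $k_B T$) is one
of the two control parameters.

**Surface attraction.** Each bead at height $z$ feels a Morse wall
$\varepsilon_a (e^{-2\alpha_s(z - r_{min,s})} - 2 e^{-\alpha_s(z -
r_{min,s})})$ with the same steepness and minimum distance as the pair
term ($\alpha_s = 24$, $r_{min,s} = 0.8$): one Morse form serves both
interactions, so the surface term inherits those constants by default
(both are separate, settable parameters). Its depth $\varepsilon_a$ is the second control parameter. The
repulsive core acts as a soft wall; beads are additionally confined to the
half-space $z \ge 0$ (trial moves below the wall are rejected outright —
the core already makes $z \approx 0$ inaccessible, the hard constraint
only removes undefined negative distances). No tail cutoff is applied to
the surface term: it is a single cheap evaluation per bead and its tail is
$\sim 10^{-13}\varepsilon_a$ at $z = 2$.

## The Metropolis engine

Kinetics are single-monomer displacements: a bead chosen uniformly at
random is displaced by a uniform draw from $[-0.15, 0.15]^3$ and the move
is accepted with probability $\min(e^{-\Delta U}, 1)$. $N+1$ trials form
one Monte Carlo step (MCS), the time unit. Moves that stretch a bond out
of the FENE range or put a bead below the wall carry $\Delta U = \infty$
and are always rejected. The energy difference is evaluated
incrementally (the moved bead's bonds, up to three angles, its surface
term and its pair terms), which is $O(N)$ per trial; the test suite pins
the incremental path to full recomputation at $10^{-8}$ relative
tolerance. A plain scan over the other beads (with a squared-distance
early exit at the cutoff) was chosen over a cell list: at the chain
lengths the model targets ($N \le 300$) the scan is at most a few hundred
squared distances and the cell-list bookkeeping does not pay for itself.

Randomness comes from R's RNG; exactly five deviates are drawn per trial
in a fixed order (bead, $\Delta x$, $\Delta y$, $\Delta z$, acceptance
$\eta$, with $\eta$ drawn even for constraint-rejected moves), so a seed
fixes the trajectory bit-for-bit. Replica $r$ of a campaign with master
seed $s$ uses the derived seed $(s + 1000003\,r) \bmod (2^{31}-1)$,
making replicas independent and individually reproducible.

A replica starts from a grown conformation: a self-avoiding random walk
with bond directions drawn from the bending Boltzmann weight at the
model's own stiffness, rigidly translated so the lowest bead sits at the
surface minimum $r_{min,s}$ — the chain starts in contact, as the
adsorption protocol requires. After the configured burn-in, samples are
recorded every sampling interval. If at a sampling boundary every bead is
above the escape threshold (default $5\,l_{max}$, several times any
interaction range, so adsorbed states can never be clipped), the chain
has diffused away and the replica restarts from a fresh conformation,
discarding its samples; exceeding the restart limit marks the replica
failed rather than silently dropping it. Escape is checked at sampling
boundaries only — cheap and unambiguous. Equilibration length is a fixed,
configurable burn-in; the engine additionally splits it into eight blocks
and records whether the surface energy of the last two block-pairs agrees
within one standard error (`equilibrated` in the restart log). The
burn-in is never extended silently: a non-converged flag is data, not a
trigger.

## Observables

* **Height distribution $N_m$ / $P(D)$** — bead heights binned into
  unit-width bins centred at integer $D$, each spanning $[D-0.5, D+0.5)$.
  The adsorbed well ($z \approx 0.8$) falls in the $D = 1$ bin. The
  bound-monomer proportion sums the bins within the attraction range
  ($D \le 1$).
* **Adsorbed fraction** — beads with $z \le 1$, the distance beyond which
  the attraction is negligible. A chain with mean fraction $\ge 0.99$
  ("almost reaches 1") is labelled *fully adsorbed*; this threshold also
  tolerates the stiffest chains keeping a dozen of three hundred monomers
  off the wall just below their critical attraction.
* **Spatial correlation $G(m)$** — for each reference bond $i$, the
  lag-$m$ autocorrelation of the direction-cosine sequence
  $\cos\theta_{i,j}$, normalised by that sequence's variance, averaged
  over the interior reference bonds. Periodic oscillation of $G$
  diagnoses winding; reference bonds with zero variance are skipped, and
  a lag where all are skipped is NaN.
* **Tangent correlation $C(s)$** — ensemble covariance between the unit
  bond vector at contour position $s$ and at the chain end, averaged over
  both chain orientations because the ends are indistinguishable. The
  printed definition leaves the vector product implicit; we take the
  scalar covariance (dot product of centred vectors), the standard
  reading. Both raw and $C(s)/C(0)$ are reported; period counting uses
  the normalised curve. Whether the curve is ensemble- or
  snapshot-based matters: $G(m)$ is per-snapshot (it is shown for
  individual configurations), $C(s)$ is an ensemble average.
* **Surface-energy fluctuation** $\langle U_s^2\rangle - \langle
  U_s\rangle^2$ — the specific-heat analogue whose peak along an
  $\varepsilon_a$ scan locates the adsorption transition. Its standard
  error is a bootstrap over whole replicas (1000 resamples, seeded).
* **Toroid classifier** — a film-like toroid must be adsorbed (fraction
  $\ge 0.9$), flat (height extent $\le 1$) and wound: the dominant
  non-zero frequency of the discrete spectrum of $G(m)$ must carry at
  least $4\times$ the median spectral power. The turn count $N_t$ is that
  frequency index — the number of full $G$ periods over the lag range.
  The periodicity score alone is deliberately permissive (random
  sequences can reach it), the conjunction with adsorption and flatness
  is what rejects coils; the thresholds are arguments, and the defaults
  classify all five constructed spiral fixtures (1–5 turns) correctly and
  none of 100 random coils.

## Sweeps, profiles and the phase diagram

`run_sweep()` runs a replica campaign per $(b, \varepsilon_a)$ grid
point and condenses each into a phase point (adsorbed fraction,
fluctuation, toroid statistics, state label). Points are persisted under
a content hash of their spec, so an interrupted sweep resumes
byte-identically; per-point seeds derive from parameter values, not grid
order. `locate_transition()` takes the fluctuation maximum on the grid —
no interpolation, grid resolution is reporting resolution, with flags for
boundary maxima and statistically ambiguous peaks. The
$\varepsilon_a$ grid step is 0.25: the reference transition values
(2.75, 4.25) are only expressible on that grid. `phase_diagram()`
assembles the monotone boundary $\varepsilon_a^{crit}(b)$ with a
least-squares fit, and reports monotonicity violations instead of hiding
them. Desorbed and partially adsorbed chains are merged into a single
state: only full adsorption is a distinct phase here.

Three profiles share one schema:

| profile | bonds | replicas | samples/replica | interval (MCS) | burn-in (MCS) |
|---------|------:|---------:|----------------:|---------------:|--------------:|
| smoke   | 32    | 4        | 3               | $10^4$         | $5\cdot10^4$  |
| desk    | 64    | 8        | 2               | $10^5$         | $3\cdot10^5$  |
| full    | 300   | 100      | 100             | $10^6$         | $10^7$        |

The full profile is the production scale: $10^4$ samples per grid point.
The desk profile reproduces trends in minutes per point on one CPU;
its burn-in (three sampling intervals) resolves the flexible-chain
($b = 50$) adsorption threshold while keeping a two-point-per-replica
sampling window. The smoke profile exercises plumbing.

## What the scaled-down runs do and do not show

At desk scale ($N = 64$) the contour length ($\approx 45$) is well below
the persistence length at $b = 300$ ($\approx b\,l_0 = 210$), so the
stiff chain behaves as a nearly rigid rod; its adsorption proceeds by
slow quasi-rigid rotation rather than the loop-and-zipper pathway of the
production-scale semiflexible chain, and within desk-scale budgets it
stays pinned by a chain end. The desk-scale assertions are therefore
trend statements — adsorbed fraction non-decreasing in $\varepsilon_a$,
and full adsorption requiring stronger attraction at higher stiffness —
not quantitative reproductions of the production-scale critical points.
Those quantitative results (transition points 2.0–5.0 for $b$ =
100–500, bound proportions 0.93/0.64/0.87 at their reference parameter
points, toroid probability above 80% in the moderate regime) are wired
into `run_full_validation()`, which executes the full profile
(hours to days of single-CPU time) and compares against
`full_profile_targets()` at the stated tolerances: one grid step for
transition points, $\pm 0.05$ for proportions.

The synthetic-data side of the test suite — analytic rod, circle,
Archimedean-spiral, helix and self-avoiding-coil fixtures — validates
the observable stack against exact geometry (closed-form direction
cosines, known turn counts, analytic rotation averages). What fixtures
cannot show is sampling correctness; that is covered separately by
quadrature oracles: two- and three-bead systems whose bond-length,
bond-angle and height marginals are computed by numeric integration of
the Boltzmann weight (with the Cartesian $l^2$ Jacobian) and compared to
engine samples at Kolmogorov–Smirnov distance $< 0.02$ with $10^5$
samples. The height oracle adds a reflecting ceiling at $z = 3$ to make
the two-bead system normalisable — without it a finite chain above a
wall has no stationary distribution; the engine exposes this optional
ceiling (`z_max`) for exactly this purpose and it is never used in
production runs.

## Numerical choices

* Infinite energies are the rejection sentinel (`Inf`), never a large
  finite number; FENE range checks happen on squared bond lengths before
  any logarithm.
* The acceptance comparison is $\eta < \min(e^{-\Delta U}, 1)$ with
  $\eta \sim U[0,1)$; $\Delta U \le 0$ short-circuits to certain
  acceptance, so no `exp` overflow path exists.
* Bond-angle cosines are clamped to $[-1, 1]$ before `acos`.
* `G(m)` lags run to $N' - 4$ so every inner sum has at least three
  terms; period counting interpolates across isolated NaN lags and a
  flat or all-NaN curve scores zero (degenerate, not toroidal).
* The energy bookkeeping identity (accumulated $\Delta U$ versus
  recomputed totals) is asserted at $10^{-6}$ relative after every
  sampling block in the tests, guarding against drift in long runs.

## Known limitations

* Single chains only; no solvent, hydrodynamics, curved substrates or
  multi-chain systems.
* The move set is deliberately local (no pivot or regrowth moves): the
  relaxation pathway is part of what the model describes, so faster
  global moves would change the observed kinetics.
* Desk-scale runs at high stiffness are kinetically limited (see above);
  only the full profile is expected to reproduce the quantitative
  transition points.
* The toroid turn counter reports the dominant winding frequency; for
  strongly chirped spirals (inner loops much tighter than outer) the
  spectral peak can smear between adjacent integers, which is why the
  fixture generator keeps loop-radius ratios moderate.
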