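# polyadsorb

Dynamic Monte Carlo simulation of a single semiflexible polymer adsorbing
onto an attractive planar surface, with the full observable suite needed
to map its phase behaviour.

## The problem

How a stiff chain molecule (DNA, actin, synthetic semiflexible polymers)
binds to a flat attractive substrate is controlled by a competition: the
monomer–surface attraction ε<sub>a</sub> favours contact, while the
bending energy *b* resists the deformation that full adsorption demands.
Two questions follow: at which critical ε<sub>a</sub> does the chain go
from partially to fully adsorbed, and what shape does the fully adsorbed
chain take? For long semiflexible chains the answer to the second is a
*film-like toroid* — a flat spiral wound N<sub>t</sub> times — whose turn
count and radius are set by (*b*, ε<sub>a</sub>). This package is for
polymer/biophysics researchers who want to simulate that system, locate
the phase boundary, and quantify the wound state.

## The model

A chain of N+1 beads (energies in k<sub>B</sub>T, lengths in units of the
maximum bond extension):

- **FENE bonds**: U = −½ k r₀² ln[1 − ((l − l₀)/r₀)²], with
  l ∈ (0.4, 1.0), l₀ = 0.7, k = 20;
- **Excluded volume**: Morse pair potential
  ε(e<sup>−2α(r−r<sub>min</sub>)</sup> − 2e<sup>−α(r−r<sub>min</sub>)</sup>),
  α = 24, r<sub>min</sub> = 0.8, ε = 1, truncated beyond unit length;
- **Stiffness**: U<sub>b</sub> = b(1 + cos θ) per interior angle (zero
  when straight);
- **Surface**: a Morse wall of depth ε<sub>a</sub> acting on each bead's
  height z, minimum at z = 0.8.

Kinetics are Metropolis single-monomer displacements drawn from
[−0.15, 0.15]³, accepted with probability min(e<sup>−ΔU</sup>, 1);
N+1 trials are one Monte Carlo step (MCS). Campaigns run independent,
individually seeded replicas with an escape-restart rule for chains that
diffuse away. The inner loop is compiled (Rcpp); energy differences are
evaluated incrementally in O(N) per trial and pinned to full
recomputation at 10⁻⁸ relative tolerance by the test suite.

Observables: monomer height histograms N<sub>m</sub>/P(D), adsorbed
fraction, the bond-direction spatial correlation G(m), the ensemble
tangent–tangent correlation C(s), the surface-energy fluctuation
⟨U<sub>s</sub>²⟩ − ⟨U<sub>s</sub>⟩² (whose peak locates the transition),
and a toroid classifier that counts turns from the dominant frequency of
G(m). See the methods vignette (`vignettes/adsorption-model.Rmd`) for
definitions, conventions and numerical choices.

## Worked example

Grow a stiff chain at moderate attraction, sample it, and classify the
final conformation:

```r
library(polyadsorb)

params <- model_params(n_bonds = 64, b = 50, eps_a = 10)
sched  <- run_schedule(n_replicas = 4, equilibration_mcs = 5e5,
                       n_samples_per_replica = 2,
                       sampling_interval_mcs = 1e5, seed = 1)
ss <- run_ensemble(params, sched)
ss
#> sample_set: 8 samples (65 beads), b = 50, eps_a = 10
#>   replicas: 4 (0 failed), restarts total: 0

mean(sapply(conformations(ss), adsorbed_fraction))
#> [1] 1

classify_toroid(conformations(ss)[[8]])
#> toroid_call: toroid (N_t = 1, score = 239.72, adsorbed = 1.000, extent = 0.057)
```

Every bead is inside the attraction range (adsorbed fraction 1), the
conformation is a quasi-2D film (height extent 0.057, a small fraction
of the bead diameter), and this short stiff chain has closed into a
single-turn ring. The fluctuation-peak machinery
then maps the boundary: `run_sweep()` over a (b, ε<sub>a</sub>) grid,
`locate_transition()` per stiffness, `phase_diagram()` for the boundary
curve and its linear fit. Feeding the production-scale reference
transitions straight through the fitting path:

```r
phase_diagram(full_profile_targets()$transitions)
#> phase boundary (critical eps_a vs b):
#>    b critical_eps_a on_boundary ambiguous
#>  100           2.00       FALSE     FALSE
#>  200           2.75       FALSE     FALSE
#>  300           3.50       FALSE     FALSE
#>  400           4.25       FALSE     FALSE
#>  500           5.00       FALSE     FALSE
#> linear fit: slope = 0.0075, intercept = 1.25; monotone: TRUE
```

The critical attraction grows linearly with stiffness at 0.0075 per unit
bending energy over this range.

A thin command-line front end is installed with the package
(`inst/cli/polyadsorb`) with `simulate`, `sweep`, `fixtures` and
`phase-diagram` subcommands; trajectories are written as plain XYZ and
sample sets as a plain-text directory container.

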