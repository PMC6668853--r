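---
title: "Models and methods in stepfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in stepfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

stepfold studies a single scientific question at desk scale: what does
substituting a bulkier, charge-carrying non-canonical residue (the
motivating case is β-methylamino-L-alanine, BMAA, in place of serine)
do to the stability and dynamics of a folded protein? This vignette
records the models behind each module, the parameters that matter, and
the design decisions taken where more than one reasonable choice
existed.

## Discrete molecular dynamics over step potentials

All dynamics in the package is event-driven. A pair potential is a
staircase in distance: an impenetrable hard core below the innermost
wall, constant shell energies between walls, zero beyond the outermost
wall. Bonds, 1–3 and 1–4 relationships are infinite square wells.
Between events every particle moves ballistically; an event is the
first time any pair reaches one of its walls, obtained in closed form
from $|r + wt| = R$. At a wall, the relative velocity component along
the line of centers either carries the pair across the step — the
radial kinetic energy in the pair frame pays the step height exactly,
so total energy is conserved to floating-point accuracy — or reflects
it elastically. Momentum is exchanged along the line of centers only.

Numerical choices:

* Events closer than $10^{-12}$ reduced time units are rejected as
  already-resolved; ties are broken by scanning pairs in index order,
  which makes runs bitwise reproducible for a fixed seed.
* On resolution the pair is renormalized exactly onto its wall
  (symmetric shift of both atoms, so momentum is untouched) to
  suppress ballistic round-off drift; the running potential energy is
  kept by shell bookkeeping and agrees with a from-scratch recompute
  to much better than $10^{-6}$ kcal/mol.
* The thermostat is Andersen-style: ghost collisions at Poisson times
  (default total rate 0.5 per atom per time unit) redraw one atom's
  velocity from the Maxwell–Boltzmann distribution. This preserves
  canonical sampling and is the convention in event-driven codes; the
  alternative (velocity rescaling) would not.

Reduced units everywhere: energy kcal/mol, length Å, mass amu,
$k_B = 1$ (so temperature carries energy units; one reduced time unit
is $\sqrt{\mathrm{amu}\,\text{Å}^2/(\mathrm{kcal/mol})} \approx 48.9$
fs). Conversion to Kelvin divides by
$k_B = 0.0019872$ kcal/(mol K) and is applied only at reporting.

## The Gō surrogate and what it stands in for

Production all-atom DMD force fields combine discretized
Lennard-Jones, solvation and hydrogen-bond terms with a large
parameter set. None of that is published in reusable form, and a
306-residue dimer is not a desk-scale object, so the folding physics
is carried by a Gō model instead: only pairs in contact in the native
structure (sequence separation ≥ 3, within a cutoff) attract, through
a single square well of depth $-\varepsilon$ spanning ±12% of the
native distance; all other nonbonded pairs are hard spheres (3.6 Å).
Chain connectivity is bond wells (±2%) only — native-shaped 1–3/1–4
wells would pin the chain to its fold and suppress unfolding
altogether, which defeats the purpose of a melting study. (For
all-atom systems `bonded_constraints()` does emit 1–3 wells at ±5%
and 1–4 at ±10%, the conventional stiffnesses.)

`discretize_potential()` is the general bridge from continuous pair
potentials (Lennard-Jones, or an implicit-solvation profile supplied
as samples) to step form: shells take the mean of the continuous
potential, the hard core sits where the potential exceeds 100
kcal/mol, and the sup-norm error decreases monotonically as the shell
count doubles — a property the test suite checks on Lennard-Jones.

## Synthetic study systems

`make_two_state()` is the analytic oracle: a two-level system with
closed-form partition function, mean energy and $C_V(T)$, plus an
exact Boltzmann sampler. Every WHAM and specific-heat code path is
validated against it.

`make_go_peptide()` builds the simulation workhorse: a 20-bead,
one-bead-per-residue chain (bead mass 100 amu, bonds 3.8 Å) in one of
two deterministic fold templates, with a small seeded jitter (0.05 Å)
so different seeds give distinct but reproducible realisations.

* **helix** (default): an α-helix-like spiral (radius 2.3 Å, rise
  1.5 Å, 100°/residue). With the default 8.8 Å cutoff the native map
  contains the $i,i\pm3$, $i,i\pm4$ and $i,i\pm5$ shells (≈47
  contacts), which is what gives a 20-bead object enough cooperative
  native energy to melt inside the standard 16-rung ladder.
* **hairpin**: two strands 5 Å apart (cutoff 7.2 Å, 17 contacts,
  close to the nominal ~15 of a minimal toy). Its inter-strand shear
  mode is soft, which makes per-residue flexibility comparisons
  noisy; that is why the helix is the default for the
  variant-comparison workflows.

`make_modified_variant()` is the coarse-grained image of the
substitution: the site bead (default: the highest-contact-degree
bead, ties toward the chain center) becomes slightly bulkier
(`delta_radius = 0.1` Å added to its hard cores and well inner edges
— steric strain on native packing) and every native well involving it
is shallowed by `delta_eps = 0.6` (to 40% depth — the weakened,
poorly-packing interactions of a side chain that lost its hydroxyl
contacts and carries an unsatisfied charge). These defaults were set,
once, as the mildest modification for which the generator meets its
own contract — a variant with higher low-temperature potential
energy, a lower melting temperature, and elevated flexibility near
the site — robustly across seeds; they are deliberately stronger in
effect than the real single-atom substitution, because a 20-bead toy
needs a resolvable signal where a 306-residue dimer shows ~2 °C.

What the toys do *not* emulate: real side-chain packing, metal sites,
a dimer interface, solvent, or the magnitude of any experimental
quantity. A passing suite demonstrates that the machinery detects a
built-in destabilization with the right signs; it says nothing about
force-field accuracy on real proteins.

## Replica exchange and WHAM

The default ladder is the conventional sixteen reduced temperatures
0.48…0.71 (the `melting_ladder()`); exchanges between neighbouring
rungs alternate even/odd pairing each attempt, with velocities
rescaled by $\sqrt{T_{new}/T_{old}}$ on acceptance. Each replica owns
a seeded RNG stream and swap draws use their own stream, so an entire
REMD run is reproducible. The exchange interval default in the
workflows is 25 reduced time units — short segments mix the small
toys well; the conventional mapping of a 50 ps interval would be
≈1000 units and is configurable.

WHAM iterates
$g(E_m) = \sum_k n_k(E_m) \big/ \sum_k N_k e^{f_k - E_m/T_k}$,
$e^{-f_k} = \sum_m g(E_m) e^{-E_m/T_k}$
in log space with log-sum-exp throughout, to tolerance $10^{-7}$ on
the free energies (cap $10^5$ iterations). Histogram bins default to
Freedman–Diaconis on the pooled sample; non-overlapping supports are
an error rather than a warning, because a disconnected density of
states is meaningless. $C_V(T)$ comes from canonical moments over the
recovered $g(E)$; melting events are local maxima with topographic
prominence at least 10% of the global maximum (enough to separate
localized unfolding shoulders from noise on the toys), and the global
maximum is the major melting event.

Workflow run lengths (40000 time units per replica for melting,
8000–12000 for single-temperature runs, 20% equilibration discard)
are the sizes at which the toy analyses reproduce across seeds; they
were chosen for convergence, and the specific-heat grid (0.40–0.85)
spans the ladder with a margin.

## Trajectory analytics

Superposition is the Kabsch SVD solution restricted to proper
rotations; RMSF and correlated-motion maps use the bead (or Cα)
positions after iterative superposition onto the mean structure (two
rounds). Correlations use the isotropic dot-product convention
$C_{ij} = \langle \Delta r_i \cdot \Delta r_j\rangle /
\sqrt{\langle|\Delta r_i|^2\rangle\langle|\Delta r_j|^2\rangle}$;
zero-variance residues get zeroed rows with a unit diagonal and are
flagged. Difference maps are element-wise with an exactly zero
diagonal.

A square-well caveat worth knowing: inside a flat well there is no
restoring force, so within-well RMSF reflects well width, not
temperature, and the flexibility signal of a weakened site rides on a
substantial baseline. The dynamics comparisons therefore run at
T = 0.40 (cold enough that global unfolding is rare, warm enough that
weakened wells open), and statistical checks pool the five beads
nearest the site over several seeds with run-averaged RMSF profiles.

## Rotamer libraries

The library builder follows the staggered-seed protocol: within each
backbone bin (10° φ/ψ increments → 1296 bins) the χ torsions are
scanned at 30° increments, each grid point is assigned to its nearest
staggered seed (+60/180/−60 per χ; boundary points are split by a
consistent half-open convention so a flat energy yields exactly
uniform probabilities), and each seed's Boltzmann mass gives its
probability with circular means and spreads (the spread is the
directional standard deviation $\sqrt{-2\ln \bar R}$, floored at
$10^{-6}$ degrees). Probabilities are normalized per backbone bin —
the backbone-dependent-library convention — and the Boltzmann
temperature defaults to $k_BT = 0.5917$ kcal/mol (298 K).

The quantum-chemical torsion surface behind the original BMAA
parameterisation is not published; the builder therefore takes any
`energy_fn(phi, psi, chi)` and ships a molecular-mechanics-style
default (`bmaa_torsion_energy()`: threefold barriers, a gauche
preference, mild backbone coupling). `apply_surrogate_spreads()`
implements the lysine-surrogate convention — overwriting χ spreads
and attaching a reference energy from a packaged table; the table is
synthetic (representative magnitudes, labelled as such), not an
extract of any published library.

## ΔΔG by repacking Monte Carlo

The estimator is deliberately simple and fully specified:

* Energy model: the same step-potential machinery as the engine,
  built per system by `build_atomic_table()` — discretized
  Lennard-Jones (six shells to 8 Å, well depth 0.15 kcal/mol,
  radii from element van der Waals sums) plus a screened Coulomb term
  between formal charges (dielectric 20). During repacking only
  nonbonded terms are scored: bond and angle geometry is preserved by
  construction when side chains are rebuilt from templates, and 1–4
  distances legitimately change with χ, so the engine's square-well
  constraints must not act as penalties there.
* Moves: Metropolis at $k_BT = 0.6$ kcal/mol over rotamer swaps at
  the site; flexible mode adds small Gaussian φ/ψ-style rotations
  (σ = 3°, capped ±10°) of the side chain about the N–Cα and Cα–C
  axes. True backbone flexing would propagate down the chain; this
  local approximation keeps the rest of the shell intact and is
  documented as such.
* Reference state: published repacking protocols subtract per-residue
  reference energies that are not available here, so each arm's
  unfolded reference is the same repack run on the extracted
  tripeptide (site ± 1 residue). Identity substitutions then cancel
  exactly, which the tests assert.
* Protocol: per round, wild-type and mutant arms are repacked
  `n_sims` times (minimum kept) over the 8 Å shell; the round's ΔΔG
  is the paired difference, and the estimate is mean ± SD over
  `n_rounds` (paired arms per round reduce variance). The defaults
  follow the 20 × 20 × 20 convention; tests and workflows use smaller
  budgets.

For the ordering property "bulky + charged ≫ conservative
same-charge" the conservative control is DAP
(2,3-diaminopropionic acid) — BMAA minus its N-methyl group, same +1
amine, one χ. With a generic LJ-plus-screened-Coulomb score, lysine
cannot serve as that control on a toy pocket: sterically its chain
sweeps a superset of BMAA's shells, so any pocket that catches BMAA
catches lysine harder. The lysine comparison of the full
serine-scan report is retained at workflow level, without an ordering
guarantee on toys; reproducing its pattern quantitatively requires
the packing context of a real protein core and a transferable force
field, both out of scope.

## Known limitations

* The Gō variant's parameters encode destabilization by construction;
  the pipeline measures *that the machinery resolves it*, not a
  prediction about BMAA chemistry.
* Melting temperatures of 20-bead toys carry seed-to-seed and
  sampling variability of order 0.01–0.05 reduced units; the
  wild-type/variant comparison is an ordering statement at matched
  seeds, not a calibrated shift.
* The repacking energy model has no solvation, torsional or
  hydrogen-bond terms beyond what the rotamer probabilities encode.
* No mmCIF input, no crystal-symmetry handling, no automatic
  protonation; hydrogens are built only where templates define them.
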