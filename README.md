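# stepfold

Desk-scale molecular simulation machinery for studying how a
non-canonical amino-acid substitution destabilizes a protein fold. The
motivating system is the misincorporation of the cyanobacterial toxin
β-methylamino-L-alanine (BMAA, side chain CH₂–NH₂⁺–CH₃) in place of
serine in Cu,Zn superoxide dismutase (SOD1), a scenario relevant to
ALS; the package provides every computational layer of that analysis
as tested, reusable R code, exercised on synthetic systems small
enough to run on a laptop.

## What it implements

* **Event-driven discrete molecular dynamics (DMD).** Pair
  interactions are piecewise-constant in distance ("step" or
  square-well potentials, with infinite square wells for bonds);
  particles move ballistically between events and exchange impulses
  along the line of centers at each wall, with total energy conserved
  exactly on crossings (`run_dmd()`, C++ core). An Andersen-style
  thermostat provides canonical sampling.
* **Gō-model construction.** `build_go_model()` turns a native bead
  structure into an interaction table in which only native contacts
  (|i−j| ≥ 3, within a cutoff) attract — square wells of depth −ε
  around the native distance — giving tunable, cooperative folding.
* **Temperature replica exchange (REMD).** `run_remd()` runs one
  replica per rung of a temperature ladder (default: the standard
  16-rung ladder 0.48 → 0.71 kcal/(mol·k_B), ≈242 → 357 K) and swaps
  neighbouring temperatures by the Metropolis rule
  accept ⇔ u < min(1, e^Δ), Δ = (1/Tᵢ − 1/Tⱼ)(Eᵢ − Eⱼ).
* **WHAM melting analysis.** `wham()` combines multi-temperature
  energy histograms into a density of states g(E) by the
  self-consistent equations, and `specific_heat()` evaluates
  C_V(T) = (⟨E²⟩−⟨E⟩²)/k_B T² whose peaks (`find_melting_events()`)
  mark melting transitions.
* **Trajectory analytics.** Kabsch superposition and RMSD
  (`superpose()`), per-residue RMSF (`rmsf()`), and normalized
  correlated-motion maps Cᵢⱼ = ⟨Δrᵢ·Δrⱼ⟩/√(⟨|Δrᵢ|²⟩⟨|Δrⱼ|²⟩)
  with wild-type/variant difference maps (`difference_map()`).
* **Backbone-dependent rotamer libraries for non-canonical residues.**
  `build_rotamer_library()` scans the χ torsions of a residue on a
  grid within each (φ, ψ) bin (10° backbone increments → 36 × 36 =
  1296 bins; 30° χ increments), pools Boltzmann mass onto the 3^n_chi
  staggered seeds, and records circular means, spreads and
  probabilities.
* **ΔΔG by repacking Monte Carlo.** `estimate_ddg()` repacks the
  mutation site over its rotamers inside an 8 Å shell, in fixed- or
  flexible-backbone mode, with a repacked tripeptide as the
  unfolded-state reference; results are mean ± SD over independent
  rounds (positive = destabilizing), and `serine_scan()` produces the
  per-serine report table.
* **Synthetic generators.** `make_two_state()` (analytic two-level
  oracle with exact C_V), `make_go_peptide()` /
  `make_modified_variant()` (foldable bead peptide and its
  destabilized variant: bulkier site bead, shallowed native wells),
  `make_ser_peptide()` and `make_packed_pocket()` (all-atom fixtures).

Everything tabular comes back as a tibble; result objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Recover the thermodynamics of an exactly solvable two-level system
(ground state non-degenerate, excited level at ΔE = 2 kcal/mol with
degeneracy 50) from sampled energies alone:

```r
library(stepfold)
ts <- make_two_state(E0 = 0, E1 = 2, g0 = 1, g1 = 50)
set.seed(42)
temps <- c(0.35, 0.5, 0.7, 1.0)
prof <- wham(energy_histograms(
  lapply(temps, function(T) ts$sample(T, 1e5)), temps, bin_width = 1))
glance(prof)
#> # A tibble: 1 × 5
#>   t_melt t_melt_kelvin n_peaks iterations     residual
#>    <dbl>         <dbl>   <int>      <int>        <dbl>
#> 1  0.416          209.       1         16 0.0000000348
```

The recovered Schottky peak at T = 0.416 matches the closed-form
maximum of C_V(T) (0.4167) to a fraction of a percent, and the
recovered ln g(E₁)/g(E₀) is ln 50 within sampling error.

The full melting comparison — wild-type Gō peptide vs its
destabilized variant, REMD over the 16-rung ladder, WHAM, peak
detection and low-temperature energy histograms:

```r
rep <- run_melting_workflow(stepfold_config(seed = 1))
rep
#> <melting_report>
#>   T_m(WT)      = 0.5440 (274 K)
#>   T_m(variant) = 0.5380 (271 K)
#>   delta T_m    = +0.0060
#>   modal PE     : WT -55.25, variant -49.25 kcal/mol
```

The variant melts at a strictly lower temperature and rests at a
higher (less favourable) modal potential energy — the toy-scale
signature of a destabilizing substitution.

Stability change of a bulky, charged substitution in a crowded
pocket, by repacking Monte Carlo:

```r
pk <- make_packed_pocket()
libs <- standard_rotamer_set(phi_increment = 180)
estimate_ddg(pk$system, pk$chain, pk$resno, "BMAA", libs,
             n_rounds = 5, n_sims = 4, n_mc = 40, seed = 1)
#> <ddg_result> SER2A -> BMAA (fixed backbone): ddG = 13.38 +/- 0.00 kcal/mol over 5 rounds
```

The same call with the conservative same-charge control (`"DAP"`, the
demethylated analogue) gives ≈ 0, reproducing the
bulky-substitution-destabilizes pattern.

A thin command-line front end for shell use ships in
`inst/cli/stepfold` (subcommands `synth`, `mutate`, `dmd`, `remd`,
`wham`, `ddg`, `rotlib`, `run`).

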