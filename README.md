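# poreblock

Tools for deciding whether general anesthetics plug the pore of a
pentameric ligand-gated ion channel — and at what concentration.

Channels like GLIC (the proton-gated prokaryotic relative of nicotinic and
GABA-A receptors) are inhibited by isoflurane and propofol at micromolar
concentrations. One candidate mechanism is direct pore block: one or two
anesthetic molecules lodge between the gate isoleucines (9′/16′ on the M2
helices) and occlude conduction. Alchemical free-energy simulations can
measure the microscopic affinity of each occupancy state, but connecting
those numbers to an electrophysiological dose-response curve takes a chain
of post-processing that this package implements:

* **Free-energy bookkeeping** — assemble absolute binding free energies
  from alchemical insertion terms with solvation, standard-state
  restraint-volume (−kT ln V/V₀, V₀ = 1661 Å³) and symmetry (kT ln σ)
  corrections; interconvert with dissociation constants
  (K_d = 1 M · e^{ΔG/kT}); classify cooperativity.
* **FEP estimation** — exponential averaging and the Bennett acceptance
  ratio (BAR) per λ window, window combination along fine/coarse λ
  schedules, replicate pooling, and the bidirectional
  (decoupling/recoupling) error convention.
* **Pore-block dose response** — the modified Adair model
  I(x) = α·p₁(x) + p₂(x), where p₁, p₂ are sequential-binding occupancies
  from stepwise constants K_d1, K_d2 and α is the probability that a lone
  monomer blocks. IC50 as the exact root of I = 1/2, closed-form bounds at
  α ∈ {0, 1}, and least-squares fitting of observed curves.
* **Pore geometry** — pore center/axis from anchor Cα atoms, M2
  non-adjacent pair distances, Boltzmann-transform free-energy profiles,
  flat-bottom restraint design, axial ligand density with mass-preserving
  three-bin smoothing, prime-notation site occupancy.
* **Synthetic data** — seeded generators with known ground truth for every
  input class (Crooks-consistent FEP samples, Metropolis toy-pore
  trajectories, Gaussian-mixture distance series, noisy dose-response
  curves, idealized pentamers).

The packaged table `inst/extdata/glic_binding_tables.tsv` ships the
published per-site free-energy components, binding totals, dissociation
constants and IC50 ranges used as reference points throughout the tests.

## Worked example

From closed-pore isoflurane component terms to a predicted IC50 range:

```r
library(poreblock)
ctx <- thermo_context()          # 300 K, kT = 0.5962 kcal/mol, V0 = 1661 A^3

comp <- free_energy_components(
  solvation = -0.2, symmetry = 0, restraint_volume = -0.3,
  site_insertion_1 = -7.5, site_insertion_1_err = 0.2,
  site_insertion_2 = -5.5, site_insertion_2_err = 0.4)
(res <- combine_binding_free_energy(comp, ctx))
#> Binding result (300 K)
#>   dG_bind,1 = -7.60 +/- 0.20 kcal/mol   Kd1 = 2.9 uM
#>   dG_bind,2 = -5.60 +/- 0.40 kcal/mol   Kd2 = 83 uM

cooperativity(res$kd1, res$kd2)
#> [1] "negative"

ic50_range(res$kd1 * 1e6, res$kd2 * 1e6)   # micromolar
#>       low      high
#>  2.812398 86.079966
```

The second molecule binds ~30-fold more weakly than the first (negative
cooperativity), and the model brackets the IC50 between 2.8 µM (a monomer
suffices to block, α = 1) and 86 µM (a dimer is required, α = 0) — a range
containing the measured 60 µM.

The FEP side, on synthetic samples with a known −7.6 kcal/mol truth:

```r
truth <- fep_ground_truth(total_delta_g = -7.6, sigma = 1,
                          n_samples = 5000, seed = 1)
estimate_stage(gen_fep_samples(truth), "bar")
#> dG = -7.6388 +/- 0.0532 kcal/mol  [bar, 25 windows]
```

A thin command-line wrapper (`inst/scripts/poreblock`) exposes the same
operations as subcommands (`predict-ic50`, `combine-fep`, `fit-dose`,
`analyze-density`, `pore-distances`, `design-restraints`, `simulate-*`,
`make-fixtures`, `run`); `run_pipeline()` chains FEP samples → ΔG → K_d →
IC50 from a single YAML config.

See `vignettes/pore-block-model.Rmd` for the model assumptions, parameter
defaults and numerical design decisions.

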