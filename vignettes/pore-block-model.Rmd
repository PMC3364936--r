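---
title: "From microscopic pore affinities to dose response: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From microscopic pore affinities to dose response: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreblock)
```

## The scientific problem

General anesthetics such as isoflurane and propofol inhibit cation-selective
pentameric ligand-gated ion channels. One candidate mechanism is direct pore
block: one or two anesthetic molecules lodge in the hydrophobic upper half of
the transmembrane pore, between the gate isoleucines at positions 9′ and 16′
of the M2 helices, and occlude conduction. Testing this hypothesis
quantitatively requires three pieces of machinery, all provided here:

1. **bookkeeping** that turns raw alchemical insertion free energies into
   absolute binding free energies and dissociation constants,
2. **estimation** of those insertion free energies from bidirectional
   free-energy-perturbation (FEP) samples, and
3. a **dose-response model** that maps the microscopic stepwise constants
   onto the macroscopic half-inhibition concentration (IC50) measured by
   electrophysiology.

Because per-window FEP samples and pore trajectories from the original
simulations are not deposited anywhere, the package also contains seeded
generators that produce every input class with known ground truth, so the
whole pipeline is testable end to end.

## Absolute binding free energies

The total microscopic free energy of binding the $n$-th ligand is assembled
as

$$\Delta G_{bind,n} = \Delta G_{FEP,n} - \Delta G_{solv} + \Delta G_V +
\Delta G_{sym},$$

where $\Delta G_{FEP,n}$ is the free energy of moving the ligand from vacuum
into the (unoccupied or singly-occupied) site, $\Delta G_{solv}$ its
solvation free energy, $\Delta G_V = -kT\ln(V_{site}/V_0)$ the entropic cost
of confining the ligand to the flat-bottom binding-site restraint relative
to the $V_0 = 1661$ Å³ free volume per molecule of a 1 M solution, and
$\Delta G_{sym} = kT\ln\sigma$ the penalty for losing the $\sigma$
indistinguishable orientations of a symmetric ligand (0.4 kcal/mol at 300 K
for twofold-symmetric propofol or ethanol — exactly a factor of two in
affinity). Dissociation constants follow from the standard-state relation
$K_d = (1\,\mathrm{M})\,e^{\Delta G_{bind}/kT}$.

Two deliberate conventions, fixed here because published component tables
often lose operator signs to typesetting, deserve note:

* the sign convention above treats $\Delta G_{FEP}$ as a vacuum→site
  *insertion*; its validity is checked not term-by-term but through the
  total→$K_d$ correspondence, which reproduces all ten published
  dissociation constants to two significant figures from the published
  totals;
* uncertainty propagation treats $\Delta G_{solv}$, $\Delta G_V$ and
  $\Delta G_{sym}$ as exact (no published uncertainties exist for them), so
  the standard error of a total equals that of its FEP term.

Temperature defaults to 300 K, the thermostat setting of the underlying
simulations; $kT$ is reported to four significant figures
(0.5962 kcal/mol). Dissociation constants are stored in molar and
auto-scaled (M/mM/µM) only for display.

## FEP estimation

Per-window energy differences $\Delta U = U(\lambda_{high}) -
U(\lambda_{low})$, sampled in both bounding ensembles, are combined by the
Bennett acceptance ratio (BAR), the minimum-variance two-state estimator.
The implementation solves the self-consistency condition on its log-sum
form — which is monotone in $\Delta G$ — by bracketed root finding on
$[-50, +50]$ kcal/mol to a tolerance of $10^{-8}$ kcal/mol, making the
estimate deterministic given the samples. The quoted per-window standard
error is the standard BAR asymptotic variance. One-sided exponential
(Zwanzig) averaging is provided as a baseline; on synthetic data BAR is
never less efficient, as its theory requires.

Window totals add along the coupling path, with errors in quadrature under
window independence. The default λ schedule uses a step of 0.025 on
$[0, 0.25]$ and 0.05 elsewhere — 25 windows per stage. The published
protocol states the two step sizes and the 25-windows-per-stage count but
the printed bounds of the fine region did not survive typesetting; the
placement at the decoupling end is this package's choice and is
configurable.

Two further conventions follow the published protocol:

* **replicate pooling**: repeated runs of the same stage are concatenated
  into one sample set per window before estimation;
* **bidirectional combination**: the decoupling and recoupling stage totals
  (the latter sign-normalized to the binding direction) are averaged, and
  the quoted standard error is half their absolute difference. This is a
  two-point spread convention, not an asymptotic variance, and is kept
  because it is how the published uncertainties are defined.

The backward one-sided estimator is $+kT\ln\langle
e^{+\Delta U/kT}\rangle_{high}$ (not the forward formula applied blindly):
with $\Delta U$ defined once as $U_{high}-U_{low}$, that is the form whose
expectation is the window free energy, and it is the convention under which
the Crooks-consistent generator makes both directions converge to the same
truth.

## The modified Adair pore-block model

With stepwise dissociation constants $K_{d1}$ (empty→single) and $K_{d2}$
(single→double), the probabilities of 0, 1, 2 ligands in the pore at free
concentration $x$ come from the partition function $Z = 1 + x/K_{d1} +
x^2/(K_{d1}K_{d2})$. A dimer always blocks; a monomer blocks with
probability $\alpha \in [0,1]$, the model's only free parameter, so
fractional inhibition is $I(x) = \alpha p_1(x) + p_2(x)$.

$I$ rises strictly from 0 to 1, so the IC50 is the unique root of
$I(x) = 1/2$. At the physical extremes of $\alpha$ the condition reduces to
a quadratic with one positive root ($x^2 \pm K_{d2}x - K_{d1}K_{d2} = 0$;
$+$ for $\alpha = 1$, $-$ for $\alpha = 0$), and those radicals bound the
predicted IC50 range. The general-α solver uses bracketed bisection with a
geometrically grown upper bracket (factor 10 from $K_{d1}$); it matches the
closed forms to $10^{-9}$ relative at the extremes. A published approximate
closed form for intermediate α exists but its printed version is
unrecoverable; the exact root is primary here, and the α ∈ {0, 1} radicals
reproduce all eight published range bounds from the published constant
pairs, which validates the solver.

The constants are treated as macroscopic stepwise constants without
per-site statistical factors — the treatment under which the published
$\Delta G \leftrightarrow K_d$ correspondence holds. The model is
scale-invariant (joint rescaling of $K_{d1}$, $K_{d2}$ and the dose axis
leaves $I$ unchanged, which is tested), so concentrations carry whatever
unit the caller uses.

`fit_dose_response()` inverts the model: uniform-weight least squares by
Levenberg–Marquardt on log-scaled constants, multistarted from a
deterministic log-spaced grid (3×3 constants × 2 α starts) to avoid local
minima. Weights are uniform because no heteroscedastic error model for the
underlying electrophysiology is available.

```{r ic50-example}
# closed-pore isoflurane constants, micromolar
ic50_range(2.9, 83)
```

## Pore geometry and density

* **Pore center and axis.** The center is the unweighted mean of the ten
  anchor alpha-carbons (Tyr 226/244 across the five subunits). No published
  axis definition exists; the axis here is the leading principal direction
  of those ten atoms, oriented extracellular-positive, and the z origin is
  the pore center.
* **M2 pair distances.** Per subunit, the geometric center of the
  alpha-carbons of residues 232–245; distances between the five
  non-adjacent pairs of the pentagon, normalized to
  {1-3, 1-4, 2-4, 2-5, 3-5}. (The published list prints "3-2", an adjacent
  pair inconsistent with its own "all pairs of non-adjacent subunits"; it
  is read as 3-5.)
* **Boltzmann profiles.** $-kT\ln$ of the histogram, minimum shifted to
  zero; empty bins are flagged undefined, never zero-filled. Default bin
  width 0.5 Å for distances and densities (0.1 Å is used in tests where
  curvature matters).
* **Flat-bottom restraint design.** The wall is placed at the barrier-side
  edge of the open basin: the largest distance below the basin minimum
  where the profile exceeds that minimum by a margin (default 1 kT). The
  basin minimum is sought within ±1 Å of the stated center — narrow enough
  to exclude the collapsed basin ~1.5 Å away; both the margin and the
  window are configurable. A single-well profile is rejected: without a
  barrier a wall would bias the landscape it is meant to preserve. The
  default force constant is 10 kcal/mol/Å², the printed order of
  magnitude. The published wall position and constant themselves did not
  survive typesetting, so the defaults are anchored to the described
  "open basin around 20 Å / collapsed below 19 Å" picture.
* **Axial density.** $\rho(z) = n\,P(z)/\Delta z$ with ligand positions
  pooled when two are present (the published per-ligand vs pooled choice is
  unstated; pooled is adopted). Smoothing is the published three-bin
  running average, implemented as redistribution: each bin exports one
  third of its mass to each existing neighbour and keeps what has no
  neighbour. In the interior this is the ordinary centered mean; at the
  edges the window shrinks without losing mass, so
  $\sum\rho\,\Delta z = n$ holds exactly before and after smoothing. The
  grid is padded by one empty bin per side so edge mass has somewhere to
  spread.
* **Prime notation.** `prime = residue − 223`, the affine map fixed by the
  two printed anchors 232→9′ and 239→16′, valid on the M2 span 223–245.

## What the synthetic generators emulate — and what they do not

* `gen_fep_samples()` draws forward/backward energy differences from the
  Gaussian Crooks-consistent pair
  $N(\Delta G \pm \sigma^2/2kT,\, \sigma^2)$. This makes BAR recovery
  well-posed with an exact known truth, and the empirical forward/backward
  log-density ratio is linear in work with slope $1/kT$ (tested,
  $R^2 > 0.99$). Real FEP output is not Gaussian — soft-core end windows
  are skewed, samples are autocorrelated, and equilibration transients
  exist. Passing recovery tests therefore validates the estimator algebra
  and its statistics, not robustness to non-Gaussian pathology.
* `gen_pore_trajectory()` samples a 1-D multi-well toy pore by Metropolis
  Monte Carlo, mixing auto-tuned local steps (30–50% acceptance, tuned and
  discarded during a 10% burn-in) with occasional uniform jump proposals
  that decorrelate hopping between deep wells; both proposals are
  symmetric, so the Boltzmann target is exact. A soft Gaussian repulsion
  between two ligands reproduces the dimer "shoulder" phenomenology. It is
  a 1-D caricature: no orientational degrees of freedom, no solvent, no
  coupling to pore breathing.
* `gen_distance_series()` is a two-component Gaussian mixture emulating the
  open (~20 Å) vs collapsed (<19 Å) distance distribution; real distance
  traces are autocorrelated and non-Gaussian.
* `gen_dose_response()` evaluates the exact model on a log-spaced grid and
  adds truncated Gaussian noise clipped to [0, 1]; an odd point count puts
  the central grid point exactly at the IC50.

All generators are bit-reproducible under their integer seed, using R's
default Mersenne-Twister stream.

## Numerical choices and problem sizes

Statistical tests in the suite run at sizes chosen to make their error
bars decisive while keeping the full suite fast: BAR recovery uses the
25-window default schedule at 5000 samples per direction per window;
efficiency and consistency properties use 2000-sample windows over 10
seeds and an $n$-ladder from $10^2$ to $10^5$; profile-curvature and
Crooks-slope checks use $10^5$ samples; the dose-response noise study uses
50 seeds of 12-point curves at noise σ = 0.02; toy-pore occupancy uses
40 000 frames, compared against a numerically integrated Boltzmann target
with batch-means (not iid) error bars, since Metropolis samples are
correlated.

Other numerical decisions: BAR bracket $[-50, 50]$ kcal/mol and tolerance
$10^{-8}$ kcal/mol; IC50 bisection tolerance $10^{-10}$ relative with
lower bracket $10^{-12}K_{d1}$; λ-grid validation to $10^{-9}$;
histogram grids aligned to multiples of the bin width; contiguity of
combined windows checked to $10^{-9}$ in λ.

## Known limitations

* The package post-processes simulation output; it does not run molecular
  dynamics, parameterize ligands, or assign protonation states.
* The bidirectional error convention (half the decoupling–recoupling gap)
  is a two-point spread; with only two stages it is a crude variance
  estimate and can be zero by coincidence.
* The dose-response model ignores allosteric potentiation entirely; where a
  competing gain-of-function site is occupied, the pore-block model alone
  is expected to overestimate inhibition (this is precisely the published
  interpretation for propofol, whose predicted IC50 range lies below the
  measured 24 µM).
* `ic50_range()` bounds assume the dimer always blocks; if that assumption
  fails the upper bound is not conservative.
* The PDB reader handles single-model ATOM records through `bio3d`;
  multi-model trajectory formats (DCD/XTC) are out of scope, and ligand
  trajectories are expected as plain CSV.
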