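---
title: "Thermodynamic and kinetic stability descriptors for amorphous solid dispersions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic and kinetic stability descriptors for amorphous solid dispersions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asdstab)
```

## The problem

An amorphous solid dispersion (ASD) keeps a poorly soluble drug (the
active pharmaceutical ingredient, API) molecularly dispersed in an
amorphous polymer matrix.  The formulation's weak point is physical
stability: the amorphous phase is metastable and will, sooner or later,
phase-separate and crystallize.  Two different physical factors can set
the *relative* stability of one drug across candidate polymers:

* **thermodynamics** — how favourable mixing is, measured by the energy
  of the blend relative to the pure amorphous phases;
* **kinetics** — how mobile the drug molecules are inside the matrix,
  measured by translational diffusion and by local roto-vibrational
  motion.

`asdstab` computes both families of descriptors from molecular dynamics
trajectories of drug–polymer blends, aggregates them over replicate
simulations, and correlates them with experimental amorphicity indices
(AI, a 0–100 score of residual amorphous content after storage; higher
is more stable) to decide which factor is rate limiting for a given
drug.  The package ships the published composition and descriptor
tables for blends of flufenamic acid (FLA) and phenacetin (PAC) with
four polymers (EEC, PAA, PSA, PVP), and a synthetic-trajectory module
so every analysis stage can be exercised and validated without an MD
engine.

Units follow the GROMACS convention throughout: nm, ps, amu, elementary
charges, kJ/mol.  Boxes are orthorhombic; triclinic cells are out of
scope.

## The energy model

Configurational energies use the classical force-field decomposition

$$E_\mathrm{tot} = E_\mathrm{bond} + E_\mathrm{angle} + E_\mathrm{dih}
  + E_\mathrm{LJ} + E_\mathrm{Coul},$$

with harmonic bonds and angles, periodic cosine dihedrals,
Lennard–Jones interactions under Lorentz–Berthelot combining, and
Coulomb interactions.  Bonded neighbours at one or two bonds (1–2,
1–3) never interact non-bonded.  1–4 pairs follow the Amber/GAFF
convention: they are excluded entirely from the reported non-bonded
energy `e_nb`, but enter `e_tot` with scaled interactions (Coulomb
divided by 1.2, LJ divided by 2).  Both conventions are exposed because
published totals rarely state which was used.

Three Coulomb evaluators share one interface: `direct` (non-periodic
all-pairs), `minimum_image` (periodic nearest image within a cutoff,
default 0.9 nm) and `ewald`.  The Ewald path is classic Ewald
summation — real-space, reciprocal-space and self terms, with excluded
pairs removed by an explicit erf correction — rather than a
mesh-interpolated (PME) variant: for the system sizes this package
analyses, classic Ewald is mathematically the same target and is
exactly testable against lattice sums.  The splitting width and
reciprocal cap are chosen from a target relative accuracy (default
1e-5): with $s = \sqrt{-\ln \epsilon}$, $\alpha = s/r_c$ and
$k_\mathrm{cut} = 2\alpha s$.  The implementation reproduces the
rock-salt Madelung energy ($-\alpha_M k_e / r_{nn}$,
$\alpha_M = 1.747565$) to about 1e-6 relative.  Non-neutral systems
warn and receive the uniform background-charge correction.  The
optional LJ dispersion tail correction assumes uniform density beyond
the cutoff and is strictly negative for attractive systems; it
requires a cutoff larger than the largest $\sigma$.

### Intermolecular Coulomb energies by charge zeroing

Under Ewald electrostatics the Coulomb energy cannot be split into
molecular pair contributions, so the intermolecular part is extracted
by re-evaluating each configuration three times: with the original
charges, with the charges of the molecule of interest zeroed, and with
all *other* charges zeroed.  Because every Coulomb term is quadratic
in the charge vector, the cross term

$$E_\mathrm{cross} = E_\mathrm{full} - E_{-\mathrm{mol}} - E_{\mathrm{mol\ only}}$$

is exactly the molecule's interaction with the rest of the system, for
any quadratic method.  `species_intermolecular_coulomb()` applies this
per molecule and aggregates without double counting; with
`species = "all"` it yields the system's total intermolecular Coulomb
energy — inter- but no intra-molecular contributions.  The tests
verify the decomposition against brute-force cross-molecule pair
summation at 1e-6 kJ/mol on random many-molecule systems.

## Mixing energies

`mixing_energy()` references a blend to *the same number of molecules
in the pure amorphous phases*:
$\Delta E = E_\mathrm{blend} - (N_\mathrm{api}\,e_\mathrm{api} +
N_\mathrm{pol}\,e_\mathrm{pol})$, with pure-phase energies stored per
API molecule / per polymer chain (pure-system trajectory averages
divided by the molecule count).  Three normalizations are attached —
raw per simulation cell, per volume (kJ/mol/nm³) and per API molecule
— because none is canonically "right" for samples of different size;
positive scalings never change sign or within-term ranking, which
`energy_trend()` checks explicitly.  Trajectory averages default to
the final 40 % of frames (`window_frames()`), reflecting the practice
of averaging late-time windows once relative energies have settled;
the window is a caller-visible parameter.

The bundled descriptor table reports the raw normalization
(kJ/mol per simulation cell), the basis its source is most consistent
with.

## Hydrogen bonds

`find_hbonds()` uses the common geometric criterion: donor–acceptor
distance ≤ 0.35 nm (minimum image) and hydrogen–donor–acceptor angle
≤ 30°.  Note the angle vertex is the **donor heavy atom**, not the
hydrogen — conventions differ between analysis tools and this choice
matches the 30° default's origin.  Donors are N/O with a covalently
bound H (the flag is derived from the bond graph and can be
overridden), acceptors are N/O; fluorine is not an acceptor unless
flagged explicitly.  Counts are monotone in both cutoffs and invariant
under rigid motion and periodic shifts, and `delta_nhb()` forms the
mixing difference with pure-phase counts scaled by molecule-count
ratios.  In systems dominated by hydrogen bonding, ΔNHB is expected to
anti-correlate with the Coulomb mixing energy; the synthetic blends
reproduce that sign relation by construction.

## Mobility descriptors

**Diffusion.**  `msd()` computes the multiple-time-origin mean squared
displacement of molecular centers of mass (mass-weighted), which
requires unwrapped coordinates — `unwrap_trajectory()` accumulates
minimum-image displacements and refuses trajectories whose sampling is
too sparse (a step of half a box edge is ambiguous).
`diffusion_coefficient()` fits a least-squares line over 10–50 % of
the maximum lag by default (configurable; the fit r² is always
reported so ballistic or plateau regimes are visible) and applies the
3-D Einstein relation $D = \mathrm{slope}/6$, converted to the
conventional unit of $10^{-10}\,\mathrm{cm^2/s}$
($1\,\mathrm{nm^2/ps} = 10^{-2}\,\mathrm{cm^2/s}$).

**RMSF.**  Following the splitting of mobility into translational and
higher-order (roto-vibrational, secondary-relaxation) parts, `rmsf()`
moves each molecule's center of mass to the origin frame by frame —
keeping conformation and orientation intact, with no rotational
superposition — and averages each atom's root mean square fluctuation
about its mean position over all heavy (non-hydrogen) atoms of all
molecules of the species, unweighted.

**Replicates.**  Production analyses average four independent
simulations; `replicate_stats()` reports the arithmetic mean and the
*sample* standard deviation (n−1 denominator, the usual error-bar
convention).

## Ranking and the limiting factor

`descriptor_range()` reports the spread (max − min) of a descriptor
across one API's polymers; on the bundled table it reproduces the
published spreads (about 8620 kJ/mol and 4535 kJ/mol for the Coulomb
mixing energies of FLA and PAC, and 0.8 and 2.5 ×10⁻¹⁰ cm²/s for
their diffusion coefficients).  The API whose stability is energy
governed shows the wider energy range; the mobility-governed API shows
the wider mobility range.

`descriptor_stability_association()` uses Spearman rank correlation
against AI (robust to the AI ceiling at 100; ties get mid-ranks), with
Pearson reported alongside.  The stability-favourable direction is
negative for both families: lower mixing energy → higher AI, lower
mobility → higher AI.

`classify_limiting_factor()` had to make a genuinely open design call:
the source analysis argues qualitatively, with no numeric rule.  The
rule adopted here scores each descriptor by its rank correlation taken
in the documented favourable direction and floored at zero,
$s = \max(0, -\rho)$, so a descriptor that correlates the "wrong" way
contributes no evidence rather than competing on magnitude; the
classification requires one score to exceed the other by a threshold
(default 0.3, exposed).  The floor matters in practice: on the bundled
table the PAC energy descriptor correlates *positively* with AI
(ρ = +0.21), and comparing absolute correlations would call PAC
indeterminate, while the directional rule recovers the expected
kinetic classification (mobility score 0.32 vs energy 0).  When
replicate spreads are available, a descriptor whose per-polymer values
all mutually overlap within one standard deviation is treated as
non-discriminating; without spreads the screening is skipped with a
warning.  Because the rule is rank-based it is invariant under unit
changes.

```{r ranking-example, eval = FALSE}
t2 <- asd_descriptors()
descriptor_range(t2, "FLA", "dE_coul")          # 8617.5 kJ/mol
classify_limiting_factor(t2, "FLA")$classification  # "thermodynamic"
classify_limiting_factor(t2, "PAC")$classification  # "kinetic"
```

## Composition bookkeeping

`molecular_mass()` uses the IUPAC 2021 standard atomic weights
(conventional values where an interval is defined); the table is
embedded because weight-percent arithmetic at the 0.1 % level is
insensitive to the choice.  `api_weight_percent()` and
`weight_percent_check()` recompute the published blend table: the
EEC, PAA and PVP rows agree within 0.05 percentage points, while the
PSA rows are internally inconsistent — the printed weight percent
matches $N_\mathrm{api} M / (N_\mathrm{api} M + m_\mathrm{pure\,PSA})$
rather than the printed total mass.  The check reports both values and
forces agreement with neither.  `enumerate_blends()` builds the
API × polymer × drug-load Cartesian product, choosing the integer API
count that minimizes the deviation from the target weight percent.

Polymer chain masses are taken from explicit molecule topologies
(including end groups) rather than inferred from monomer weights; the
end-group composition of the published systems is unstated, so
pure-polymer masses are not treated as exact reproduction targets.

## What the synthetic generators emulate — and what they do not

The generators produce statistically exact samples rather than
integrated dynamics, removing integrator error from parameter-recovery
tests:

* `gen_brownian()` — independent Gaussian steps with per-axis variance
  $2 D_\mathrm{in} \Delta t$; defaults (95 molecules, 2 ps frames,
  $D = 10^{-10}\,\mathrm{cm^2/s}$) mirror the shape of a production
  blend.  Recovery tests use 100 molecules × 10⁴ frames × 4
  replicates and recover $D_\mathrm{in}$ within a few percent.
* `gen_harmonic()` — i.i.d. Gaussian fluctuations about fixed sites.
  The prescribed variance $kT/k$ refers to the fluctuation *in the
  molecule's center-of-mass frame*, the quantity RMSF measures:
  subtracting the COM of $n$ equal-mass i.i.d. atoms shrinks the
  per-atom variance by $(1 - 1/n)$, so raw draws are scaled by the
  inverse factor and $\sqrt{3kT/k}$ is the exact ground truth at any
  molecule size.
* `gen_hbond_fixture()` — donor–H–acceptor triples at exactly the
  requested distance and angle.
* `gen_toy_blend()` / `gen_toy_pure()` — a hand-packed periodic blend
  of a donor-bearing API against an acceptor-only polymer (the
  configuration that makes mixing energetically favourable: strong
  cross hydrogen bonds that do not compete with any polymer–polymer
  donors), jittered over frames and replicated with four seeds.
* `gen_rocksalt()` and `gen_random_charged()` — analytic and
  brute-force-checkable electrostatic fixtures.

Passing tests on these generators validate the estimators —
unwrapping, MSD/Einstein fitting, COM-frame RMSF, H-bond geometry,
energy decomposition — under known ground truth.  They do **not**
emulate realistic amorphous packing, force-field realism, glassy aging
or the slow, correlated dynamics of real blends; published per-blend
descriptor values required microsecond-scale production simulations
and enter this package as input data, not as desk-scale reproduction
targets.

## Numerical choices and degenerate inputs

* Coulomb constant $k_e = 138.935458$ kJ mol⁻¹ nm e⁻²; all unit
  conversions live in `md_constants` and are unit-tested.
* Cutoffs must not exceed half the smallest box edge; charged pairs
  closer than 1e-6 nm are an error (overlap), as are zero-length bond
  vectors in angle/dihedral evaluation and dangling bonded indices.
* Exclusion sets are always rederived from the bond graph by
  shortest-path classification, so a 1–2 pair can never double as 1–4.
* A negative fitted MSD slope clamps D to 0 with a warning; a single
  replicate yields an undefined standard deviation, flagged NA.
* Wrapped vs unwrapped storage is an explicit trajectory flag; MSD and
  RMSF refuse wrapped input rather than silently producing box-bounded
  artefacts.
* Empty trajectory files, inconsistent atom counts across frames, and
  malformed fixed-column records are parse errors naming the line.

Problem sizes in the test-suite and acceptance script (hundreds of
atoms, 10⁴-frame point-particle runs, 4 replicates) were chosen as the
smallest sizes at which the statistical tolerances stated above are
comfortably met.

## Known limitations

* Classic Ewald scales poorly beyond a few thousand atoms; a
  mesh-interpolated method is a non-goal here.
* Only orthorhombic boxes; no velocities; no force evaluation or
  dynamics propagation.
* The geometric H-bond criterion is purely structural; energetic
  definitions and proton tunnelling are out of scope.
* The limiting-factor rule is a package-level formalization of a
  qualitative argument; with only four polymers per API the rank
  correlations are coarse (n = 4 is flagged "ok" but close to the
  low-power regime).
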