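---
title: "Models and numerical methods in AntioxDesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in AntioxDesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AntioxDesign)
```

AntioxDesign implements the desk-scale layer of a computer-aided
antioxidant-design workflow.  The electronic-structure work (DFT geometry
optimisation, frequencies, continuum solvation) is out of scope and enters
only as tabulated inputs: reaction and activation free energies, imaginary
wavenumbers, deprotonation free energies, bond dissociation and ionisation
energies, and sampled IRC energy profiles.  This vignette documents the
models behind each stage, the tunable parameters with their defaults, the
numerical choices, and what the synthetic generators do and do not emulate.

## Scaffold enumeration and drug-likeness

A scaffold is a SMILES template with `{R1}`..`{Rn}` site tokens plus a
substituent library whose fragments carry a single `[*]` attachment point.
Enumeration forms every assignment of library groups (or hydrogen) to
sites, caps the number of simultaneous substitutions if asked, and
deduplicates on OpenBabel canonical SMILES.  Site symmetry is deliberately
*not* detected: on the bundled caffeic-acid scaffold the five positions are
chemically inequivalent, so structural deduplication alone is the correct
reduction; on symmetric test scaffolds equivalent placements collapse as a
consequence of canonicalisation, which is the behaviour we want.  The raw
pattern space of a scaffold with *s* sites and a library of *g* groups has
$(g+1)^s$ entries (32768 for the bundled 5-site/7-group design); published
cohorts derived from such designs are usually smaller after policy
reductions that are not part of the combinatorics, so the enumerator
exposes a `patternFilter` hook instead of hard-coding any particular count.

Descriptors (HBD, HBA, MW, logP, MR, heavy atoms, rotatable bonds, TPSA)
come from OpenBabel's implementations of the standard algorithms
(Crippen-type logP/MR, Ertl-type TPSA).  Different toolkits disagree in the
second decimal of logP-like quantities, which is why all rule and score
logic is tested property-wise rather than against third-party decimals.
Rule bounds (Lipinski MW ≤ 500, logP ≤ 5, HBD ≤ 5, HBA ≤ 10; Ghose
160 ≤ MW ≤ 480, −0.4 ≤ logP ≤ 5.6, 40 ≤ MR ≤ 130, 20 ≤ AtX ≤ 70; Veber
RB ≤ 10, PSA ≤ 140 Å²) are inclusive: a compound with HBD exactly 5 passes.

## Selection and elimination scores

Candidates are scored relative to a reference cohort of compounds in
clinical use.  Each property maps to a desirability in [0, 1]:

* the eight ADME descriptors score 1 inside their compliance window (the
  intersection of the applicable rule bounds, see `propertyWindows()`) and
  decay as $1/(1+d)$ outside, where $d$ is the distance to the nearest
  bound in units of the reference standard deviation;
* LD50 and synthetic accessibility use increasing logistic desirabilities
  centred on the reference mean (higher LD50 = less toxic, higher SA =
  easier to make — both desirable);
* Ames mutagenicity enters as one minus the predicted probability.

S^S is the weighted sum of the drug-likeness, toxicity and
synthesizability terms (default weights 1/1/1), divided by the reference
cohort's mean raw score, so the reference set averages exactly 1.0.  A
design point worth making explicit: with any nonlinear desirability no
normalisation can simultaneously make the cohort *mean* exactly 1 and the
*centroid compound* (every property at the reference mean) score exactly 1
— the mean of a nonlinear function is not the function of the mean.  We
pin the cohort mean (that is the documented calibration line) and accept
that the centroid sits near, not at, 1.  The weights are exposed so a
bespoke scheme — e.g. one recovered from a supplementary specification —
can be slotted in without touching the pipeline.

S^E counts properties whose standardized deviation from the reference mean
exceeds `zThreshold` (default 2.0, the conventional outlier cut; the
methodology we follow states no value).  Deviations that are desirable on
their own terms (LD50 or SA above the mean) are flagged but marked benign.

## pKa and speciation

The fitted-parameters approach maps a computed deprotonation free energy
to pKa linearly, pKa = m·ΔG_BA + C0, with per-functional-group
coefficients fitted elsewhere against experimental data (bundled table:
thiol 0.357/−94.639, phenol 0.316/−81.497, carboxylic acid 0.356/−94.380,
amine 0.464/−121.000).  Speciation uses the macroscopic successive-
deprotonation ladder: with pKa₁ < pKa₂ < …, the fraction of the k-times
deprotonated species at a given pH is proportional to
$10^{k\,\mathrm{pH} - \sum_{i\le k} \mathrm{p}K_{a,i}}$.  No
microspecies/tautomer branching is modelled — the inputs are macroscopic
constants, one per step.  Fractions are computed in log10 space and
normalised after subtracting the maximum exponent, so ladders far from the
working pH cannot overflow.  `equilibriumFractions()` solves the same
equilibrium by numeric root finding on the mass balance at fixed proton
activity and serves as the cross-check oracle; `speciationSensitivity()`
propagates the stated ±0.2 pKa-unit uncertainty through the fractions.
The default working pH is 7.4 (physiological), exposed in `runConfig()`.

## Rate-constant assembly

Energies are kcal/mol throughout, with R = 1.98720×10⁻³ kcal mol⁻¹ K⁻¹ and
T defaulting to 298.15 K.  Per channel:

1. **Feasibility.** Channels with ΔG_rxn > 0 are excluded from rate
   assembly by default (switchable), and excluded channels are reported —
   exclusion decisions must be auditable.  Channels whose barrier is
   unavailable (`na` cells) are likewise excluded with a notice.
2. **TST.** k = σκ(k_BT/h)·exp(−ΔG‡/RT) under the 1 M standard state.
   σ defaults to 1 and is an explicit input; tabulated studies rarely
   print per-channel degeneracies.
3. **Tunneling.** `wigner` uses the parabolic expansion
   1 + (hcν̃/k_BT)²/24.  `eckart_zct` fits an asymmetric Eckart barrier to
   the forward barrier, reverse barrier and imaginary wavenumber and
   Boltzmann-averages the exact transmission probability — the standard
   desk-scale realisation of a zero-curvature treatment when the
   transmission-probability grid of the original calculation is not
   available.  The transmission formula was validated against a numeric
   Schrödinger integration (the test suite keeps that oracle); the thermal
   average uses adaptive quadrature over energies above the higher
   asymptote, and the result is floored at 1.
4. **Marcus.** Electron-transfer barriers come from
   ΔG‡ = (λ/4)(1 + ΔG/λ)², with the reorganisation energy an input.
5. **Diffusion.** Stokes–Einstein D = k_BT/(6πηa) per reactant (solute
   radii are inputs; the radical partner's radius defaults to 2.0 Å, a
   typical hydroperoxyl-scale value), Smoluchowski
   k_D = 4πR·D_AB·N_A·10³ with R the sum of the radii, and
   Collins–Kimball k_app = k_D·k_act/(k_D + k_act).  Barrier-less channels
   (explicit flag or ΔG‡ ≤ 0) short-circuit to k_app = k_D.
6. **Aggregation.** Per-species totals are sums of channel k_app; the
   global coefficient weights totals by the molar fractions at the working
   pH.  Solvent viscosities default to water 8.91×10⁻⁴ Pa s and
   pentylethanoate 8.62×10⁻⁴ Pa s at 298.15 K.

Reproducing *tabulated per-channel* rate constants from tabulated barriers
alone is not attempted: published tables typically omit the per-channel
κ and σ that entered them, and without those the Eyring expression is
under-determined.  The package's per-channel claims are therefore tested
against its own closed forms and oracles, while *aggregates* (totals,
global coefficients) are tested against published values, which are sums
and weighted sums of printed numbers.

## Donating-ability maps

The eH-DAMA screen plots each species' minimum BDE over its H-donor sites
against its ionisation energy, with reference lines taken from the single
oxidant pair on the map (H-donation line at the oxidant's O–H bond
strength; electron-transfer line at its acceptor level).  Only relative
placement is interpreted — classification is invariant under shifting
either axis — and comparisons are strict, so a species exactly on a line
is reported as a tie, not a pass.

## Reaction-force analysis

The reaction force is RF(ξ) = −dV/dξ along the IRC.  The default
differentiation fits a cross-validated smoothing cubic spline (QM grids
are unevenly spaced and mildly noisy); when the fit's residuals show the
profile is effectively noiseless (residual sd < 10⁻⁷ of the energy range)
the interpolating spline is used instead, so analytic test profiles are
differentiated without smoothing bias.  Second-order central differences
are available as a no-smoothing fallback.  β is the force zero-crossing
nearest the energy maximum (with noise there can be several crossings; the
transition state is by definition the one at the barrier), α the force
minimum on the reactant side, γ the force maximum on the product side; all
three are refined off-grid (linear interpolation for the crossing, local
quadratic for the extrema).  Zone energies are differences of the fitted
potential at the refined points, with reactants/products taken at the
first/last grid point, so each activation energy equals the sum of its two
zone components exactly by construction.  Work integrals use adaptive
quadrature of the fitted force with a dense-trapezoid fallback for
nearly-flat tails.

Error propagation worth knowing: under noise the *activation energies* are
recovered much more accurately than the individual zone components,
because a localisation error δα in the force minimum propagates as
|RF(α)|·δα into the preparation energy — and |RF(α)| is by definition the
largest retarding force — while V(β) sits at a stationary point.  The test
suite therefore holds activation energies to 1% under 0.1% noise but gives
the individual components a looser band tied to the critical-point grid
tolerance; noiseless profiles are held to 1% throughout.

Hartree input converts at 627.5095 kcal/mol; reaction-coordinate units are
pass-through (nothing downstream interprets them absolutely).

## The synthetic generators

The generators stand in for the quantum-chemistry stage in all tests:

* `makeIrcProfile()` samples sech² (symmetric) or asymmetric Eckart-type
  profiles.  Both families were chosen because their critical points have
  closed forms — the sech² force extrema sit at ±L·artanh(1/√3) where the
  energy splits exactly 2/3 : 1/3, and the Eckart inflection points solve
  a quadratic in y = e^(ξ/L) — so parameter recovery can be asserted
  against ground truth rather than against the code under test.  Gaussian
  noise is optional; generation retries (then fails loudly) when noise
  drowns the barrier.
* `makeChannelTable()` emulates the *structure* of a QM channel table —
  mechanisms f-HAT/SET/RAF across three protonation states and two
  solvents, RAF drawn endergonic so the feasibility filter removes it, one
  barrier-less di-anion channel — and computes its own expected totals and
  global coefficient from the same closed forms, for round-trip testing of
  the assembly bookkeeping.
* `makeReferenceDescriptors()` draws a 54-compound cohort (the size of the
  reference set the scoring stage is calibrated against) with LD50
  log-normal around 1142.87 mg/kg and plausible oral-drug ADME ranges.
* `makeSpeciationCase()` draws strictly increasing 2–4 step ladders and
  solves them with the numeric equilibrium oracle.

What they deliberately do **not** emulate: electronic-structure-level
realism (geometries, frequencies, conformers), correlations between
descriptors, multi-barrier or valley-ridge IRC topologies, and
microspeciation.  A green test suite shows the *pipeline arithmetic* is
right under the stated models; it says nothing about the quality of any
particular DFT input.

## Problem sizes and determinism

The bundled tests and the acceptance script run entirely on synthetic or
curated desk-scale inputs: 1000 random ladders for the speciation
cross-check, a dozen random barriers for the tunneling quadrature check,
301-point IRC grids, and 54-compound cohorts — sizes chosen so any
workstation reproduces the suite in well under a minute per stage.  All
generators take explicit seeds and restore the global RNG state, so runs
are bit-reproducible; pipeline CSVs are written at 6 significant digits so
re-runs are byte-stable.

## Known limitations

* Variational TST and small-curvature tunneling are not implemented; the
  zero-curvature Eckart treatment is the ceiling of the kinetic model.
* Solute radii for Stokes–Einstein are inputs, not computed from volume.
* The selection-score scheme is a documented, calibrated stand-in where
  the original methodology's exact formula is unpublished; all published
  calibration facts it states (reference mean at 1.0, three additive
  terms, higher-is-better, benign high-LD50 deviations) are reproduced and
  tested.
* No temperature dependence of pKa, and no computation of ΔG_BA, BDE, IE
  or reorganisation energies — these remain quantum-chemistry deliverables.
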