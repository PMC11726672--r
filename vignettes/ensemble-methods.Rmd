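---
title: "Methods: conformer thermochemistry, cycle pKa, and structure-ensemble analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformer thermochemistry, cycle pKa, and structure-ensemble analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcensemble)
```

This vignette records the models the package implements, the defaults
it pins, and the design decisions taken where more than one defensible
convention exists. It is the place to look before changing a parameter.

## Conformer uniqueness screening

Stochastic conformer searches over-count: rotamers re-converge to the
same basin. Two records are merged when **both** of these hold:

* each of the three descending-sorted rotational constants agrees
  within a relative tolerance `rel_tol` (default 0.01, i.e. 1%), and
* the comparison electronic energies agree within `e_tol` (default
  0.1 kcal·mol⁻¹).

The conjunctive reading matters: an *or* rule would merge genuinely
distinct conformers that happen to be isoenergetic. Rotational
constants are compared relative to the kept record's constants.
Because pairwise similarity is not transitive, the screen is greedy in
ascending energy order: each record is compared against the already
kept set, and every duplicate group ends up represented by its
lowest-energy member. The comparison energy defaults to the best
available column (`e_dft`, then `e_qz`, `e_tz`, `e_dz`), selectable via
`energy_col`, because screening happens at more than one stage of a
funnel workflow (semiempirical ensemble first, DFT-refined ensemble
later).

## RRHO thermochemistry

`rrho_corrections()` assembles ideal-gas translational, rigid-rotor
rotational and harmonic-oscillator vibrational contributions:

* translational enthalpy 5/2·RT and Sackur–Tetrode entropy at the
  stated pressure (default 1 atm, the convention of standard
  frequency-analysis codes);
* rigid-rotor rotational terms from the rotational constants, with
  symmetry number fixed at 1 (flexible drug-like ligands have C1
  symmetry; a symmetry-number option would only matter for small
  symmetric molecules);
* harmonic vibrational ZPE, thermal energy and entropy with every
  frequency multiplied by `scale` (default 0.971, appropriate for the
  range-separated hybrid functional family used to generate the
  frequencies) **before all terms**, zero-point and thermal alike. The
  alternative — scaling ZPE only — changes G_corr by well under the
  method error but is not what the reference treatment does.

Temperature defaults to 310.15 K throughout because the downstream
question is physiological abundance. Negative-tagged (imaginary)
frequencies abort by default; `drop_imaginary = TRUE` discards them
with a warning, for consumers who have already inspected the offending
saddle points. No quasi-harmonic damping of low frequencies is applied:
low-mode entropies are therefore upper bounds, which cancels
substantially in conformer *differences* of the same molecule.

Physical constants are CODATA 2018; hartree→kcal·mol⁻¹ is pinned at
627.5095 so that results are bit-reproducible across machines.

### The proton and standard states

A bare proton has only translational degrees of freedom, so its
gas-phase free energy follows in closed form: H = 5/2·RT and S from the
Sackur–Tetrode equation. `proton_gas_free_energy()` defaults to a
**1 bar** standard state — the modern thermochemical convention under
which the tabulated S°(H⁺) = 26.04 cal·mol⁻¹·K⁻¹ and
G = −6.28 kcal·mol⁻¹ at 298.15 K are defined — with an `"atm"` option
(which gives −6.27). The sign is thermodynamic (entropy dominates, G is
negative); parts of the cycle literature quote the magnitude, so
`pka_cycle()` accepts any user-supplied `g_gas_h` override.

## CBS extrapolation

Correlation-consistent energies at cardinal numbers n = 2, 3, 4 are
extrapolated with E(n) = E_CBS + A·n⁻⁴ + B·n⁻⁵, solved exactly as a
3×3 linear system; the fit residuals are returned and are ≤10⁻¹⁰
hartree by construction. The exponent pair (4, 5) and a cardinal-number
offset are configurable: published inverse-polynomial schemes differ on
whether effective cardinal numbers carry a half-integer shift, and the
plain-n form is this package's default rather than a claim about any
particular literature scheme. With three points and three parameters
the model is interpolatory, so the scheme choice *is* the extrapolation
assumption — which is why it is exposed.

## Thermodynamic-cycle pKa

For HA⁺ → A + H⁺:

* ΔG_gas = G_gas(A) + G_gas(H⁺) − G_gas(HA⁺)
* ΔΔG_sol = ΔG_sol(A) + ΔG_sol(H⁺) − ΔG_sol(HA⁺)
* ΔG_aq = ΔG_gas + ΔΔG_sol, pKa = ΔG_aq/(RT ln 10)

Component energies are expected at solution-phase geometries
("method 2"); the cycle is then path-consistent by construction.
ΔG_sol(H⁺) defaults to the experimental −265.6 kcal·mol⁻¹, the single
largest uncertainty of any such cycle (±2 kcal·mol⁻¹ across the
literature ≈ ±1.4 pKa units — a floor no amount of QM accuracy on the
solute lowers). A 1 atm → 1 M standard-state correction term
(RT ln 24.46) is available behind an explicit flag and **off** by
default, since conventions differ on whether the solvation free
energies already absorb it; enabling it shifts every pKa by the same
+0.47 units at 310.15 K.

## Superposition, region RMSD, atom matching

Kabsch superposition uses SVD with a determinant correction so only
proper rotations are returned; fewer than three pairs, or collinear
pairs, are errors rather than silently rank-deficient fits.

Per-helix reports fit **once** on the conserved region (default
66–349) and then measure each helix in that common frame, because the
scientific statement "helix 6 swings outward" is about displacement
relative to the shared scaffold; `refit_per_region = TRUE` gives the
per-helix best-fit alternative. Backbone means {N, CA, C, O}. Pairing
is by (residue number, atom name) after any renumbering offset (+2
maps the mouse receptor onto human numbering); unresolved residues are
dropped from the pairing and counted, since experimental GPCR
structures routinely lack loop density. Residues with insertion codes
are rejected outright — none occur in the transmembrane ranges this
package targets, and guessing an ordering would corrupt pairings
silently.

Ligand heavy-atom RMSD minimises over per-element atom assignments:
Hungarian assignment with squared-distance cost alternates with Kabsch
refits until the assignment is stable (≤50 rounds), started from the
input order and from all 24 proper axis permutation/flip hypotheses of
the principal-axes frames. The multi-start matters: near-degenerate
inertia axes make any single principal-axes hypothesis unreliable, and
plain alternation from one start can stall in a local minimum. On
small test molecules the result is verified against exhaustive
permutation enumeration.

## Ensemble alignment, invariant core, clustering, PCA

Ensemble members are mapped to common positions either by residue
number or by progressive pairwise global sequence alignment against
the first structure (match +1, mismatch 0, gap −1) — adequate at the
≥94% identity of a single-receptor structure set, and deliberately not
a multiple-alignment engine. Positions absent from any member (gaps)
are removed before analysis.

The invariant core starts from all common positions and iteratively
drops the position with the largest variance-ellipsoid volume
(4/3·π·√det Σ of the 3×3 positional covariance across members,
computed after superposing on the current core), until every remaining
position is below `volume_cutoff` (default 0.5 ų) or `min_core`
(default 30) positions remain. Both defaults are this package's
choices: the cutoff is roughly the volume of thermal backbone motion
in a well-ordered crystal, and the floor prevents the core collapsing
onto a trivially rigid fragment. The procedure is deterministic and
invariant to rigid motions of any input.

Pairwise Cα RMSDs are measured in the common superposed frame without
per-pair refitting (a flag enables refits), clustered agglomeratively
with **complete** linkage — chosen so that a group label guarantees a
bounded within-group diameter, which is how "four groups of receptor
conformations" is naturally read; the linkage is configurable because
nothing in the science forces it — and cut at the requested k.

PCA stacks each member's gap-free Cα coordinates into a
3·n_positions vector, mean-centers, and eigen-decomposes the
covariance (divisor n−1). All 3·n_positions eigenvalues are reported
(276 aligned positions give 828), each over their sum giving the
proportion of positional variance. Mode signs are fixed by making the
largest-magnitude loading positive — scores are otherwise
sign-ambiguous between runs. An ensemble with no variance at all is
flagged `degenerate` with NA proportions rather than NaNs. Mode
trajectories interpolate mean ± amplitude along a unit mode vector for
visualisation.

## What the synthetic generators emulate — and what they do not

`gen_conformer_ensemble()` plants duplicate groups (constants jittered
≤0.5%, energies shifted upward ≤0.05 kcal·mol⁻¹ so the group head
stays lowest), exact inverse-polynomial basis-set series, and a
relative free-energy spectrum realised through the same RRHO+CBS
assembly the analysis applies, so the planted populations are exact
fixed points of the pipeline. `gen_structure_ensemble()` adds
orthonormal collective modes — drawn orthogonal to the template's
rigid-body subspace, since a displacement parallel to a rotation would
be absorbed by superposition and no estimator could see it — plus
optional rigid sub-domain group offsets and isotropic Gaussian noise,
then hides everything behind random rigid motions. Truth records carry
both the generative variance fractions (mode variance over total
including the 3·n_positions·σ² noise floor) and the realized fractions
of the finite sample actually drawn; estimator checks use the realized
spectrum, because at ensemble sizes around 50 the sampling
fluctuation of an eigenvalue is itself of order several percent.
`gen_pka_inputs()` samples plausible component magnitudes and closes
the cycle exactly on a target pKa.

None of this is physical: geometries are synthetic point sets, noise
is isotropic Gaussian, modes are random directions. Passing tests
therefore demonstrate that the estimators recover what was planted
under their own model assumptions — not that real conformer searches
are exhaustive, that harmonic thermochemistry is adequate for floppy
ligands, or that crystal-structure ensembles sample a receptor's
conformational distribution.

## Problem sizes and tolerances in the test suite

The suite runs ensembles of 8–50 synthetic structures with 10–50
positions, conformer tables of up to 24 records, and ligands of ≤6
heavy atoms where exhaustive permutation enumeration is the oracle —
sizes chosen so every oracle is exact and the whole suite runs in
seconds. Equality tolerances follow the quantity: 10⁻⁹ hartree for the
CBS solve, 10⁻⁶ Å against the quaternion superposition oracle, 10⁻⁹
for planted pKa recovery, 3% absolute for variance proportions at
n = 50 (sampling-limited), and two decimals for tabulated
thermochemical constants.

## Known limitations

* Harmonic-only vibrational treatment; no hindered-rotor or
  quasi-harmonic corrections.
* The pKa cycle inherits the ±2 kcal·mol⁻¹ uncertainty of the proton
  solvation free energy, and handles one protonation site at a time —
  no microstate/tautomer enumeration.
* Sequence mapping is pairwise-progressive; below ~90% identity a true
  multiple alignment should be built externally and fed in by residue
  number.
* PDB parsing keeps the first model and altloc A only; mmCIF is not
  read.
* The invariant-core defaults are sensible for single-receptor
  crystal-structure sets; ensembles with genuinely mobile cores (e.g.
  MD snapshots of unfolding) need a tighter cutoff or an explicit core.
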