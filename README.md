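# qcensemble

Post-quantum-chemistry analysis for ligand conformer ensembles and
receptor structure ensembles, written for computational chemists who
already have electronic-structure output in hand (conformer searches,
harmonic frequencies, correlated single-point energies, solvation free
energies, experimental receptor coordinates) and need the statistical
layer on top: which conformers are distinct, how abundant is each in
solution at body temperature, what pKa does a thermodynamic cycle
predict, and which collective motions separate active from inactive
receptor states.

The package grew out of μ-opioid receptor (MOR) ligand work — fentanyl,
naltrexone and related alkaloids binding a class A GPCR — but every
stage is generic.

## What it computes

**Conformer thermochemistry and populations.** Conformers from a
stochastic search are screened for uniqueness: two records merge only
when all three rotational constants agree within 1% *and* energies
agree within 0.1 kcal·mol⁻¹ (greedy, in ascending energy order, keeping
the lowest-energy representative). Rigid-rotor/harmonic-oscillator
(RRHO) corrections are built from scaled harmonic frequencies (default
scale 0.971) at 310.15 K and 1 atm. Electronic energies at double-,
triple- and quadruple-ζ cardinal numbers are extrapolated to the
complete-basis-set (CBS) limit through the inverse-polynomial model

    E(n) = E_CBS + A n⁻⁴ + B n⁻⁵ ,  n = 2, 3, 4

solved exactly (three equations, three unknowns). Gibbs free energies
G = 627.5095·E_CBS + G_corr feed equilibrium populations

    p_i = exp(−ΔG°_i / RT) / Σ_j exp(−ΔG°_j / RT) ,
    R = 1.9872041×10⁻³ kcal·mol⁻¹·K⁻¹.

**Thermodynamic-cycle pKa.** For a dissociation HA⁺ → A + H⁺,
ΔG_aq = ΔG_gas + ΔΔG_sol assembled from component free energies
("method 2": solution-phase geometries throughout), with the
experimental proton constants ΔG_sol(H⁺) = −265.6 kcal·mol⁻¹ and the
Sackur–Tetrode gas-phase proton free energy (|G| = 6.28 kcal·mol⁻¹ at
298.15 K). Then pKa = ΔG_aq / (RT ln 10).

**Superposition and RMSD.** Kabsch least-squares superposition with
proper-rotation enforcement; fixed-frame RMSD; per-helix RMSD reports
after a single fit on the conserved region (residues 66–349 in hMOR
numbering, mMOR shifted by +2), with the seven TM helix ranges built
in; and ligand heavy-atom RMSD under optimal like-element atom
matching (Hungarian assignment alternating with Kabsch refits, started
from all 24 proper principal-axes hypotheses).

**Structure-ensemble PCA.** Cα ensembles are sequence-aligned, gap
positions removed, an invariant core detected by iteratively dropping
the position with the largest variance-ellipsoid volume, the ensemble
superposed on that core, all-pairs RMSDs clustered (complete linkage),
and PCA run on the stacked Cartesian coordinates — 3·n_positions
eigenvalues whose fractions are the proportions of positional variance,
with per-structure scores and exportable mode trajectories.

**Synthetic data.** Deterministic generators plant duplicate groups,
CBS limits, relative free-energy spectra, collective displacement
modes, group offsets and pKa targets, with JSON truth sidecars, so the
whole pipeline is testable without downloading anything.

## Worked example

```r
library(qcensemble)

sim <- gen_conformer_ensemble(seed = 42, n_unique = 5, n_dup_per_group = 3,
                              dg_spectrum = c(0, 0.6, 1.1, 2.3, 3.4))
res <- conformer_free_energies(sim$table)   # dedup + RRHO + CBS + Boltzmann
res[, c("conformer_id", "delta_g_kcal", "population_pct")]
#>   conformer_id delta_g_kcal population_pct
#> 1       c01_01          0.0         63.550
#> 2       c02_01          0.6         24.006
#> 3       c03_01          1.1         10.666
#> 4       c04_01          2.3          1.522
#> 5       c05_01          3.4          0.255
```

Fifteen records collapse to the five planted conformers; the global
minimum holds 63.6% of the room-temperature-like (310.15 K) population
and everything below ~3 kcal·mol⁻¹ is populated enough to matter for
binding. A pKa cycle from component free energies:

```r
cyc <- pka_cycle(g_gas_ha = -850000, g_gas_a = -849772,
                 dg_sol_ha = -58.73, dg_sol_a = -1.74, temperature = 310.15)
delta_g_aq(cyc)
#> pKa cycle at 310.15 K:
#>   dG_gas  =  221.404 kcal/mol
#>   ddG_sol = -208.610 kcal/mol
#>   dG_aq   =   12.794 kcal/mol
#>   pKa     =    9.015
```

A pKa near 9 means the ligand is overwhelmingly protonated at
physiological pH 7.4 (ratio ≈ 10^(9.0−7.4) ≈ 40:1). A command-line
wrapper covering `dedup`, `thermo`, `cbs`, `boltz`, `pka`, `rmsd`,
`helices`, `pca` and `simulate` ships at
`system.file("cli", "qcensemble.R", package = "qcensemble")`.

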