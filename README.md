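# hbhydro

Atomistic hydrogen-bond donor/acceptor strengths and hydration free
energies for small molecules, in R.

Hydrogen bonding drives target affinity, solubility and oral
availability, so medicinal chemists constantly ask: *how strong a donor
is this N-H, how strong an acceptor is that ring nitrogen, and how much
does hydration cost this molecule?* Quantum-mechanical answers exist but
are slow. `hbhydro` implements a fast empirical alternative: per-atom
strengths from partial charges, and a hydration free energy assembled
from three additive terms, at hundreds of molecules per minute.

## The model

For a 3D conformation with explicit hydrogens:

- **Strengths.** Each hydrogen gets `sd = D (qH + dq)`, each
  lone-pair-bearing atom `sa = A (qa + dq)`, where `q` are
  electronegativity-equilibration (EEQ) partial charges and
  `dq = T Σ_α q + T² Σ_β q + T³ Σ_γ q` propagates neighbour charges
  through the bond shells at distance 1/2/3 (`T = 0.274`). `D` and `A`
  are calibrated so the hydrogens and oxygen of MMFF94-minimised water
  score exactly 1.0 — strengths read as "relative to water".
- **Polar term.** `ΔG_p = g_d Σ sd_i n_H^0.50 + g_a Σ sa_i n_LP^0.34`
  over X–H donor heavy atoms (X ≠ C) and all acceptors.
- **Apolar term.**
  `ΔG_a = g_0 + g_s N_s + g_r N_r + g_π² N_π² + g_π¹ N_π¹` with the
  topological surface `N_s = Σ 4π r_vdW² (1 − n_l/(h+1))`, SSSR ring
  count and sp1/sp2 π counts.
- **Interaction term.** `ΔG_i = g_i Σ_j a_j (Σ_n a + Σ_nn a + F Σ_nnn a)`
  with `a = sa n_LP^0.34`, an empirical correction for proximal
  acceptors sharing a hydration shell.
- `ΔG_total = ΔG_p + ΔG_a + ΔG_i`, kJ/mol.

Molecule preparation (SMILES/SDF parsing, hydrogen addition, seeded 3D
embedding, MMFF94 minimisation, hybridisation/ring perception) is
delegated to RDKit through the system `python`; charges, strengths,
energies, calibration, fitting, metrics and SVG depictions are computed
in R. See the vignette (`vignettes/hydration-model.Rmd`) for every
equation, parameter and design decision.

## Worked example

```r
library(hbhydro)

f <- tempfile(fileext = ".smi")
writeLines(c("CCO ethanol",
             "CC(=O)Nc1ccc(O)cc1 paracetamol",
             "c1ccncc1 pyridine"), f)
mols <- load_molecules(f, "smiles")
mols <- prepare_conformers(mols, seed = 1)     # ETKDG + MMFF94, deterministic
mols <- lapply(mols, compute_charges_radii)    # EEQ charges + radii

cal <- calibrate_water(seed = 1)               # water-referenced scale
p   <- hydration_params(strength = strength_params(cal$D, cal$A))
predict_hydration(mols, p)
#>            id dG_polar dG_apolar dG_interaction dG_total sdx_mol sdc_mol sd_mol sa_mol
#> 1     ethanol   -20.02      5.11           0.00   -14.91    0.73    1.67   2.40   2.03
#> 2 paracetamol   -44.73    -11.83           7.07   -49.49    1.76    5.02   6.78   4.19
#> 3    pyridine   -10.76     -8.03           0.00   -18.79    0.00    2.97   2.97   0.67
```

Reading the rows: ethanol's hydration is dominated by its polar term
(one O–H donor at 0.73 water-equivalents, one acceptor oxygen near 1.0)
against a small positive apolar surface cost; paracetamol adds an
interaction penalty (+7.1 kJ/mol) because its amide and phenol acceptors
sit within three bonds; pyridine has no polar X–H donor at all — its
entire donor column comes from C–H hydrogens, which are tabulated
(`sdc_mol`) but excluded from the polar term.

Per-atom detail and depictions:

```r
s <- molecular_strengths(mols[[1]], p$strength)
round(s$donor, 2)
#>    4    5    6    7    8    9
#> 0.37 0.30 0.26 0.41 0.33 0.73      # atom 9 is the hydroxyl hydrogen
render_strengths(mols[[1]], s, depiction_spec("both"))  # ethanol.svg
```

A command-line front end wraps the same functions
(`inst/cli/hbhydro.R`): subcommands `predict`, `strengths`, `depict`,
`calibrate`, `fit`, `validate`, `sar`; every batch output gets a
resolved-config YAML sidecar, and interrupted batches resume past
already-computed molecules.

## Fitting and validation

`fit_parameters()` refits the eleven free-energy parameters against an
experimental dataset (CSV with `id`, `smiles`, `dG_exp_kj_mol`; kcal/mol
columns are converted by 4.184) by seeded MAE minimisation with a
300-cycle early stop. When validating on external sets, drop compounds
present in the fitting set. `regression_metrics()` reports MAE, RMSE and
both r² conventions; `sar_correlate()` builds activity-strength
correlation tables like the two packaged case studies
(`load_fixture("table1_cdk2_activities")` and friends — a CDK2 inhibitor
series probing donor strengths and an 11β-HSD1 series probing acceptor
strengths).

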