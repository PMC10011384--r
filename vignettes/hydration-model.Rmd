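---
title: "An additive model of hydrogen-bond strengths and hydration free energy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An additive model of hydrogen-bond strengths and hydration free energy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`hbhydro` estimates the free energy of hydration of a small organic
molecule as the sum of three additive contributions,

$$\Delta G_{hydr} = \Delta G^{p} + \Delta G^{a} + \Delta G^{i},$$

all in kJ/mol, evaluated on a single 3D conformation. The model is
deliberately simple - no solvent model, no conformational ensembles, no
hydrogen-bond directionality - which is what makes it fast enough for
interactive design and for feature generation at scale.

### Atomic strengths

Every hydrogen receives a donor strength and every atom with at least one
lone pair an acceptor strength,

$$sd = D\,(q_H + \delta q_H), \qquad sa = A\,(q_a + \delta q_a),$$

where $q$ is the atom's partial charge and $\delta q$ a corrective term
that propagates the charges of topological neighbours through three bond
shells, attenuated by the bond reduction factor $T$:

$$\delta q = T \sum_{k}^{\alpha} q_k + T^2 \sum_{k}^{\beta} q_k +
  T^3 \sum_{k}^{\gamma} q_k .$$

The $\alpha/\beta/\gamma$ shells are all atoms (hydrogens included) at
bond distance 1, 2, 3; an atom reachable by several paths counts once, at
its shortest distance. $T = 0.274$ throughout.

$D$ and $A$ are water-referenced calibration constants: they are defined
by requiring that the hydrogens and the oxygen of an MMFF94-minimised
water molecule score exactly 1.0 under the charge backend in use
([`calibrate_water()`]). A strength above 1 therefore means "forms a
stronger hydrogen bond than water does".

### Polar term

$$\Delta G^{p} = g_d \sum_i^{donors} sd_i\,(n_H)^{exp_d}
  + g_a \sum_i^{acceptors} sa_i\,(n_{LP})^{exp_a}.$$

Two indexing questions are left open by the equation as usually stated,
and both are explicit, switchable design choices here:

* **Donor indexing.** The donor sum runs over *heavy atoms* bearing at
  least one hydrogen, with $sd_i$ the arithmetic mean of that atom's
  hydrogen strengths and $n_H$ its hydrogen count (flag
  `donor_aggregation`, default `"mean"`). Pairing one $sd_i$ with a
  $(n_H)^{exp_d}$ multiplicity only makes sense with a per-heavy-atom
  representative strength.
* **Donor scope.** Only X-H hydrogens with X not carbon enter the polar
  term (flag `donor_scope`, default `"xh-only"`); C-H strengths are
  still computed and aggregated (`sdc_mol`) because they carry SAR
  signal, but the polar term models polar hydrogens. Both readings can
  be compared against external data via the flag.

The acceptor sum runs over all atoms with $n_{LP} \ge 1$ - including
halogens, divalent sulfur and pyridine-type nitrogens. $(n_{LP})^{exp_a}$
with $n_{LP} = 0$ never occurs by construction.

### Apolar term

$$\Delta G^{a} = g_0 + g_s N_s + g_r N_r + g_\pi^2 N_\pi^2
  + g_\pi^1 N_\pi^1,$$

with the topological surface area summed over non-hydrogen atoms,

$$N_s^i = 4\pi\,(r_i^{vdW})^2\left(1 - \frac{n_l^i}{h_{spk}^i + 1}\right),$$

$h = 1, 2, 3$ for sp1/sp2/sp3 hybridisation and $n_l$ the heavy-neighbour
count. $N_r$ is the SSSR ring count of the whole molecule; $N_\pi^2$ adds
two per sp1 atom and $N_\pi^1$ one per sp2 atom, over all non-hydrogen
atoms (not only carbon - a deliberate choice, the counts being surrogate
measures of exposed pi density). Hypervalent atoms whose hybridisation
falls outside sp1-sp3 are rejected with a typed error rather than
guessed.

### Interaction term

Proximal acceptors share their hydration shell, which the model captures
empirically:

$$\Delta G^{i} = g_i \sum_j a^j\left(\sum_{k \in n(j)} a^k +
  \sum_{l \in nn(j)} a^l + F \sum_{m \in nnn(j)} a^m\right),
  \qquad a^p = sa_p\,(n_{LP}^p)^{exp_a},$$

where $n/nn/nnn$ are acceptor atoms at bond distance 1/2/3 from the
origin acceptor $j$. The sum is over *ordered* pairs exactly as written -
an unordered pair within range contributes from both origins; any
symmetrisation convention is absorbed by the fitted $g_i$.

### Default parameters

| parameter | default | role |
|---|---|---|
| $D$, $A$ | 63.7, -4.4362 | strength calibration (reference backend) |
| $T$ | 0.274 | shell attenuation |
| $exp_d$, $exp_a$ | 0.50, 0.34 | multiplicity exponents |
| $g_d$, $g_a$ | 0.908, -16.131 | polar coefficients |
| $g_0$, $g_s$, $g_r$ | 1.884, 0.0467, -3.643 | apolar constant/surface/ring |
| $g_\pi^2$, $g_\pi^1$ | -1.174, -1.602 | pi-orbital coefficients |
| $g_i$, $F$ | 4.9996, 0.514 | interaction coefficient / nnn attenuation |

## The charge backend

The strengths are only as meaningful as the partial charges underneath.
The package ships a geometry-aware electronegativity-equilibration (EEQ)
solver: charges minimise an isotropic electrostatic energy with
erf-damped Coulomb kernels and coordination-number-corrected
electronegativities, solved as one constrained linear system per
molecule (charges sum exactly to the total formal charge, and are
invariant under rigid motions). The embedded element table
(electronegativity, hardness, CN correction, charge width for H, B, C,
N, O, F, Si, P, S, Cl, Br, I) follows the published EEQ parameterisation
family fitted to PBE0/def2-TZVP Hirshfeld charges. Van der Waals radii
are charge-dependent: the free-atom (Bondi/Mantina) radius scaled by
$((N_{val} - q)/N_{val})^{1/3}$, the package's own convention - anions
swell, cations shrink, smoothly and boundedly.

**On the default calibration constants.** The defaults $D = 63.7$,
$A = -4.4362$ belong to the reference charge model of the original
implementation of this method, which is not redistributable here. They
cannot be reproduced by *any* charge backend under the literal shell
equations above: for a symmetric neutral water ($q_O = -2q_H$) the two
corrected sums are $q_H(1-T)^2$ and $-2q_H(1-T)$, fixing the ratio
$A/D = -(1-T)/2 = -0.363$ for every charge assignment, while the default
pair has ratio $-0.070$. The donor constant of the original
implementation therefore stems from an internal convention that differs
from the published equations; this package follows the equations as
stated. With the shipped EEQ backend, `calibrate_water()` returns
backend-consistent constants ($D \approx 8.63$, $A \approx -3.13$), and
these - not the defaults - put strengths on the water-referenced scale
for this backend. The defaults are retained so that parameter files and
comparisons against the original scale remain expressible.

```{r, eval = FALSE}
library(hbhydro)
cal <- calibrate_water(seed = 1)
cal$D  # 8.63 with the shipped EEQ backend
params <- hydration_params(strength = strength_params(cal$D, cal$A))
```

## Perception choices

* **Lone pairs** follow a fixed element/valence table:
  $n_{LP} = (V - \text{total bond order} - \text{formal charge})/2$ with
  $V$ the group valence electron count, zero for carbon and hydrogen,
  minus one when an aromatic atom donates its pair into the ring pi
  system (pyrrole-type N, aromatic O/S). Pyridine N keeps one pair,
  single-bonded halogens three, divalent sulfur two, charged species
  shift accordingly (ammonium 0, alkoxide 3).
* **Hybridisation** comes from the perception toolkit, with aromatic
  atoms mapped to sp2.
* **Conformers** are embedded by seeded distance geometry and minimised
  with MMFF94 (force tolerance $10^{-6}$); with an identical seed the
  coordinates are bitwise reproducible. Structures supplied as 3D SD
  files can instead be preserved as given, with only hydrogens added -
  the mode intended for deposited ligand conformations, since strengths
  are conformation-sensitive.
* Protonation states and tautomers are taken as given in the input;
  molecules are scored as drawn.

## Fitting

`fit_parameters()` fits the eleven free parameters against experimental
energies by minimising the mean absolute error. D, A, T stay fixed, so
geometries, charges and strengths are computed once and each trial is a
cheap re-scoring of cached per-molecule features. The seeded sampler
exploits the model's structure: conditional on the three nonlinear
parameters ($exp_d$, $exp_a$, $F$) the model is linear in the remaining
eight coefficients, so each trial proposes the nonlinear trio (local
log-normal steps around the incumbent, with occasional uniform draws
inside the bounds) and solves the linear coefficients by least squares.
Bounds default to one decade either side of the reference values,
sign-preserving. The search stops after `patience` (default 300)
consecutive trials without improvement of the best MAE; the
early-stop counter resets on every strict improvement, ties keep the
first-seen trial, and the result is never worse than the starting point.
Runs are deterministic given (data, seed).

## The synthetic-data generator

`generate_synthetic_dataset()` draws molecules from a seeded fragment
grammar - an optional benzene head, a 2-6 atom chain with occasional
in-chain ether/amine heteroatoms, and a terminal polar or halogen group
(alcohols, amines, ethers, nitriles, chlorides, fluorides). The grammar
stays inside MMFF94-parameterised, EEQ-supported chemistry by
construction, so every generated molecule survives preparation. Labels
are the model's own predictions under the generating parameters plus
Gaussian noise of chosen standard deviation.

This emulates the *fitting problem* (known ground truth, controllable
noise), not real chemistry: the grammar contains no fused rings, no
charged species, no intramolecular hydrogen bonds, no conformational
flexibility worth the name. A successful fitting-recovery test therefore
demonstrates that the optimiser identifies the generating parameters
from 50 clean molecules (the suite checks $g_d$, $g_a$ back to within 5%
with final MAE below 0.1 kJ/mol) - it says nothing about accuracy on
experimental data, which must be assessed against external datasets
(kJ/mol or kcal/mol CSVs; kcal entries are converted by 4.184, and
compounds present in a fitting set should be dropped from a validation
set).

## Validation metrics

`regression_metrics()` reports MAE, RMSE and two r-squared conventions
side by side: the squared Pearson correlation (`r2`, the default
reading for a calibration scatter without a fitted line) and
$1 - SS_{res}/SS_{tot}$ (`r2_ss`). `sar_correlate()` computes Pearson r
between activities and per-feature strengths over the identifier
intersection; a feature with zero variance yields NA for that feature
only. Correlations recomputed from the packaged 2-decimal tables differ
from the originally reported ones by up to 0.06 for the 6-compound
series, because those were computed on unrounded strengths - the
packaged tables store the printed values verbatim.

## Problem sizes and numerical choices

The shipped test-suite scale - ten prepared example molecules, 100
random graphs per property test, 50 molecules for fitting recovery -
keeps the whole suite around half a minute while exercising every code
path; the EEQ solve is exact linear algebra, so correctness does not
depend on molecule count. Embedded water is symmetric only to the
minimiser's tolerance, so the calibrated *mean* hydrogen strength closes
to 1.0 at $10^{-9}$ while individual hydrogens agree to about $10^{-6}$;
tests assert both at their own scales. Strengths and energies are kept
unrounded internally and rounded to 2 decimals only in file outputs.

## Known limitations

* The backend's absolute charge scale differs from the reference model
  the free-energy coefficients were fitted against, so absolute
  $\Delta G$ values should be interpreted with care until refitted
  against experimental data with `fit_parameters()`.
* Conformation sensitivity is a feature (strength differences between
  symmetric hydrogens reflect geometry) but also a caveat: a single
  embedded conformer is one sample from an ensemble.
* No intramolecular hydrogen-bond geometry detection: ortho-substituted
  systems with internal hydrogen bonds are systematically mispredicted,
  an inherent limit of the additive form.
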