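---
title: "Field-based 3D-QSAR in qsar3d: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-based 3D-QSAR in qsar3d: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsar3d)
```

## The model

qsar3d implements field-based three-dimensional quantitative
structure-activity relationship (3D-QSAR) modelling for congeneric
small-molecule series, in the CoMFA/CoMSIA tradition. The working
assumptions are the classical ones: the compounds bind non-covalently in a
common orientation, so that after rigid superposition of a shared skeleton
their activity differences are explained by differences in the interaction
fields they project into the surrounding space.

Each aligned conformer is sampled on a cubic lattice (edge length 2 Å by
default). Two families of descriptors are available per lattice node:

* **CoMFA probe energies.** A steric term from the Tripos 6-12 potential,
  $E_S = \sum_i \varepsilon_{ij}\left[(R_{ij}/r_i)^{12} - 2 (R_{ij}/r_i)^6\right]$,
  with $R_{ij} = r_i^{vdW} + r_{probe}$ and
  $\varepsilon_{ij} = \sqrt{\varepsilon_i\,\varepsilon_{probe}}$, and an
  electrostatic term from the Coulomb potential
  $E_E = \sum_i 332.0636\, q_i q_{probe} / (\varepsilon(r_i)\, r_i)$ with the
  distance-dependent dielectric $\varepsilon(r) = r$. The probe is an
  sp³-carbon-like atom: radius 1.52 Å, charge +1 e.
* **CoMSIA similarity indices.** Gaussian-attenuated similarity
  $A_k = -\sum_i w_{probe} w_{i,k}\, e^{-\alpha r_i^2}$ with attenuation
  factor $\alpha = 0.3$ Å⁻², for five physicochemical kinds $k$: steric,
  electrostatic, hydrophobic, H-bond donor and H-bond acceptor. The Gaussian
  keeps the field finite everywhere, so no energy cutoff is needed.

The descriptor matrix (compounds × lattice-nodes × kinds) is regressed
against pIC50 with partial least squares (PLS1, NIPALS). The number of
latent components is chosen by leave-one-out cross-validation: every
compound is predicted by a model refitted without it, $q^2 = 1 -
\sum(y_i - \hat y_{(-i)})^2 / \sum(y_i - \bar y)^2$, and the optimum number
of components (ONC) maximises $q^2$ with ties resolved toward fewer
components. The final model reports $r^2$, $SEE = \sqrt{RSS/(n-c-1)}$,
$F = (r^2/c)/((1-r^2)/(n-c-1))$ and per-field contributions, defined as the
normalised share of $\sum_j |\beta_j|\, s_j$ per field kind.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| grid spacing | 2.0 | Å | lattice edge length |
| grid margin | 4.0 | Å | padding around the union bounding box |
| probe radius / charge | 1.52 / +1.0 | Å / e | CoMFA probe atom |
| energy cutoff | 30 | kcal/mol | clamp for both CoMFA potentials |
| attenuation α | 0.3 | Å⁻² | CoMSIA Gaussian width |
| atomic ε | 0.107 | kcal/mol | Lennard-Jones well depth (probe and atoms) |
| column filter σ | 2.0 | field units | minimum training-column SD |
| block scaling | on | — | equal total variance per field kind |

The grid margin, the Lennard-Jones parameterisation, the column filter and
the block scaling are tool conventions rather than physical constants; all
are configurable, and the 2 kcal/mol filter appropriate for CoMFA energies
should be reduced (we use 0.02) when only similarity fields, whose dynamic
range is of order one, are in play.

## Numerical choices

* **Clamping.** CoMFA steric energies are clamped to +30 kcal/mol (a node
  coinciding with an atom gets exactly the clamp); electrostatic energies
  are clamped to ±30 kcal/mol. Nodes at the steric clamp are flagged
  *buried*, and their electrostatic values are replaced at assembly time by
  the column mean over non-buried training compounds, so that meaningless
  in-core Coulomb values never drive the regression.
* **Alignment.** Skeleton superposition uses the Kabsch SVD solution with a
  reflection guard (det(R) = +1 enforced), equal weights on all skeleton
  atoms, and an explicitly supplied atom correspondence — no substructure
  search, so the procedure is deterministic and testable. Non-skeleton
  atoms do not influence the fit.
* **Centring.** X and y are mean-centred on the training set; individual
  columns are not autoscaled (the CoMFA-STD convention), so a column's
  influence remains proportional to its field variance.
* **Degenerate inputs.** A constant response yields the zero model with
  $r^2 = 0$ by convention; requesting more components than the effective
  rank is an error; LOO silently truncates `max_components` to $n-2$ with a
  warning; collinear or coincident skeleton point sets are rejected.
* **Contours.** StDev*Coeff values (training-column SD × coefficient) are
  ranked; the favoured set collects the largest positive values until their
  cumulative share reaches 80 % of the total positive contribution, the
  disfavoured set analogously to 20 % of the negative contribution — the
  conventional display levels.
* **Duplicated columns.** PLS predictions are invariant to duplicating a
  column only at the full component count (where the fit equals the
  least-squares projection onto the unchanged column space); at smaller
  counts NIPALS re-weights the duplicated direction. The test suite asserts
  the full-rank form.

## External validation

Beyond $q^2$ and $r_{pred}^2 = 1 - PRESS/SD$ (PRESS the test-set squared
prediction error, SD the test-set squared deviation from the *training*
mean), the package implements the Golbraikh–Tropsha battery: the test-set
Pearson $R^2$; through-origin slopes $k = \sum y\hat y / \sum \hat y^2$ and
$k' = \sum y\hat y / \sum y^2$; through-origin determination coefficients
$R_0^2$ and $R_0'^2$ computed with those slopes; and
$r_m^2 = R^2(1 - \sqrt{R^2 - R_0^2})$. The battery passes when $R^2 > 0.6$,
$0.85 < k$ or $k' < 1.15$, the relative gaps $(R^2 - R_0^2)/R^2$ or
$(R^2 - R_0'^2)/R^2$ are below 0.1, $|R_0^2 - R_0'^2| < 0.3$ and
$r_m^2 > 0.5$.

Two analytical notes. First, $r_m^2$ is implemented in its square-root form;
the occasionally-typeset form without the square root does not reproduce the
reference values that the square-root form reproduces to printing precision.
Second, the radicand $R^2 - R_0^2$ is never negative — over the common
denominator $\sum(y-\bar y)^2$ the free-intercept regression residual cannot
exceed the through-origin residual — so the "undefined $r_m^2$" branch is
kept only as a numerical guard.

Y-randomization refits the model on seeded permutations of the response
(10 by default); a model whose shuffled $q^2$ ever approaches the original
is a chance correlation.

## The embedded reference series

The package embeds, as plain-text fixtures, the activity table of a
41-compound stilbene-derived series of reversible LSD1 (KDM1A) inhibitors
(pIC50 4.443–6.917, 9-compound test set, 22 %) together with its printed
CoMFA/CoMSIA predictions, the printed external-validation battery, and the
MM/GBSA energy components of four simulated ligand–LSD1 complexes.
`reproduce_paper()` recomputes everything recomputable from those tables and
compares at ±0.005 (±0.001 kcal/mol for energy sums).

Two printed oddities surface, and are flagged rather than repaired or
forced: one activity row (compound 33) carries an IC50 that disagrees with
its own pIC50 by 0.17 log units (the pIC50 is the internally consistent
cell — it equals the printed prediction plus residual exactly); and the
printed CoMSIA external-validation row is not reproducible from the printed
CoMSIA predictions (direct evaluation gives $R^2 = 0.904$ against a printed
0.861), whereas the CoMFA row reproduces throughout. The published
model-internal statistics ($q^2$, $r^2$, SEE, F, ONC, field contributions)
depend on the original tool's field implementation and on 3D structures
defined only in figures, and are therefore not numeric targets here; the
package validates those code paths with the property-based experiments
below instead.

### pIC50 convention

pIC50 is the negative decadic logarithm of the *molar* IC50 with input in
µM: $\mathrm{pIC50} = 6 - \log_{10}(\mathrm{IC50}_{\mu M})$. The convention
is forced by the reference data (0.121 µM ↔ 6.917).

## The synthetic-data generator

`generate_pseudo_compounds()` emulates what the analysis assumes: a rigid
shared skeleton (a short helix, identical local geometry in every compound),
per-compound decoration atoms with random positions, charges in ±0.5 e and
radii in 1.2–1.9 Å, and an activity that is a *linear function of the
compound's steric similarity field* evaluated at a few spatial region
centres, plus Gaussian noise:
$y = \beta_0 + \sum_k w_k (S_k - \overline{S_k}) + \mathcal N(0, \sigma)$.
Centring the field summaries makes the dataset mean equal the intercept.
Every compound is then randomly rotated and translated (up to 180° / 5 Å)
so the alignment stage is genuinely exercised; the canonical-pose template
and the region centres are returned as ground truth.

Defaults were chosen once as the study conditions: 40 compounds, 6 skeleton
atoms, 10–16 atoms total, four regions with weights (1.5, −1.0, 0.8, −0.6),
intercept 6 on the pIC50 scale, noise σ = 0.1 pIC50 units, and a mandatory
seed. With these conditions the full pipeline (align → fields → PLS → LOO)
reaches LOO $q^2 \approx 0.75{-}0.95$ and recovers the planted regional
weights with correlation > 0.95 via the Gaussian-kernel coefficient readout
`recover_region_weights()` (the readout is, equivalently, the model's
predicted activity response to placing a test atom at the queried centre).
Note the readout must be performed in the frame the centres are defined in,
i.e. the set must be aligned onto the canonical-pose template.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: chemistry (valence, bonding, tautomers, realistic
charge distributions), conformational flexibility, alignment ambiguity for
heterogeneous scaffolds, and activity cliffs not expressible as a linear
field functional. Recovery on this generator validates the statistical
machinery, not the biology.

## MM/GBSA bookkeeping

The binding free-energy module is deliberately downstream-only: it ingests
per-complex component tables ($\Delta E_{ele}$, $\Delta E_{vdW}$,
$\Delta G_{GB}$, $\Delta G_{SA}$, optional $-T\Delta S$), aggregates
$\Delta E_{gas} = \Delta E_{vdW} + \Delta E_{ele}$,
$\Delta G_{sol} = \Delta G_{GB} + \Delta G_{SA}$,
$\Delta G_{bind} = \Delta E_{gas} + \Delta G_{sol} - T\Delta S$ (entropy
omitted by default, matching common practice), cross-checks optional raw
per-species totals, and ranks complexes against pIC50 (Spearman ρ between
$-\Delta G_{bind}$ and pIC50, ties broken by complex id). It does not run
dynamics or solvation calculations.

## Problem sizes

The test suite and the acceptance script run the synthetic experiment at
its default size (40 compounds, ~1 100 lattice nodes, one similarity field,
LOO over up to 10 components) and 10 Y-randomization shuffles; a full run
takes on the order of a second on one core. Field oracles are checked on
20-atom random molecules against naive per-atom sums at 10⁻¹⁰.

## Known limitations

* Conformer generation, energy minimisation, docking and molecular dynamics
  are out of scope; conformers are accepted as given (SDF/MOL2).
* CoMSIA hydrophobic atom weights use a documented element rule (C +1,
  halogens +0.5, N/O −1, H/S 0) rather than fitted logP increments; they
  are overridable per atom via the structure table.
* H-bond donor detection needs explicit hydrogens (an N/O with an H within
  1.2 Å); structures without explicit hydrogens get acceptor flags only.
* The skeleton correspondence is supplied, not searched; flexible or
  maximum-common-substructure alignment is out of scope.
* Reproducing another tool's internal $q^2$/$r^2$ requires that tool's
  exact field and scaling implementation; such values are treated as
  non-reproducible and validated by property instead.
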