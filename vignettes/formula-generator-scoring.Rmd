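---
title: "Discovering nonlinear scoring functions from FMO and hydrophobic-probe descriptors"
author: "fgscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering nonlinear scoring functions from FMO and hydrophobic-probe descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgscore)
```

## The problem

Binding of small-molecule inhibitors to metalloenzymes such as human
carbonic anhydrase II (hCA II) is dominated by interactions that classical
force fields describe poorly: the coordination of the anionic
benzenesulfonamide head to the active-site Zn^2+^ ion is charged,
polarizable and charge-transfer-heavy, while the aromatic tail of the
ligand buries itself against hydrophobic side chains.  A practical scoring
function for such systems therefore needs two ingredients that usually
come from different worlds: quantum-mechanical interaction energetics and
an empirical account of hydrophobic burial.

`fgscore` implements the post-processing and machine-learning side of such
a pipeline.  The quantum chemistry itself (fragment molecular orbital,
FMO2, calculations with solvation) and the lipophilicity prediction happen
upstream in external engines; this package consumes their outputs and
turns them into interpretable scoring functions.

## Descriptors

Four FMO-derived descriptors enter the models:

* **E^INT^** — the sum of pair interaction energies (PIEs) between the
  ligand fragment and every receptor fragment, from a pair interaction
  energy decomposition analysis (PIEDA).  Each PIE splits into
  electrostatic, exchange-repulsion, charge-transfer, dispersion and
  solvation components; `parse_pieda_output()` reads these tables and
  `check_pieda_decomposition()` verifies that components sum to totals
  (default tolerance 0.05 kcal/mol, the rounding of printed tables).
* **ΔE^FMO^** — the supermolecular binding energy
  `E_LR − (E_R + E_L)` from `fmo_binding_energy()`, which additionally
  captures polarization-destabilization and desolvation.
* **FE** and **F2LE** — the two energies divided by the ligand heavy-atom
  count (`efficiency_normalize()`), removing the size dependence of
  interaction-energy magnitudes.

Two hydrophobic descriptors complement them:

* **HIE** — the hydrophobic interaction energy from a neutral probe moved
  over a 3D grid around the structure (`build_grid()`,
  `compute_field()`).  At each point the probe feels a 12-6
  Lennard-Jones term, a *sign-inverted* hydrogen-bond penalty near polar
  atoms (polar contacts are unfavourable for a hydrophobic probe), and a
  constant hydration-entropy reward of −0.848 kcal/mol.  There is no
  electrostatic term: the probe is neutral.
* **HIE-E** — HIE per heavy atom (`hie_efficiency()`).

`logP`, the octanol/water partition coefficient, is taken as an input
column (its prediction is out of scope).

Experimental labels are binding free energies obtained from inhibition
constants via `delta_g_from_ki()`: ΔG = RT ln K_i with
R = 1.9872×10^−3^ kcal/(mol·K) and a default temperature of 298.15 K
(configurable; the conversion temperature used for the original hCA II
inhibition data is not recorded, so the conventional laboratory value is
the default).

The nine-ligand hCA II descriptor table ships as `hca2_dataset()`.  Its
energies come from FMO2 RI-MP2/PCM calculations and a proprietary
hydrophobic force field; **they are reference inputs and cannot be
regenerated by this package**.  The heavy-atom counts stored with the
table were derived once from the mutual consistency of the printed
energy/efficiency ratios (every count reproduces FE, F2LE and HIE-E at
1-decimal rounding).  Experimental labels are user-supplied
(`hca2_labels()`), since the underlying inhibition constants belong to the
primary literature.

## The formula generator

The core contribution is a symbolic-regression-by-enumeration engine.
Starting from a set of basic properties (BPs), it applies seven prototype
functions — x, x², x³, x⁴, x⁵, e^x and √x — and combines the transformed
terms into rational *basic features* (BFs) with two generators:

* `ratio3`: `[f(BP1) ∘ f(BP2)] / f(BP3)` with three distinct BPs;
* `ratio4`: `[f(BP1) ∘ f(BP2)] / [f(BP3) ∘ f(BP4)]` with three or four
  distinct BPs (one BP may appear on both sides of the ratio),

where `∘` is addition, subtraction or multiplication.  Even powers and the
square root are restricted to positive-definite BPs, because they destroy
sign information or leave the real domain.  Each BF is fit to the label by
single-feature ordinary least squares and ranked by R².  The top ten
formulas per generator then enter an exhaustive grid search over per-term
weights a, b, c (and d) on `{0, 0.1, ..., 1}`, with the slope and
intercept refit at every tuple; leave-one-out cross-validation reports an
overfitting-aware error for the winners.

```{r search-example, eval = FALSE}
tab <- make_feature_table(synthetic_spec(seed = 42, n_samples = 20, noise_sd = 0))
res <- run_search(tab, basic_properties(c("logP", "HIE_E", "F2LE")))
res$summary[1, c("generator", "r2", "rmse", "loocv_rmse")]
```

### Enumeration conventions

Several conventions pin down the enumeration exactly (they are verified
against an independent brute-force oracle in the test suite; three
unrestricted BPs give exactly 768 `ratio3` features):

* Term pairs are **unordered** for `+` and `×` (which commute) and
  **ordered** for `−`, so algebraically identical strings are not double
  counted.
* Both numerator terms use distinct BPs; `ratio3` uses three distinct BPs
  in total (the all-distinct reading is adopted for symmetry with the
  stated `ratio4` rule).
* Descriptors that represent the same physical quantity — here the four
  FMO binding-strength estimates — form an *exclusivity group*
  (`hca2_basic_properties()`), and a formula may contain at most one
  member of each group.

### Numerical choices

* Samples whose denominator magnitude falls below 10^−9^, or that violate
  a prototype-function domain, are flagged invalid; a formula with any
  invalid training sample is discarded during the search.
* `e^x` clamps its argument at |x| ≤ 50 to avoid overflow; non-finite
  features are discarded.
* Weight tuples whose weighted numerator or denominator is identically
  zero are skipped as degenerate.
* Grid-search ties are broken toward the lexicographically largest weight
  tuple, making the optimizer fully deterministic.  Note the inherent
  scale degeneracy: multiplying both numerator weights by λ multiplies the
  feature by λ and divides the refit slope by λ, leaving predictions
  unchanged — maximal tuples come in equivalence classes.
* LOOCV refits only the slope and intercept in each fold; the weights are
  considered part of the formula's identity.  `refit_weights = TRUE`
  offers the stricter protocol that re-runs the grid search per fold.
* R² is reported as the squared correlation between prediction and label
  (the R² of the correlation line through the scatter plot, which for a
  refit line coincides with the regression convention); RMSE is computed
  directly on prediction − label.  A zero-variance label defines R² = 0.

### The published hCA II scoring function

`hca2_scoring_function()` packages the nonlinear function discovered on
the nine-ligand set,

ΔG = −7.4 · {[0.7·logP³ − 0.5·e^HIE-E^] / [0.5·F2LE³ − 0.4·HIE-E⁵]} − 13,

with its coefficients stored exactly as published and never refit on
load.  Its numerator contains only hydrophobicity descriptors; its
denominator balances the polar/electrostatic FMO ligand efficiency
against the hydrophobic efficiency.

```{r eval-example}
pred <- evaluate_scoring_function(hca2_scoring_function(), hca2_dataset())
round(pred, 2)
```

## The hydrophobic probe in detail

The probe evaluator is a *generic*, GRID-like implementation with an
editable parameter table (`default_probe_params()`); it is not a
reimplementation of the proprietary force field, and the packaged HIE
values are not expected to be regenerated by it.  Defaults: grid spacing
0.5 Å, margin 4 Å, Lennard-Jones cutoff 8 Å, hydrogen-bond cutoff 5 Å,
core clamp +5 kcal/mol.  The hydrogen-bond radial form is
ε_hb[2(r₀/r)⁶ − 3(r₀/r)⁴] (minimum −ε_hb at r₀); its *negated* attractive
part is added as a penalty, so polar surfaces repel the probe.  Beyond the
cutoff radius from every atom the field equals the entropy constant
exactly.  That constant is stored as the literal −0.848 kcal/mol rather
than recomputed from RT ln 4, since the temperature implied by the
published figure (~308 K) conflicts with the usual 298 K convention.

The reduction of a field to the scalar HIE is deliberately configurable
(`aggregate_hie()`: sum of points below −1 kcal/mol by default, or the
field minimum, or the sum over local minima), because the exact reduction
used to produce the reference values is not public.  Whether the field is
computed over the ligand alone or the whole complex is likewise the
caller's choice.

## The reduced binding core

For FMO calculations at tractable cost, each complex is reduced to a
*core model*: all residues with any heavy atom within 6 Å of the ligand
(`select_pocket()`; the distance criterion uses heavy atoms only by
default because deposited crystal structures usually lack hydrogens),
unified across all complexes of a congeneric series
(`union_pockets()`, which refuses silently-mismatched residue numbering),
plus the metal ion and the ligand.  Severed backbone bonds are capped with
hydrogens placed along the former bond vector at standard lengths
(N–H 1.01 Å, C–H 1.09 Å) by `cap_termini()`, with no subsequent geometry
optimization — optimization is out of scope, so selections computed on
raw X-ray coordinates can differ marginally (about one residue) from
selections computed on force-field-prepared structures.  Alternate
conformers resolve to the highest-occupancy copy; waters are excluded by
default.  `split_ligand()` separates the zinc-binding sulfonamide head
(F1, identified by its sulfonamide sulfur, or by a user anchor) from the
hydrophobic tail (F2) at a user-named single bond, capping F1 with H and
F2 with a methyl group.

## What the synthetic generator does and does not emulate

`synthetic_spec()` / `make_feature_table()` generate feature tables whose
labels follow a known planted formula plus Gaussian noise.  The defaults
mirror the study conditions: nine samples, three sign-indefinite
descriptors with logP-, HIE-E- and F2LE-like ranges, the published
formula structure and weights, and 0.3 kcal/mol label noise (about the
published model RMSE).  The generator emulates the *statistical* shape of
the problem — small n, correlated nonlinear features, modest noise — and
is the basis of the package's recovery tests.  It does not emulate the
physics: descriptor correlations induced by shared molecular structure,
heteroscedastic experimental error, or systematic preparation effects.
A passing recovery test therefore demonstrates the correctness of the
search machinery, not the accuracy of any particular scoring function on
real data.

PIEDA text fixtures (`make_pieda_fixture()`) and minimal PDB layouts
(`make_pdb_fixture()`) are likewise exact-by-construction inputs for the
parser and pocket modules.

## Known limitations

* The enumerate–rank–optimize funnel screens formulas by their
  *unweighted* fit before optimizing weights.  A generating formula whose
  true weights are far from 1 can rank below the top-N cut and be missed:
  on some seeded synthetic tables the search returns a different formula
  with lower R² than the planted one would reach after optimization.
  Raising `top_n` widens the funnel at linear cost in the optimization
  stage.
* With ten samples or fewer, formulas with near-perfect training R² are
  abundant; the LOOCV error and the physical plausibility of the terms,
  not training R² alone, should drive model selection.
* The probe evaluator's generic parameters make HIE values internally
  consistent but not comparable to those of any proprietary
  parameterization.
* Problem sizes used throughout the test suite (chosen as representative
  desk-scale cases): 3–4 BPs for enumeration oracles, 9–20 samples for
  search and recovery, grids of up to ~10^5^ points for field tests.
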