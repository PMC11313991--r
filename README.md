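# fgscore

Interpretable scoring functions for metalloenzyme–ligand binding affinity,
discovered by combinatorial symbolic regression over quantum-chemical and
hydrophobic descriptors.

## What this is for

Predicting how strongly a small molecule binds a metalloenzyme is hard for
classical scoring functions: metal coordination is dominated by
polarization and charge transfer, which only quantum-mechanical (QM)
treatments capture, while the rest of the binding is often driven by
hydrophobic burial, which desk-scale QM misses.  The practical remedy is
to compute a few physically meaningful descriptors — fragment molecular
orbital (FMO2) interaction energies, hydrophobic-probe field energies,
logP — and learn an empirical function of them against measured
affinities.

`fgscore` is an R implementation of that workflow for people building
QM-based empirical scoring functions (the worked case is a congeneric
series of benzenesulfonamide inhibitors of human carbonic anhydrase II,
a Zn^2+^ enzyme):

* **Formula generator (the core)** — enumerate every rational combination
  `[f(BP1) ∘ f(BP2)] / f(BP3)` and `[f(BP1) ∘ f(BP2)] / [f(BP3) ∘ f(BP4)]`
  of basic properties under seven prototype functions
  (x, x², x³, x⁴, x⁵, eˣ, √x), rank candidates by single-feature linear
  regression, refine the best by an exhaustive grid search over per-term
  weights (step 0.1 on [0, 1], slope/intercept refit at every tuple), and
  cross-validate by leave-one-out.  The result is a human-readable formula
  `ΔG = m·{[a·f(BP1) ∘ b·f(BP2)] / [c·f(BP3) ∘ d·f(BP4)]} + q`, not a
  black box.
* **FMO/PIEDA post-processing** — parse pair-interaction-energy
  decomposition tables from FMO2 output, check the decomposition closure,
  compute the ligand interaction energy E^INT, the binding energy ΔE^FMO,
  per-heavy-atom efficiencies (FE, F2LE) and per-residue interaction
  profiles.
* **Hydrophobic (DRY-like) probe** — evaluate a neutral probe on a 3D
  grid (12-6 Lennard-Jones + inverted hydrogen-bond penalty + constant
  hydration-entropy term −0.848 kcal/mol, no electrostatics) and reduce
  the field to the scalar HIE and its per-heavy-atom efficiency.
* **Binding-core reduction** — select pocket residues within a distance
  cutoff of the ligand from PDB structures, take the union across a
  congeneric series, cap severed backbone bonds with hydrogens, split
  ligands into head/tail fragments, and emit fragment annotations.
* **Validation utilities** — correlation metrics, multilinear baselines,
  K_i → ΔG conversion (RT ln K_i), and deterministic synthetic-data
  generators for everything above.

## Worked example

The packaged scoring function for the hCA II benzenesulfonamide series,

ΔG = −7.4·{[0.7·logP³ − 0.5·e^HIE-E^] / [0.5·F2LE³ − 0.4·HIE-E⁵]} − 13,

applied to the packaged nine-ligand descriptor table:

```r
library(fgscore)
pred <- evaluate_scoring_function(hca2_scoring_function(), hca2_dataset())
round(pred, 2)
#> [1] -14.53 -13.52 -14.41 -13.52 -13.20 -12.79 -12.98 -13.05 -12.81
```

Ligand 1 — the most lipophilic compound with the most favourable
hydrophobic field energy — is predicted to bind most strongly
(−14.53 kcal/mol); the span of ~1.7 kcal/mol across the series comes
almost entirely from the hydrophobic terms, which is the chemical message
of the formula.

Discovering a formula from scratch on a synthetic table with a known
generating model (zero noise, 20 samples):

```r
tab <- make_feature_table(synthetic_spec(seed = 42, n_samples = 20, noise_sd = 0))
res <- run_search(tab, basic_properties(c("logP", "HIE_E", "F2LE")))
res$summary[1, c("generator", "r2", "rmse", "loocv_rmse")]
#>   generator        r2       rmse  loocv_rmse
#> 1    ratio4 0.9944956 0.06002286  0.0640583
```

The search enumerates 25,344 candidate features, ranks them, grid-searches
weights for the top ten per generator and recovers a formula explaining
99.4% of the variance of the planted model.

Command-line wrappers for each stage live in `inst/scripts/`
(`fg-search.R`, `sf-eval.R`, `fmo-terms.R`, `hie.R`, `reduce-pocket.R`),
e.g.

```sh
Rscript inst/scripts/fg-search.R --features table.csv --label dG_exp --out formulas.json
```

## Scope notes

The quantum chemistry itself (FMO2 RI-MP2/PCM energies), force-field
geometry preparation and logP prediction happen upstream in external
engines; their outputs are inputs here.  The packaged hCA II descriptor
values are reference data from such engines and are not regenerable at
desk scale — the probe module is a generic, configurable evaluator, not a
clone of any proprietary parameterization.
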