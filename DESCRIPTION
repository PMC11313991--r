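Package: fgscore
Title: Formula-Generator Scoring Functions for Metalloenzyme-Ligand Binding
    Affinity from FMO and Hydrophobic-Probe Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers empirical scoring functions for ligand-metalloenzyme
    binding affinity by combinatorial symbolic regression (the "formula
    generator"): basic molecular descriptors are combined through prototype
    functions into rational basic features, ranked by single-feature linear
    regression, and refined by an exhaustive grid search over per-term
    weights with leave-one-out cross-validation. Companion modules parse
    FMO2/PIEDA fragment pair-interaction-energy tables from quantum-chemistry
    output, evaluate a GRID-like hydrophobic (DRY) probe field on a 3D grid
    and reduce it to hydrophobic interaction energies, build reduced
    binding-core models from PDB structures (distance-cutoff residue
    selection, pocket union, hydrogen capping, ligand fragment splitting),
    and convert inhibition constants to experimental binding free energies.
    Ships the nine-ligand human carbonic anhydrase II benzenesulfonamide
    descriptor set and the published nonlinear scoring function derived
    from it.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
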