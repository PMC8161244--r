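Package: rednmf
Title: Rare Event Detection in Molecular Dynamics Trajectories by
    Non-Negative Matrix Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects rare conformational-transition events in molecular
    dynamics trajectories of proteins (designed around G-protein-coupled
    receptors).  Residue-residue contact maps are built per frame at a
    distance cutoff, flattened to a feature-by-time matrix, smoothed with a
    sliding window, and factorized by non-negative matrix factorization with
    deterministic NNDSVD initialization into structural archetypes (W) and
    temporal weights (H).  Transitions of dominance between consecutive
    components are reported as events together with the residue pairs that
    drive them.  Companion structural metrics (intracellular-cavity water
    counts, helix bend/wobble angles, residue-pair distances, transmembrane
    selections and superposition RMSD) support the functional interpretation
    of each event.  A synthetic-data module generates trajectories and
    contact series with planted transitions so the whole pipeline is
    testable without MD data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
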