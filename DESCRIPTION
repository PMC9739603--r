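Package: fwbench
Title: Free-Wilson Benchmarking of Protein-Ligand Scoring Functions
Version: 0.1.0
Authors@R:
    person("fwbench", "maintainers", email = "fwbench@example.org", role = c("aut", "cre"))
Description: Diagnoses the residual errors of protein-ligand scoring functions in
    terms of medicinal-chemistry interaction fragments. Counts interaction-motif
    fragments in ligands via SMARTS patterns to build a Free-Wilson occurrence
    matrix, applies an uncentered-cosine correlation filter and per-feature
    standardization, and fits L1-regularized (Lasso) regression paths relating
    experimental affinities, scoring-function predictions, and fragment presence.
    Includes a minimal solvent-accessible-surface-area scoring function (delta SAS,
    Shrake-Rupley) and a synthetic-data generator with known ground truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
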