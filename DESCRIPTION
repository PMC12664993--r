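Package: pentagate
Title: Gating Metrics and Calcium-Site Analysis for Pentameric Ligand-Gated Ion Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conformational analysis of pentameric ligand-gated ion channel
    (pLGIC) structures and molecular dynamics trajectories. Computes per-subunit
    ECD-twist dihedral and beta-expansion gating coordinates, tracks rigid-body
    displacement of periplasmic N-terminal domain (NTD) lobes after
    transmembrane-domain alignment, profiles the transmembrane pore radius with
    a largest-inscribed-sphere probe, and characterizes bound-cation
    coordination shells and residence through trajectories. Ships a synthetic
    pentamer and trajectory generator with exactly known ground truth so every
    metric is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
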