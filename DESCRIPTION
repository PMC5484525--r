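Package: msdesign
Title: Multi-State Protein Sequence Design with a Genetic Algorithm
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A modular framework for multi-state computational protein
    design (MSD). A genetic-algorithm sequence optimizer is strictly
    separated from pluggable per-state evaluators and combined through
    user-defined fitness functions (mean-over-states or
    positive/negative design). Includes native sequence recovery (nsr)
    and BLOSUM62-based native sequence similarity recovery (nssr)
    metrics, a Monte-Carlo simulated-annealing single-state baseline
    (SSD), synthetic multi-state sequence-energy landscapes with a
    planted native optimum and a brute-force enumeration oracle, a
    distance-based design/repack shell detector for PDB ensembles with
    a bound ligand, and an SSD-versus-MSD benchmarking harness with
    convergence curves, per-protein summaries, ensemble grouping and a
    Wilcoxon signed-rank comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    parallel,
    jsonlite,
    yaml,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
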