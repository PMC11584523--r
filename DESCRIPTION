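Package: tunneldyn
Title: Tunnel Dynamics in Protein Snapshot Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transport tunnels in ensembles of protein structure
    snapshots with a probe-constrained voxel-grid shortest-path search,
    clusters per-frame tunnels within trajectories and merges them across
    replicates and conditions into superclusters, and computes
    tunnel-dynamics statistics: detection frequency, bottleneck-radius
    summaries and distributions, open-state dwell durations, cluster
    discovery curves, and replicate-level two-condition comparisons with
    Welch t tests. Includes a synthetic-data module that builds toy shell
    structures with gated channels driven by a continuous-time two-state
    Markov gating model, so that every statistic can be validated against
    known ground-truth kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
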