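# tunneldyn

Tunnel dynamics in protein snapshot ensembles: detection, superclustering,
and replicate-level statistics of transport-tunnel gating.

## What it is for

Enzymes with buried active sites exchange ligands and solvent through
transport tunnels whose lining residues open and close like molecular gates.
Given an ensemble of structure snapshots (trajectory frames in PDB format,
or synthetic ensembles generated in-package), `tunneldyn` answers the
questions practitioners ask of such data:

- How often is each tunnel open (**detection frequency**, fraction of frames
  with bottleneck radius BR > 0.7 Å)?
- How wide is it (**mean/max BR**, BR distributions) and how long?
- How long do **open states** (BR ≥ 1.4 Å) persist before closing?
- How quickly do new tunnel clusters appear (**discovery curves**), and how
  many distinct clusters does each condition find?
- Do two conditions (e.g. two solvent models) **differ significantly** in any
  of these metrics, given 3–4 replicates each?

The core computation per frame is a probe-constrained grid search: the free
radius field r(v) = min over atoms of (‖v − atom‖ − vdW radius) is computed
exactly on a voxel grid; bulk solvent is the flood-fill of {r ≥ shell
radius} from the box boundary; tunnels are Dijkstra-optimal paths from a
buried start point over voxels with r ≥ probe radius under edge cost
step × r(target)⁻², trimmed by the shell depth and de-duplicated at a 4.5 Å
exit threshold. Per-frame tunnels are clustered within each trajectory
(average linkage on an arc-length spine metric, 4.5 Å cut; clusters in
> 5% of frames kept) and merged across replicates and conditions into
superclusters (Ward linkage, 1 Å cut, minimum BR 0.7 Å and length 5 Å).
Statistics are computed per supercluster × replicate and compared across
conditions with Welch t tests (untestable cells — tunnels found in a single
replicate — are flagged, not dropped).

A first-class synthetic-data module builds toy shell structures with gated
channels driven by an exact continuous-time two-state Markov gating model
(exponential dwells, Gaussian radius noise, 20 ps sampling), so every
statistic can be validated against known ground truth. See the methods
vignette (`vignettes/tunnel-dynamics.Rmd`) for the models, parameter
rationale, and limitations.

## Worked example

```r
library(tunneldyn)

study <- run_gating_study(seed = 1, n_frames = 2000,
                          replicates_per_condition = 3, verbose = FALSE)

study$counts
#> # A tibble: 2 × 2
#>   condition n_superclusters
#>   <chr>               <int>
#> 1 A                       2
#> 2 B                       2

study$frequency
#> # A tibble: 12 × 5
#>    supercluster_id condition replicate_id detection_frequency n_frames
#>              <int> <chr>     <chr>                      <dbl>    <int>
#>  1               1 A         A_rep1                     0.511     2000
#>  2               1 A         A_rep2                     0.505     2000
#>  3               1 A         A_rep3                     0.514     2000
#>  4               1 B         B_rep1                     0.335     2000
#>  5               1 B         B_rep2                     0.306     2000
#>  6               1 B         B_rep3                     0.332     2000
#>  7               2 A         A_rep1                     0.292     2000
#>  ...
```

Both engineered channels are recovered as one supercluster each, and the
per-replicate detection frequencies track the generator's stationary open
probabilities (0.5 and 0.25 in condition A; 1/3 and 0.25 in condition B —
the main gate closes twice as fast in condition B). `tidy(study$comparison)`
lists per-metric Welch tests; `autoplot(study$comparison)` and
`autoplot(study$discovery)` draw the replicate mean ± SD bars and the
cluster discovery curves.

For real data, the same steps run individually:

```r
ens      <- read_pdb_frames(Sys.glob("frames/*.pdb"), condition = "modelA")
start    <- compute_start_point(get_snapshot(ens, 1),
                                c("HIS:57", "ASP:102", "SER:195"))
profiles <- detect_tunnels(ens, start, detection_params())
clusters <- cluster_within_trajectory(profiles, n_frames(ens)) |>
  filter_rare(n_frames(ens))
sc       <- merge_superclusters(clusters, profiles)
series   <- bottleneck_series(sc, n_frames(ens))
metric_table(series) |> compare_conditions()
```

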