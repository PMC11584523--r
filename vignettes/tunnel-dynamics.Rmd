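---
title: "Tunnel dynamics in snapshot ensembles: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tunnel dynamics in snapshot ensembles: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tunneldyn)
library(dplyr)
```

## The problem

Enzymes with buried active sites exchange substrates, products and solvent
with the bulk through transport tunnels. These tunnels are not static: lining
residues act as molecular gates that open and close on nanosecond and
sub-nanosecond timescales, so a tunnel's *bottleneck radius* (BR) — the radius
of the narrowest sphere along its spine — is a fluctuating time series, and
functionally meaningful statements ("the main tunnel is open 99% of the time",
"open states persist for 20–100 ps") are statements about the distribution of
that series across an ensemble of structure snapshots and across independent
trajectory replicates.

`tunneldyn` implements the full chain of computations behind such statements:

1. **Detection** — find tunnels in each snapshot with a probe-constrained
   grid search from a buried start point to bulk solvent.
2. **Clustering** — group per-frame tunnels into clusters within a
   trajectory, discard rarely seen ones, and merge clusters across replicates
   and conditions into *superclusters* so that "the same tunnel" has one
   identity everywhere.
3. **Dynamics statistics** — detection frequencies, BR summaries and
   histograms, open-state dwell durations, and cluster discovery curves.
4. **Comparison** — replicate-level means ± SD per condition and Welch
   t tests per supercluster and metric, with explicit "untestable" marking
   where a tunnel was seen in a single replicate.

Because validating these computations against real molecular-dynamics output
would require an external tunnel-detection program as ground truth, the
package instead ships a **synthetic-data module**: toy structures with
engineered channels whose gating kinetics are exactly known. Every statistic
the package reports is validated against that ground truth in the test suite.

## Tunnel detection

### Free-radius field and bulk

A snapshot is voxelised at `grid_spacing` (default 0.5 Å). The *free radius*
at a voxel centre $v$ is

$$ r(v) \;=\; \min_a \big( \lVert v - x_a \rVert - \rho_a \big), $$

the radius of the largest sphere centred at $v$ touching no atom ($x_a$,
$\rho_a$ are atom centres and van der Waals radii). The field is exact — an
expanding cell-ring search finds the true minimum for every voxel — and the
test suite checks it against a brute-force minimum over all atoms at
tolerance $10^{-9}$.

*Bulk solvent* is the set of voxels with $r(v) \ge$ `shell_radius` (default
3 Å) that are flood-fill reachable from the grid boundary. The reachability
condition matters: a wide internal cavity is not bulk. Everything else is
*interior*.

### Search

Tunnels are cheapest paths in the 26-connected graph over interior voxels
with $r(v) \ge$ `probe_radius` (default 0.7 Å), with edge weight

$$ w(u \to v) \;=\; \lVert u - v \rVert \cdot r(v)^{-c}, $$

where the cost exponent $c$ (default 2) makes wide corridors strongly
preferred, following the cost law used by grid- and Voronoi-based tunnel
finders. Dijkstra from the start voxel (ties broken by voxel index, so the
search is deterministic and independent of atom order) yields optimal paths;
the suite checks path costs against an independent `igraph` shortest-path
oracle on instances up to $20^3$ voxels, exactly.

The start point is typically the mass-weighted centre of a few active-site
residues (`compute_start_point()`). If its voxel is narrower than the probe
it is snapped to the nearest traversable voxel within 3 Å (with a warning);
a start point in bulk is an error, since the search presumes a buried site.

### Exits, redundancy, trimming

Interior voxels adjacent to bulk are candidate tunnel exits. Candidates are
processed in ascending path cost; a candidate is suppressed when its exit
lies within `duplicate_threshold` (default 4.5 Å) of an already kept exit,
**or** when its path passes within that distance of a kept exit. The second
clause is the package's redundancy rule: on any closed protein-like surface
the probe-accessible layer just outside the atoms is connected, so every
surface voxel is "reachable" from an open mouth by creeping along the
surface — such paths re-use an existing mouth and are not separate tunnels.
With this rule a sealed toy shell yields zero tunnels, one engineered
channel yields exactly one, and two antipodal channels yield exactly two
(all tested).

Kept paths are trimmed from the bulk end by `shell_depth` (default 4 Å) of
arc length — the same role the shell-depth parameter plays in established
tunnel software: suppressing the shallow surface funnel that belongs to
solvent rather than to the tunnel. Paths shorter than the trim depth are
discarded as surface dimples. The trimmed path becomes a spine of spheres
(voxel centres with their free radii), from which `profile_geometry()`
computes the bottleneck radius (minimum sphere radius) and length (polyline
length).

Grid resolution is an accuracy/runtime dial: the detected BR is within one
`grid_spacing` of the engineered truth on toy channels, and the suite checks
that the error shrinks as the grid refines (1.0 → 0.5 → 0.25 Å). Because the
toy channels run through lattice-aligned voxel columns, the analyses in this
vignette and the study pipeline default to a 1 Å grid, which separates the
toy's open (1.6 Å) and closed (0.4 Å) states by far more than the grid
error; 0.5 Å remains the package default for general structures.

## Clustering into superclusters

The distance between two tunnels resamples each spine to `spine_samples`
(default 20) points equidistant in arc length and averages the point-wise
Euclidean distances. This arc-length-correspondence metric is symmetric,
zero exactly for identical spines, and equals the obvious brute-force
computation (tested to $10^{-9}$).

Within a trajectory, tunnels are clustered by average-linkage agglomeration
with the dendrogram cut at `within_threshold` (default 4.5 Å); within a
cluster at most one tunnel per frame survives (the cheapest), and cluster
ids are ordered by occurrence. Clusters observed in **strictly more than**
`min_occurrence_fraction` (default 5%) of frames are retained — a cluster in
exactly 5.00% of 2000 frames is dropped, one in 5.05% is kept; the boundary
is unit-tested because off-by-one-frame behaviour here changes which
tunnels exist downstream.

Across replicates and conditions, each retained (replicate, cluster) is
represented by the point-wise mean of its members' resampled spines;
tunnels narrower than `min_tunnel_radius` (0.7 Å) or shorter than
`min_tunnel_length` (5 Å) are excluded first. Representatives are merged by
Ward-linkage clustering cut at `merge_cutoff` (default 1 Å). Ward heights
are variance-based rather than raw distances, so the absolute cutoff is not
comparable across distance conventions; the default is calibrated on the
synthetic two-channel system, where within-channel representative distances
are well below 1 and between-channel distances are tens of Å, making the
recovery of exactly one supercluster per engineered channel insensitive to
the precise value. Supercluster ids are ordered by total occurrence, and a
(replicate, frame) contributes at most one tunnel per supercluster.

Batch processing (`chunk_size`) exists purely as a memory/compute-management
device for long trajectories; chunked and unchunked runs produce identical
superclusters, and the suite asserts bit-identical results for a 10-batch
split.

## Dynamics statistics

`bottleneck_series()` expands supercluster membership onto the full frame
grid with `NA` where the tunnel was not detected. All statistics treat
absence explicitly:

- **Detection frequency**: fraction of frames with a present BR **strictly
  greater than** `detection_threshold` (default 0.7 Å, the probe radius) —
  a BR exactly at the threshold is not detected.
- **BR summaries and histograms**: over detected frames only; a replicate
  with no detections reports `NA`, never zero. Histogram bins are half-open
  `[e_i, e_{i+1})` with a final open overflow bin, so masses sum to one.
  The default 0.1 Å bins from 0.7 to 3.0 Å resolve the radius ranges in
  which gating effects show up (e.g. 0.7–0.9 Å vs 1.4–2.1 Å).
- **Open-state dwells**: maximal runs of consecutive frames with BR ≥
  `open_threshold` (default 1.4 Å — a *functional* openness threshold, twice
  the detection probe, chosen to capture states wide enough for ligand
  passage; a frame exactly at 1.4 Å is open). An absent frame closes a run:
  an undetected tunnel has no BR at all, hence none ≥ 1.4 Å. A run of $L$
  frames lasts $L \times$ `frame_spacing`, so a single open frame lasts one
  frame interval (0.02 ns at 20 ps sampling). Runs touching either end of
  the series are *censored* — their true duration is only bounded below —
  and are excluded from histograms under the default policy (`"flag"`),
  with `"include"` available; with inclusion, summed run durations account
  exactly for every open frame (tested on 1000 random series). Dwell
  histograms use a geometric bin ladder from one frame interval past 8 ns
  (`default_dwell_bins()`), since dwell durations span orders of magnitude;
  the ladder is fully configurable.
- **Discovery curves**: per replicate, the cumulative count of distinct
  superclusters first seen by time $t$; across replicates the mean and the
  min/max envelope, plus each replicate's saturation time (its last first
  detection).

## The synthetic generator

### Toy structure

`build_toy_structure()` packs pseudo-atoms (radius 1.7 Å, carbon-like) on a
cubic lattice (1.2 Å) filling a spherical wall between `cavity_radius`
(6 Å) and `cavity_radius + shell_thickness` (11 Å) — small enough that a
frame is detected in ~10 ms, tight enough (lattice ≤ atom radius) that the
wall is impassable to a 0.7 Å probe. Each channel is a radial cylindrical
perforation; a ring of gate atoms at mid-shell constricts it to the
channel's `free_radius`, which is also the gate's geometric maximum opening.
`realize_trajectory()` displaces the ring radially per frame so the
channel's minimal free radius equals a prescribed series value; requesting
more than the geometric maximum is an error, and the generator truncates
observation noise at that maximum just as it truncates at zero.

### Gating kinetics

`simulate_gating()` is an exact continuous-time two-state Markov simulation:
open/closed holding times are exponential with rates `k_close`/`k_open`, and
the state is then *sampled* on the 20 ps frame grid. Simulating in
continuous time and sampling — rather than flipping a per-frame Bernoulli
coin — preserves the exact exponential dwell laws and reproduces the
aliasing a real trajectory saved at fixed intervals exhibits: sub-frame
excursions are invisible, and frame-sampled run lengths are biased upward
relative to the true dwells (at $k_{open}=k_{close}=5\,\mathrm{ns}^{-1}$ and
20 ps sampling the sampled mean open run is $\approx 0.221$ ns against the
true 0.2 ns). For this reason the simulator returns the continuous-time
segment table alongside the sampled series, and dwell-recovery checks use
the segments: their mean matches $1/k_{close}$ within sampling error and
their distribution passes a KS test against the exponential law.

Observed radii add Gaussian noise (SD `noise_sd`) to the state radius,
truncated at zero; the default SD is kept small relative to the state
separation so truncation bias is negligible.

### Study defaults

The default study emulates a few-replicate two-condition comparison:

| parameter | value | rationale |
|---|---|---|
| frame spacing | 0.02 ns | 20 ps trajectory saving interval |
| replicates | 3 per condition | typical few-replicate design |
| channels | 2, antipodal | distinct main and side tunnel |
| geometric max opening | 2.0 Å | comfortably above the open state |
| $r_{open}$ / $r_{closed}$ | 1.6 / 0.4 Å | straddle both the 0.7 Å probe and the 1.4 Å open threshold, so closed frames are genuinely undetectable |
| noise SD | 0.1 Å | ≈ r_closed/3; mis-classification across 0.7 Å is a ≈3σ event |
| gate rates | 10/10, 5/15 (A); 10/20, 5/15 (B) | mean dwells 50–100 ps, the dominant gating timescale at 20 ps sampling; condition B closes the main gate twice as fast, emulating a solvent-model effect on gating |

With these defaults the stationary open probabilities are 0.5 and 0.25 in
condition A and 1/3 and 0.25 in condition B, and the end-to-end test
demands: exactly two superclusters per condition, ≥ 99% of member tunnels
assigned to their true channel, and pooled detection frequencies within
0.05 of the stationary probabilities. The problem size for that test and
for the acceptance script — 2 conditions × 3 replicates × 2000 frames on a
1 Å grid — keeps a full pipeline run in the minutes range while leaving the
per-estimate sampling error (≈ 0.01–0.02 after pooling 6000 correlated
frames) well inside the tolerance.

What the toy does *not* emulate: real protein geometry (curved, branching
tunnels; moving walls beyond the gate ring), water molecules and their
exchange, force-field physics, and correlated gating between channels.
Passing the recovery tests therefore demonstrates that the *computations*
are correct on data with known truth — not that any particular biological
system behaves like the toy.

## Comparison and reporting

`metric_table()` computes per-replicate detection frequency, mean BR, max
BR and mean length per supercluster; `compare_conditions()` aggregates
replicates (mean, SD with $n-1$; SD absent for a single replicate) and runs
a Welch unequal-variance t test per supercluster × metric. Welch is the
default for 3–4 replicates with no variance-homogeneity assumption; the
statistic is computed in closed form with an explicit guard for the
zero-variance degenerate case (equal means give $t=0, p=1$; unequal means
give the limiting $p=0$ with pooled df rather than a division blow-up), and
is verified against `stats::t.test` to $10^{-8}$. Cells where either
condition has fewer than two values are marked *untestable* — mirroring the
exclamation-mark convention for tunnels found in a single replicate — and
are never silently dropped. No multiple-testing correction is applied by
default, matching raw per-metric reporting; Holm adjustment is available.
The type-I error of the whole path is checked on 200 null synthetic studies
(identical gating in both conditions) and falls inside the binomial 95%
interval of α = 0.05.

## A small worked run

```{r study, eval = FALSE}
study <- run_gating_study(seed = 1, n_frames = 500,
                          replicates_per_condition = 3)
study$counts                    # superclusters per condition
study$frequency                 # detection frequency per replicate
tidy(study$comparison)          # per-metric Welch tests
autoplot(study$comparison)
autoplot(study$discovery)
```

Scaled down to a few hundred frames this runs in well under a minute; the
statistics simply carry wider replicate SDs than the 2000-frame runs used
by `scripts/acceptance.R`.

## Numerical choices and limitations

- **Determinism.** Field values are order-independent minima; Dijkstra ties
  break lexicographically; cluster and supercluster ids have explicit
  tie-break orders (occurrence, then first frame / id). Identical inputs
  give identical outputs, and all stochastic stages are seeded.
- **Grid anchoring.** Voxel centres sit at integer multiples of the grid
  spacing, so results do not depend on the bounding box realisation.
- **Degenerate inputs.** Empty snapshots, absent ATOM records, unknown
  elements, zero-length spines, spines with fewer than two spheres,
  all-filtered merges, and empty series all raise informative errors or
  warnings rather than propagating nonsense.
- **Known limitations.** The detector is grid-based, not Voronoi-based: BR
  accuracy is bounded by the grid spacing, and costs are evaluated at voxel
  centres. The redundancy rule can merge genuinely distinct tunnels whose
  mouths lie within `duplicate_threshold` of each other. The Ward cutoff
  is calibrated on synthetic geometry and should be re-examined for
  structures whose tunnel spacing approaches the within-trajectory
  threshold. Dwell statistics are empirical; no survival model is fitted
  and no kinetic rates are estimated from the dwell histograms.
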