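#' Run the full synthetic gating study pipeline
#'
#' Chains the whole analysis on a synthetic two-condition study: generate
#' gated toy ensembles, detect tunnels in every frame, cluster tunnels
#' within each trajectory, drop rare clusters, merge clusters across
#' replicates and conditions into superclusters, assemble bottleneck
#' series, and compute dynamics statistics and the two-condition
#' comparison.
#'
#' @param seed Master seed for the study generator.
#' @param n_frames Frames per replicate.
#' @param replicates_per_condition Replicates per condition.
#' @param spec,models Toy structure and gating models; see
#'   [default_study_spec()].
#' @param frame_spacing Frame interval, ns.
#' @param detection [detection_params()]; the default uses a 1 A grid,
#'   adequate for the toy channels whose open/closed radii differ by far
#'   more than the grid error.
#' @param clustering [cluster_params()].
#' @param detection_threshold,open_threshold Statistic thresholds, A.
#' @param alpha Significance level for the comparison.
#' @param chunk_size Optional detection batch size (see [detect_tunnels()]).
#' @param config Optional named list (e.g. from [read_config()]) overriding
#'   any scalar argument by name.
#' @param verbose Log per-stage parameters and progress.
#' @return A `td_study` list: `ground_truth`, `profiles`, `clusters`,
#'   `superclusters`, `series`, `metrics`, `comparison`, `frequency`,
#'   `geometry`, `runs`, `dwell`, `discovery`, `counts`.
#' @export
run_gating_study <- function(seed = 1, n_frames = 2000,
                             replicates_per_condition = 3,
                             spec = default_study_spec(),
                             models = default_study_models(),
                             frame_spacing = 0.02,
                             detection = detection_params(grid_spacing = 1.0),
                             clustering = cluster_params(),
                             detection_threshold = 0.7, open_threshold = 1.4,
                             alpha = 0.05, chunk_size = NULL, config = NULL,
                             verbose = TRUE) {
  if (!is.null(config)) {
    for (key in intersect(names(config),
                          c("seed", "n_frames", "replicates_per_condition",
                            "frame_spacing", "detection_threshold",
                            "open_threshold", "alpha", "chunk_size"))) {
      assign(key, config[[key]])
    }
    for (key in intersect(names(config), names(detection)))
      detection[[key]] <- config[[key]]
    for (key in intersect(names(config), names(clustering)))
      clustering[[key]] <- config[[key]]
  }
  say <- function(...) if (verbose) inform(sprintf(...))

  say("[generate] seed=%d, %d frames x %d replicates/condition, dt=%g ns",
      seed, n_frames, replicates_per_condition, frame_spacing)
  study <- generate_study_ensemble(
    spec = spec, models = models,
    replicates_per_condition = replicates_per_condition,
    n_frames = n_frames, frame_spacing = frame_spacing, seed = seed
  )

  say("[detect] probe=%g, shell=%g/%g, grid=%g A",
      detection$probe_radius, detection$shell_radius, detection$shell_depth,
      detection$grid_spacing)
  profiles <- bind_rows(lapply(study$ensembles, function(e) {
    p <- detect_tunnels(e, start = c(0, 0, 0), params = detection,
                        chunk_size = chunk_size)
    say("[detect] %s: %d tunnels", e$replicate_id,
        nrow(distinct(p, .data$frame_index, .data$tunnel_id)))
    p
  }))

  say("[cluster] within=%g A (%s), min occurrence > %g",
      clustering$within_threshold, clustering$within_linkage,
      clustering$min_occurrence_fraction)
  clusters <- cluster_within_trajectory(profiles, n_frames, clustering) %>%
    filter_rare(n_frames, clustering)

  say("[merge] cutoff=%g A (%s), min radius %g A, min length %g A",
      clustering$merge_cutoff, clustering$merge_linkage,
      clustering$min_tunnel_radius, clustering$min_tunnel_length)
  superclusters <- merge_superclusters(clusters, profiles, clustering)

  series <- bottleneck_series(superclusters, n_frames, frame_spacing)
  metrics <- metric_table(series, detection_threshold)
  comparison <- compare_conditions(metrics, alpha = alpha)
  runs <- open_state_runs(series, open_threshold, frame_spacing)
  dwell <- dwell_histogram(runs,
                           default_dwell_bins(frame_spacing),
                           replicates = distinct(series, .data$supercluster_id,
                                                 .data$condition,
                                                 .data$replicate_id))
  out <- list(
    ground_truth = study$ground_truth,
    profiles = profiles, clusters = clusters,
    superclusters = superclusters, series = series, metrics = metrics,
    comparison = comparison,
    frequency = detection_frequency(series, detection_threshold),
    geometry = br_summary(series),
    runs = runs, dwell = dwell,
    discovery = discovery_curve(superclusters, frame_spacing,
                                t_end = (n_frames - 1) * frame_spacing),
    counts = count_distinct_superclusters(superclusters),
    params = list(seed = seed, n_frames = n_frames,
                  replicates_per_condition = replicates_per_condition,
                  frame_spacing = frame_spacing, detection = detection,
                  clustering = clustering,
                  detection_threshold = detection_threshold,
                  open_threshold = open_threshold, alpha = alpha)
  )
  class(out) <- "td_study"
  out
}

#' @export
print.td_study <- function(x, ...) {
  cat(sprintf("<gating study> %d frames x %d replicates/condition\n",
              x$params$n_frames, x$params$replicates_per_condition))
  print(x$counts)
  print(x$comparison)
  invisible(x)
}
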