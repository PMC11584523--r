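#' Tunnel clustering parameters
#'
#' @param within_threshold Dendrogram cut height for within-trajectory
#'   average-linkage clustering, A (default 4.5).
#' @param min_occurrence_fraction Rare-cluster filter: clusters observed in
#'   strictly more than this fraction of frames are retained (default 0.05).
#' @param merge_cutoff Dendrogram cut height for the across-ensemble Ward
#'   merge, A (default 1). Ward heights are not plain inter-tunnel
#'   distances, so absolute cutoffs are calibrated on synthetic data.
#' @param min_tunnel_radius Tunnels with a smaller bottleneck radius are
#'   excluded from the merge, A (default 0.7).
#' @param min_tunnel_length Tunnels shorter than this are excluded from the
#'   merge, A (default 5).
#' @param spine_samples Number of arc-length-equidistant points used to
#'   resample spines for the distance metric (default 20).
#' @param within_linkage,merge_linkage `stats::hclust` methods (defaults
#'   `"average"` and `"ward.D2"`).
#' @return A `td_cluster_params` list.
#' @export
cluster_params <- function(within_threshold = 4.5,
                           min_occurrence_fraction = 0.05,
                           merge_cutoff = 1, min_tunnel_radius = 0.7,
                           min_tunnel_length = 5, spine_samples = 20,
                           within_linkage = "average",
                           merge_linkage = "ward.D2") {
  check_number_(within_threshold, "within_threshold", 0, strict = TRUE)
  check_number_(merge_cutoff, "merge_cutoff", 0, strict = TRUE)
  check_number_(min_tunnel_radius, "min_tunnel_radius", 0, strict = TRUE)
  check_number_(min_tunnel_length, "min_tunnel_length", 0, strict = TRUE)
  if (min_occurrence_fraction < 0 || min_occurrence_fraction > 1)
    abort("min_occurrence_fraction must be in [0, 1]")
  if (spine_samples < 2) abort("spine_samples must be >= 2")
  structure(
    list(within_threshold = within_threshold,
         min_occurrence_fraction = min_occurrence_fraction,
         merge_cutoff = merge_cutoff, min_tunnel_radius = min_tunnel_radius,
         min_tunnel_length = min_tunnel_length,
         spine_samples = as.integer(spine_samples),
         within_linkage = within_linkage, merge_linkage = merge_linkage),
    class = "td_cluster_params"
  )
}

#' Resample a tunnel spine to equidistant arc-length points
#'
#' @param spine Numeric matrix (spheres x 3) of ordered spine centres, or a
#'   profile tibble with `x`, `y`, `z` ordered by `sphere_index`.
#' @param n Number of sample points.
#' @return An `n x 3` matrix.
#' @export
resample_spine <- function(spine, n = 20) {
  if (is.data.frame(spine)) {
    if ("sphere_index" %in% names(spine)) spine <- arrange(spine, .data$sphere_index)
    spine <- cbind(spine$x, spine$y, spine$z)
  }
  if (nrow(spine) < 2) abort("a spine needs at least 2 spheres")
  seg <- sqrt(rowSums((spine[-1, , drop = FALSE] -
                         spine[-nrow(spine), , drop = FALSE])^2))
  keep <- c(TRUE, seg > 0)
  spine <- spine[keep, , drop = FALSE]
  if (nrow(spine) < 2) abort("degenerate zero-length spine")
  arc <- c(0, cumsum(sqrt(rowSums((spine[-1, , drop = FALSE] -
                                     spine[-nrow(spine), , drop = FALSE])^2))))
  at <- seq(0, arc[length(arc)], length.out = n)
  cbind(approx(arc, spine[, 1], at)$y,
        approx(arc, spine[, 2], at)$y,
        approx(arc, spine[, 3], at)$y)
}

#' Geometric distance between two tunnels
#'
#' Both spines are resampled to `spine_samples` points equidistant in arc
#' length; the distance is the mean of the point-wise Euclidean distances
#' under this arc-length correspondence. Symmetric, zero for identical
#' spines.
#'
#' @param a,b Spines (matrices or profile tibbles, see [resample_spine()]).
#' @param spine_samples Resampling resolution.
#' @return Distance in A.
#' @export
tunnel_distance <- function(a, b, spine_samples = 20) {
  pa <- resample_spine(a, spine_samples)
  pb <- resample_spine(b, spine_samples)
  mean(sqrt(rowSums((pa - pb)^2)))
}

# Resample every tunnel in a profile table; returns the key tibble (one row
# per tunnel, canonical order) and an [n_tunnels, samples, 3] array.
resample_all_ <- function(profiles, n_samples) {
  keys <- intersect(c("condition", "replicate_id", "frame_index", "tunnel_id"),
                    names(profiles))
  profiles <- arrange(profiles,
                      dplyr::across(dplyr::all_of(c(keys, "sphere_index"))))
  id <- do.call(paste, c(profiles[keys], sep = "\r"))
  starts <- which(!duplicated(id))
  ends <- c(starts[-1] - 1L, length(id))
  n_t <- length(starts)
  arr <- array(NA_real_, c(n_t, n_samples, 3))
  xyz <- cbind(profiles$x, profiles$y, profiles$z)
  for (i in seq_len(n_t)) {
    arr[i, , ] <- resample_spine(xyz[starts[i]:ends[i], , drop = FALSE], n_samples)
  }
  list(keys = profiles[starts, keys, drop = FALSE], points = arr)
}

# mean point-wise Euclidean distance matrix over a resampled spine array
spine_dist_ <- function(points) {
  n_samples <- dim(points)[2]
  acc <- NULL
  for (s in seq_len(n_samples)) {
    d <- dist(points[, s, , drop = TRUE])
    acc <- if (is.null(acc)) d else acc + d
  }
  acc / n_samples
}

#' Cluster per-frame tunnels within a trajectory
#'
#' Agglomerative clustering (average linkage by default) of all tunnels of
#' one replicate on the [tunnel_distance()] metric, with the dendrogram cut
#' at `within_threshold`. Within each cluster, at most one tunnel per frame
#' is kept (the cheapest). Cluster ids are assigned by descending occurrence
#' (ties broken by first frame of appearance). If the table contains several
#' replicates they are clustered independently.
#'
#' @param profiles Profile tibble (see [detect_tunnels()]).
#' @param n_frames Total number of frames in the trajectory (needed because
#'   frames without tunnels do not appear in `profiles`).
#' @param params [cluster_params()].
#' @return Tibble with one row per retained tunnel: identifier columns,
#'   `cluster_id`, `occurrence_fraction`, `bottleneck_radius`, `length`,
#'   `cost`.
#' @export
cluster_within_trajectory <- function(profiles, n_frames,
                                      params = cluster_params()) {
  if (nrow(profiles) == 0) abort("no tunnels to cluster")
  if (n_frames < 1) abort("n_frames must be >= 1")
  rep_col <- if ("replicate_id" %in% names(profiles)) profiles$replicate_id
             else rep("rep1", nrow(profiles))
  parts <- split(seq_len(nrow(profiles)), rep_col)
  bind_rows(lapply(parts, function(idx)
    cluster_one_trajectory_(profiles[idx, , drop = FALSE], n_frames, params)))
}

cluster_one_trajectory_ <- function(profiles, n_frames, params) {
  geo <- profile_geometry(profiles)
  rs <- resample_all_(profiles, params$spine_samples)
  stopifnot(nrow(rs$keys) == nrow(geo))
  n_t <- nrow(geo)
  membership <- if (n_t == 1) {
    1L
  } else {
    hc <- hclust(spine_dist_(rs$points), method = params$within_linkage)
    cutree(hc, h = params$within_threshold)
  }
  geo <- arrange(geo, dplyr::across(dplyr::all_of(
    intersect(c("condition", "replicate_id", "frame_index", "tunnel_id"),
              names(geo)))))
  geo$raw_cluster <- membership
  if (!"cost" %in% names(geo) || all(is.na(geo$cost))) geo$cost <- geo$length
  kept <- geo %>%
    arrange(.data$raw_cluster, .data$frame_index, .data$cost,
            .data$tunnel_id) %>%
    distinct(.data$raw_cluster, .data$frame_index, .keep_all = TRUE)
  ranking <- kept %>%
    group_by(.data$raw_cluster) %>%
    summarise(n_frames_seen = n_distinct(.data$frame_index),
              first_frame = min(.data$frame_index), .groups = "drop") %>%
    arrange(dplyr::desc(.data$n_frames_seen), .data$first_frame,
            .data$raw_cluster) %>%
    mutate(cluster_id = row_number(),
           occurrence_fraction = .data$n_frames_seen / n_frames)
  kept %>%
    left_join(select(ranking, "raw_cluster", "cluster_id",
                     "occurrence_fraction"), by = "raw_cluster") %>%
    select(-"raw_cluster") %>%
    arrange(.data$cluster_id, .data$frame_index)
}

#' Drop rarely observed tunnel clusters
#'
#' Retains only clusters observed in strictly more than
#' `min_occurrence_fraction` of the frames (a cluster seen in exactly that
#' fraction is dropped).
#'
#' @param clusters Assignment tibble from [cluster_within_trajectory()].
#' @param n_frames Total frames per trajectory.
#' @param params [cluster_params()].
#' @return Filtered assignment tibble.
#' @export
filter_rare <- function(clusters, n_frames, params = cluster_params()) {
  if (nrow(clusters) == 0) return(clusters)
  if (n_frames < 1) abort("n_frames must be >= 1")
  keys <- intersect(c("condition", "replicate_id", "cluster_id"),
                    names(clusters))
  occ <- clusters %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    summarise(occ = n_distinct(.data$frame_index) / n_frames,
              .groups = "drop") %>%
    filter(.data$occ > params$min_occurrence_fraction)
  semi_join(clusters, occ, by = keys)
}

#' Merge clusters across replicates and conditions into superclusters
#'
#' Tunnels below `min_tunnel_radius` or shorter than `min_tunnel_length` are
#' excluded; each remaining (replicate, cluster) is represented by the
#' point-wise mean of its members' resampled spines; representatives are
#' merged by Ward-linkage clustering on [tunnel_distance()], cut at
#' `merge_cutoff`. Supercluster ids are assigned by descending total
#' occurrence. Within a supercluster, a (replicate, frame) contributes at
#' most one tunnel (the cheapest).
#'
#' @param clusters Assignment tibble rows from all ensembles (bind the
#'   per-replicate outputs of [cluster_within_trajectory()] /
#'   [filter_rare()]).
#' @param profiles The corresponding profile tibble (spine geometry).
#' @param params [cluster_params()].
#' @return Membership tibble: `supercluster_id`, `condition`,
#'   `replicate_id`, `cluster_id`, `frame_index`, `tunnel_id`,
#'   `bottleneck_radius`, `length`, `cost`.
#' @export
merge_superclusters <- function(clusters, profiles, params = cluster_params()) {
  members <- filter(clusters,
                    .data$bottleneck_radius >= params$min_tunnel_radius,
                    .data$length >= params$min_tunnel_length)
  if (nrow(members) == 0) {
    warn("all tunnels removed by the radius/length filters; no superclusters")
    return(tibble(supercluster_id = integer(0), condition = character(0),
                  replicate_id = character(0), cluster_id = integer(0),
                  frame_index = integer(0), tunnel_id = integer(0),
                  bottleneck_radius = numeric(0), length = numeric(0),
                  cost = numeric(0)))
  }
  tun_keys <- intersect(c("condition", "replicate_id", "frame_index",
                          "tunnel_id"), names(members))
  grp_keys <- intersect(c("condition", "replicate_id", "cluster_id"),
                        names(members))
  spines <- semi_join(profiles, members, by = tun_keys)
  rs <- resample_all_(spines, params$spine_samples)
  tun_tab <- rs$keys %>%
    left_join(select(members, dplyr::all_of(c(tun_keys, "cluster_id"))),
              by = tun_keys)
  grp_id <- do.call(paste, c(tun_tab[grp_keys], sep = "\r"))
  grp_levels <- unique(grp_id)
  n_g <- length(grp_levels)
  reps <- array(NA_real_, c(n_g, params$spine_samples, 3))
  for (g in seq_len(n_g)) {
    sel <- which(grp_id == grp_levels[g])
    reps[g, , ] <- apply(rs$points[sel, , , drop = FALSE], c(2, 3), mean)
  }
  membership <- if (n_g == 1) {
    1L
  } else {
    hc <- hclust(spine_dist_(reps), method = params$merge_linkage)
    cutree(hc, h = params$merge_cutoff)
  }
  grp_tab <- tun_tab[!duplicated(grp_id), grp_keys, drop = FALSE]
  grp_tab$raw_sc <- membership
  out <- members %>%
    left_join(grp_tab, by = grp_keys)
  ranking <- out %>%
    group_by(.data$raw_sc) %>%
    summarise(total = n(), .groups = "drop") %>%
    arrange(dplyr::desc(.data$total), .data$raw_sc) %>%
    mutate(supercluster_id = row_number())
  frame_keys <- intersect(c("condition", "replicate_id", "frame_index"),
                          names(out))
  out %>%
    left_join(select(ranking, "raw_sc", "supercluster_id"), by = "raw_sc") %>%
    select(-"raw_sc") %>%
    arrange(.data$supercluster_id,
            dplyr::across(dplyr::all_of(frame_keys)),
            .data$cost, .data$tunnel_id) %>%
    distinct(.data$supercluster_id,
             dplyr::across(dplyr::all_of(frame_keys)),
             .keep_all = TRUE) %>%
    select(dplyr::all_of(c("supercluster_id", grp_keys,
                           "frame_index", "tunnel_id",
                           "bottleneck_radius", "length", "cost"))) %>%
    arrange(.data$supercluster_id,
            dplyr::across(dplyr::all_of(frame_keys)))
}

#' Per-supercluster bottleneck-radius time series
#'
#' Expands a supercluster membership table to the full frame grid: one row
#' per supercluster x replicate x frame, with `bottleneck` (and `length`)
#' `NA` where the supercluster was not detected in that frame.
#'
#' @param superclusters Membership tibble from [merge_superclusters()].
#' @param n_frames Frames per trajectory.
#' @param frame_spacing Frame interval, ns.
#' @param replicates Optional tibble of `condition`, `replicate_id` defining
#'   the replicate set (defaults to the replicates present in the table;
#'   pass explicitly if some replicate detected no tunnels at all).
#' @return Series tibble: `supercluster_id`, `condition`, `replicate_id`,
#'   `frame_index`, `time` (ns), `bottleneck` (A), `length` (A).
#' @export
bottleneck_series <- function(superclusters, n_frames, frame_spacing = 0.02,
                              replicates = NULL) {
  if (n_frames < 1) abort("n_frames must be >= 1")
  replicates <- replicates %||%
    distinct(superclusters, .data$condition, .data$replicate_id)
  grid <- tidyr::crossing(
    supercluster_id = sort(unique(superclusters$supercluster_id)),
    replicates,
    frame_index = seq_len(n_frames) - 1L
  )
  grid %>%
    left_join(
      select(superclusters, "supercluster_id", "condition", "replicate_id",
             "frame_index", bottleneck = "bottleneck_radius", "length"),
      by = c("supercluster_id", "condition", "replicate_id", "frame_index")
    ) %>%
    mutate(time = .data$frame_index * frame_spacing,
           .after = "frame_index")
}
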