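#' Tunnel-detection parameters
#'
#' Geometric parameters of the probe-constrained grid search. `probe_radius`
#' is the minimal free radius a voxel must have to be traversable;
#' `shell_radius` defines where bulk solvent begins (voxels at least that far
#' from every atom surface, flood-filled from the box boundary) and
#' `shell_depth` how much arc length is trimmed back from the bulk end of
#' each tunnel, together suppressing shallow surface dimples. Path cost per
#' step is the step length times the target voxel's free radius raised to
#' `-cost_exponent`, so wide corridors are preferred. Candidate exits closer
#' than `duplicate_threshold` to an already kept tunnel (or whose path passes
#' that close to a kept exit) are suppressed as redundant.
#'
#' @param probe_radius Probe radius, A (default 0.7).
#' @param shell_radius Bulk shell radius, A (default 3).
#' @param shell_depth Trim-back depth, A (default 4).
#' @param grid_spacing Voxel edge length, A (default 0.5; accuracy/runtime
#'   trade-off).
#' @param cost_exponent Exponent of the inverse-radius cost (default 2).
#' @param duplicate_threshold Within-snapshot redundancy radius, A
#'   (default 4.5).
#' @return A `td_detection_params` list.
#' @export
detection_params <- function(probe_radius = 0.7, shell_radius = 3,
                             shell_depth = 4, grid_spacing = 0.5,
                             cost_exponent = 2, duplicate_threshold = 4.5) {
  check_number_(probe_radius, "probe_radius", 0, strict = TRUE)
  check_number_(shell_radius, "shell_radius", 0, strict = TRUE)
  check_number_(shell_depth, "shell_depth", 0)
  check_number_(grid_spacing, "grid_spacing", 0, strict = TRUE)
  check_number_(cost_exponent, "cost_exponent", 0, strict = TRUE)
  check_number_(duplicate_threshold, "duplicate_threshold", 0)
  if (shell_radius <= probe_radius) abort("shell_radius must exceed probe_radius")
  structure(
    list(probe_radius = probe_radius, shell_radius = shell_radius,
         shell_depth = shell_depth, grid_spacing = grid_spacing,
         cost_exponent = cost_exponent, duplicate_threshold = duplicate_threshold),
    class = "td_detection_params"
  )
}

coords_matrix_ <- function(snapshot) {
  if (nrow(snapshot) == 0) abort("snapshot contains no atoms")
  cbind(snapshot$x, snapshot$y, snapshot$z)
}

# grid geometry covering the atoms plus a bulk margin; the origin is snapped
# to integer multiples of the spacing so voxel centres are lattice-aligned
grid_geometry_ <- function(coords, vdw, params) {
  margin <- max(vdw) + params$shell_radius + 2 * params$grid_spacing
  h <- params$grid_spacing
  lo <- h * floor((apply(coords, 2, min) - margin) / h)
  hi <- h * ceiling((apply(coords, 2, max) + margin) / h)
  dims <- as.integer(round((hi - lo) / h)) + 1L
  list(origin = lo, dims = dims, spacing = h)
}

#' Compute the start point from residue selections
#'
#' Mass-weighted centre of mass of the atoms belonging to the listed
#' residues (the conventional way to anchor a tunnel search at an active
#' site, e.g. the centre of mass of three catalytic residues).
#'
#' @param snapshot A `td_snapshot`.
#' @param residues Either a data frame with columns `residue_name` and
#'   `residue_id`, or a character vector like `c("TRP:109", "HIS:272")`.
#' @param heavy_only Exclude hydrogens from the selection (default TRUE).
#' @return Numeric length-3 start point (A).
#' @export
compute_start_point <- function(snapshot, residues, heavy_only = TRUE) {
  if (is.character(residues)) {
    parts <- strsplit(residues, ":", fixed = TRUE)
    residues <- tibble(
      residue_name = toupper(vapply(parts, `[`, "", 1)),
      residue_id = as.integer(vapply(parts, `[`, "", 2))
    )
  }
  sel <- rep(FALSE, nrow(snapshot))
  for (i in seq_len(nrow(residues))) {
    hit <- snapshot$residue_name == residues$residue_name[i] &
      snapshot$residue_id == residues$residue_id[i]
    if (!any(hit))
      abort(sprintf("residue %s %d not found in snapshot",
                    residues$residue_name[i], residues$residue_id[i]))
    sel <- sel | hit
  }
  atoms <- snapshot[sel, , drop = FALSE]
  if (heavy_only && !is.null(atoms$element)) {
    heavy <- atoms$element != "H"
    if (any(heavy)) atoms <- atoms[heavy, , drop = FALSE]
  }
  w <- atoms$mass / sum(atoms$mass)
  c(x = sum(w * atoms$x), y = sum(w * atoms$y), z = sum(w * atoms$z))
}

#' Free-radius scalar field on a voxel grid
#'
#' The free radius at a voxel centre `v` is `min over atoms a of
#' (||v - a|| - vdw_radius(a))`: the radius of the largest sphere centred at
#' `v` that touches no atom. Negative inside atoms. The grid covers the
#' atom bounding box plus a bulk margin at `params$grid_spacing`.
#'
#' @param snapshot A `td_snapshot` (or any atom tibble with `x`, `y`, `z`,
#'   `vdw_radius`).
#' @param params [detection_params()].
#' @return A `td_field`: list with `values` (3D array, A), `origin` (A),
#'   `spacing` (A) and `dims`.
#' @export
free_radius_field <- function(snapshot, params = detection_params()) {
  coords <- coords_matrix_(snapshot)
  geom <- grid_geometry_(coords, snapshot$vdw_radius, params)
  vals <- cpp_free_radius_field(coords, snapshot$vdw_radius,
                                geom$origin, geom$dims, geom$spacing)
  structure(
    list(values = vals, origin = geom$origin, spacing = geom$spacing,
         dims = geom$dims, params = params),
    class = "td_field"
  )
}

#' @export
print.td_field <- function(x, ...) {
  cat(sprintf("<free-radius field> %d x %d x %d voxels at %g A\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing))
  invisible(x)
}

#' Classify voxels as bulk solvent or interior
#'
#' Bulk is the set of voxels with free radius at least `shell_radius`,
#' flood-filled (26-connected) from the grid boundary; wide internal voids
#' that are not connected to the boundary remain interior.
#'
#' @param field A [free_radius_field()].
#' @param shell_radius Bulk threshold, A; defaults to the field's params.
#' @return Logical 3D array, `TRUE` for bulk voxels.
#' @export
classify_bulk <- function(field, shell_radius = NULL) {
  if (!inherits(field, "td_field")) abort("`field` must be a td_field")
  shell_radius <- shell_radius %||% field$params$shell_radius
  cpp_flood_bulk(field$values, field$dims, shell_radius)
}

empty_profile_tibble_ <- function() {
  tibble(tunnel_id = integer(0), sphere_index = integer(0),
         x = numeric(0), y = numeric(0), z = numeric(0),
         radius = numeric(0), cost = numeric(0))
}

#' Find tunnels in one snapshot
#'
#' Runs the probe-constrained grid search: Dijkstra over the 26-connected
#' voxel graph restricted to interior voxels with free radius at least
#' `probe_radius`, edge weight `step length x free_radius(target)^(-cost
#' exponent)`, from the (snapped) start voxel. Reached interior voxels
#' adjacent to bulk are candidate exits; processed in ascending path cost, a
#' candidate is dropped if its exit or its path comes within
#' `duplicate_threshold` of an already kept exit. Kept paths are trimmed by
#' `shell_depth` of arc length from the bulk end and returned as sphere
#' spines. A start point whose voxel lies below the probe radius is snapped
#' to the nearest traversable voxel within 3 A (with a warning); a start in
#' bulk is an error.
#'
#' @param snapshot A `td_snapshot`.
#' @param start Numeric length-3 start point (A), e.g. from
#'   [compute_start_point()].
#' @param params [detection_params()].
#' @return Tibble with one row per spine sphere: `tunnel_id` (1 = cheapest
#'   path), `sphere_index` (0-based from the start), `x`, `y`, `z`, `radius`
#'   (A) and the tunnel's path `cost`. Zero rows when no tunnel reaches
#'   bulk.
#' @export
find_tunnels <- function(snapshot, start, params = detection_params()) {
  coords <- coords_matrix_(snapshot)
  geom <- grid_geometry_(coords, snapshot$vdw_radius, params)
  res <- cpp_detect_frame(coords, snapshot$vdw_radius, geom$origin, geom$dims,
                          geom$spacing, as.numeric(start),
                          params$probe_radius, params$shell_radius,
                          params$shell_depth, params$cost_exponent,
                          params$duplicate_threshold, snap_radius = 3.0)
  if (isTRUE(res$snapped))
    warn("start point below probe radius; snapped to the nearest traversable voxel")
  profiles_from_cpp_(res)
}

profiles_from_cpp_ <- function(res) {
  if (length(res$tunnels) == 0) return(empty_profile_tibble_())
  bind_rows(lapply(seq_along(res$tunnels), function(i) {
    sp <- res$tunnels[[i]]
    tibble(tunnel_id = i, sphere_index = seq_len(nrow(sp)) - 1L,
           x = sp[, 1], y = sp[, 2], z = sp[, 3], radius = sp[, 4],
           cost = res$cost[i])
  }))
}

#' Bottleneck radius and length of tunnel profiles
#'
#' The bottleneck radius is the minimum sphere radius along a spine; the
#' length is the polyline length of the sphere centres. Operates on any
#' profile tibble and summarises each tunnel (grouping by the identifier
#' columns present among `condition`, `replicate_id`, `frame_index`,
#' `tunnel_id`).
#'
#' @param profiles Profile tibble (from [find_tunnels()],
#'   [detect_tunnels()] or [read_profile_table()]).
#' @return Tibble with one row per tunnel: identifier columns,
#'   `bottleneck_radius` (A), `length` (A), exit coordinates, and `cost` if
#'   present.
#' @export
profile_geometry <- function(profiles) {
  keys <- intersect(c("condition", "replicate_id", "frame_index", "tunnel_id"),
                    names(profiles))
  if (nrow(profiles) == 0) {
    out <- profiles[, keys, drop = FALSE]
    out$bottleneck_radius <- numeric(0)
    out$length <- numeric(0)
    return(as_tibble(out))
  }
  has_cost <- "cost" %in% names(profiles)
  profiles %>%
    arrange(dplyr::across(dplyr::all_of(c(keys, "sphere_index")))) %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    summarise(
      n_spheres = n(),
      bottleneck_radius = min(.data$radius),
      length = sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2 + diff(.data$z)^2)),
      exit_x = .data$x[n()], exit_y = .data$y[n()], exit_z = .data$z[n()],
      cost = if (has_cost) .data$cost[1] else NA_real_,
      .groups = "drop"
    ) %>%
    (function(d) {
      if (any(d$n_spheres < 2))
        abort("a tunnel spine must contain at least 2 spheres")
      select(d, -"n_spheres")
    })
}

#' Detect tunnels across an ensemble
#'
#' Maps [find_tunnels()] over every frame of an ensemble and returns the
#' combined profile table. For [gated_ensemble()]s the frames are streamed
#' from the compact representation (gate coordinates are updated in place),
#' which keeps memory flat over long trajectories. `chunk_size` splits the
#' frames into batches processed one after the other — a compute-management
#' device only; results are identical to unchunked processing.
#'
#' @param x A `td_ensemble` or `td_gated_ensemble`.
#' @param start Start point (length-3 numeric). Defaults to the cavity
#'   centre (origin) for toy structures.
#' @param params [detection_params()].
#' @param chunk_size Frames per processing batch (default: all frames).
#' @param ... Unused.
#' @return Profile tibble with columns `condition`, `replicate_id`,
#'   `frame_index`, `tunnel_id`, `sphere_index`, `x`, `y`, `z`, `radius`,
#'   `cost`.
#' @export
detect_tunnels <- function(x, start = c(0, 0, 0), params = detection_params(),
                           chunk_size = NULL, ...) {
  UseMethod("detect_tunnels")
}

detect_frames_ <- function(run_frame, n, chunk_size, replicate_id, condition) {
  chunk_size <- chunk_size %||% n
  out <- vector("list", n)
  warned <- FALSE
  for (chunk_start in seq(1, n, by = chunk_size)) {
    for (f in seq(chunk_start, min(chunk_start + chunk_size - 1, n))) {
      res <- run_frame(f)
      if (isTRUE(res$snapped) && !warned) {
        warn("start point below probe radius in at least one frame; snapped")
        warned <- TRUE
      }
      if (length(res$tunnels) > 0) {
        prof <- profiles_from_cpp_(res)
        prof$frame_index <- f - 1L
        out[[f]] <- prof
      }
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- empty_profile_tibble_()
    res$frame_index <- integer(0)
  }
  res$replicate_id <- rep(replicate_id, nrow(res))
  res$condition <- rep(condition, nrow(res))
  select(res, "condition", "replicate_id", "frame_index", "tunnel_id",
         "sphere_index", "x", "y", "z", "radius", "cost")
}

#' @rdname detect_tunnels
#' @export
detect_tunnels.td_snapshot <- function(x, start = c(0, 0, 0),
                                       params = detection_params(),
                                       chunk_size = NULL, ...) {
  prof <- find_tunnels(x, start, params)
  prof$frame_index <- rep(frame_index(x) %||% 0L, nrow(prof))
  prof$replicate_id <- rep("rep1", nrow(prof))
  prof$condition <- rep("default", nrow(prof))
  select(prof, "condition", "replicate_id", "frame_index", "tunnel_id",
         "sphere_index", "x", "y", "z", "radius", "cost")
}

#' @rdname detect_tunnels
#' @export
detect_tunnels.td_ensemble <- function(x, start = c(0, 0, 0),
                                       params = detection_params(),
                                       chunk_size = NULL, ...) {
  a1 <- x$atoms[[1]]
  all_coords <- lapply(x$atoms, function(a) cbind(a$x, a$y, a$z))
  span <- apply(do.call(rbind, all_coords), 2, range)
  geom <- grid_geometry_(span, a1$vdw_radius, params)
  run_frame <- function(f) {
    cpp_detect_frame(all_coords[[f]], a1$vdw_radius, geom$origin, geom$dims,
                     geom$spacing, as.numeric(start), params$probe_radius,
                     params$shell_radius, params$shell_depth,
                     params$cost_exponent, params$duplicate_threshold,
                     snap_radius = 3.0)
  }
  detect_frames_(run_frame, nrow(x), chunk_size, replicate_id(x),
                 condition_label(x))
}

#' @rdname detect_tunnels
#' @export
detect_tunnels.td_gated_ensemble <- function(x, start = c(0, 0, 0),
                                             params = detection_params(),
                                             chunk_size = NULL, ...) {
  toy <- attr(x$structure, "toy")
  base <- cbind(x$structure$x, x$structure$y, x$structure$z)
  # the grid must not depend on per-frame gate positions: use the full
  # structure's bounds (gates only ever move inward from the built state)
  geom <- grid_geometry_(base, x$structure$vdw_radius, params)
  gate_rows <- unlist(lapply(toy$gates, function(g) g$rows))
  wall_rows <- setdiff(seq_len(nrow(base)), gate_rows)
  # only the gate rings move between frames: compute the wall field once and
  # fold in the gate atoms' exact contribution per frame
  static_field <- cpp_free_radius_field(
    base[wall_rows, , drop = FALSE], x$structure$vdw_radius[wall_rows],
    geom$origin, geom$dims, geom$spacing
  )
  a_r <- toy$spec$pseudo_atom_radius
  run_frame <- function(f) {
    gate_coords <- do.call(rbind, lapply(seq_along(toy$gates), function(ci) {
      gate_positions_(toy$gates[[ci]], max(0, x$series[f, ci]), a_r)
    }))
    cpp_detect_frame_cached(
      static_field, gate_coords, rep(a_r, nrow(gate_coords)),
      geom$origin, geom$dims, geom$spacing, as.numeric(start),
      params$probe_radius, params$shell_radius, params$shell_depth,
      params$cost_exponent, params$duplicate_threshold, snap_radius = 3.0
    )
  }
  detect_frames_(run_frame, nrow(x$series), chunk_size, x$replicate_id,
                 x$condition)
}
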