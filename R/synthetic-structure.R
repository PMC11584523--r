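#' Specification for a toy shell structure with engineered channels
#'
#' Describes a hollow pseudo-atom shell (a cartoon of a buried active-site
#' cavity): lattice-packed pseudo-atoms fill the spherical shell between
#' `cavity_radius` and `cavity_radius + shell_thickness`, centred at the
#' origin. Each channel is a straight radial perforation along `axis`; a ring
#' of gate pseudo-atoms at mid-shell constricts it to `free_radius`, and the
#' ring can later be displaced radially to emulate gating
#' ([realize_trajectory()]). The lattice spacing must not exceed the
#' pseudo-atom radius so the wall is probe-tight.
#'
#' @param shell_outer_radius Outer bound of the structure, A.
#' @param shell_thickness Wall thickness, A.
#' @param cavity_radius Inner cavity radius, A.
#' @param lattice_spacing Pseudo-atom lattice constant, A.
#' @param pseudo_atom_radius Van der Waals radius of the pseudo-atoms, A.
#' @param channels List of channels, each `list(axis = unit 3-vector,
#'   free_radius = A)`; `channel()` is a convenience constructor.
#' @return A `td_toy_spec` list.
#' @export
#' @examples
#' toy_structure_spec(channels = list(channel(c(0, 0, 1), 1.5)))
toy_structure_spec <- function(shell_outer_radius = 18, shell_thickness = 5,
                               cavity_radius = 6, lattice_spacing = 1.2,
                               pseudo_atom_radius = 1.7, channels = list()) {
  check_number_(shell_outer_radius, "shell_outer_radius", 0, strict = TRUE)
  check_number_(shell_thickness, "shell_thickness", 0, strict = TRUE)
  check_number_(cavity_radius, "cavity_radius", 0, strict = TRUE)
  check_number_(lattice_spacing, "lattice_spacing", 0, strict = TRUE)
  check_number_(pseudo_atom_radius, "pseudo_atom_radius", 0, strict = TRUE)
  if (cavity_radius + shell_thickness > shell_outer_radius)
    abort("cavity_radius + shell_thickness must not exceed shell_outer_radius")
  if (lattice_spacing > pseudo_atom_radius)
    abort("lattice_spacing must be <= pseudo_atom_radius (probe-tight wall)")
  channels <- lapply(channels, function(ch) {
    ax <- as.numeric(ch$axis)
    if (length(ax) != 3 || !all(is.finite(ax)) || sum(ax^2) == 0)
      abort("channel axis must be a non-zero 3-vector")
    list(axis = ax / sqrt(sum(ax^2)), free_radius = as.numeric(ch$free_radius))
  })
  for (ch in channels) {
    if (ch$free_radius < 0) abort("channel free_radius must be >= 0")
  }
  structure(
    list(shell_outer_radius = shell_outer_radius,
         shell_thickness = shell_thickness,
         cavity_radius = cavity_radius,
         lattice_spacing = lattice_spacing,
         pseudo_atom_radius = pseudo_atom_radius,
         channels = channels),
    class = "td_toy_spec"
  )
}

#' @rdname toy_structure_spec
#' @param axis Channel direction (3-vector, normalised internally).
#' @param free_radius Bottleneck free radius of the built channel, A; this is
#'   also the geometric maximum radius the gate can open to.
#' @export
channel <- function(axis, free_radius) list(axis = axis, free_radius = free_radius)

# orthonormal frame perpendicular to unit vector u
perp_frame_ <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Build a toy shell structure snapshot
#'
#' Places pseudo-atoms on a cubic lattice filling the spherical wall, carves
#' a cylindrical perforation for each channel, and lines each perforation
#' with a mid-shell gate ring whose central opening equals the channel's
#' `free_radius`. The resulting snapshot carries the gate geometry as
#' metadata so [realize_trajectory()] can animate the rings.
#'
#' @param spec A [toy_structure_spec()].
#' @return A `td_snapshot` with a `toy` attribute (spec plus per-channel gate
#'   bookkeeping).
#' @export
build_toy_structure <- function(spec) {
  if (!inherits(spec, "td_toy_spec")) abort("`spec` must be a td_toy_spec")
  s <- spec$lattice_spacing
  a_r <- spec$pseudo_atom_radius
  r_in <- spec$cavity_radius
  r_out <- spec$cavity_radius + spec$shell_thickness

  # pairwise channel overlap check at the cavity mouth, where rays are closest
  n_ch <- length(spec$channels)
  if (n_ch >= 2) {
    for (i in seq_len(n_ch - 1)) {
      for (j in seq(i + 1, n_ch)) {
        ui <- spec$channels[[i]]$axis
        uj <- spec$channels[[j]]$axis
        sep <- r_in * sqrt(sum((ui - uj)^2))
        need <- spec$channels[[i]]$free_radius + spec$channels[[j]]$free_radius +
          2 * a_r
        if (sep < need)
          abort(sprintf("channels %d and %d overlap: separation %.2f A < %.2f A",
                        i, j, sep, need))
      }
    }
  }

  k <- ceiling(r_out / s)
  ax <- s * seq(-k, k)
  grid <- expand.grid(x = ax, y = ax, z = ax)
  r <- sqrt(grid$x^2 + grid$y^2 + grid$z^2)
  keep <- r >= r_in & r <= r_out
  pts <- as.matrix(grid[keep, , drop = FALSE])

  for (ch in spec$channels) {
    u <- ch$axis
    t_ax <- pts %*% u
    rho2 <- rowSums(pts^2) - t_ax^2
    carve <- t_ax > 0 & rho2 < (ch$free_radius + a_r)^2
    pts <- pts[!carve, , drop = FALSE]
  }

  gate_meta <- list()
  gate_pts <- NULL
  z_gate <- r_in + spec$shell_thickness / 2
  for (ci in seq_along(spec$channels)) {
    ch <- spec$channels[[ci]]
    fr <- perp_frame_(ch$axis)
    d <- ch$free_radius + a_r
    n_ring <- max(8L, ceiling(2 * pi * d / min(s, 1.0)))
    theta <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
    ring <- z_gate * matrix(ch$axis, n_ring, 3, byrow = TRUE) +
      d * (cos(theta) %o% fr$e1 + sin(theta) %o% fr$e2)
    gate_meta[[ci]] <- list(
      axis = ch$axis, e1 = fr$e1, e2 = fr$e2, z_gate = z_gate,
      theta = theta, max_radius = ch$free_radius,
      rows = nrow(pts) + NROW(gate_pts) + seq_len(n_ring)
    )
    gate_pts <- rbind(gate_pts, ring)
  }

  all_pts <- rbind(pts, gate_pts)
  n_wall <- nrow(pts)
  n_gate <- NROW(gate_pts)
  atoms <- tibble(
    serial = seq_len(n_wall + n_gate),
    name = "C",
    residue_name = c(rep("SHL", n_wall),
                     rep("GAT", n_gate)),
    residue_id = c(rep(1L, n_wall),
                   if (n_gate > 0) unlist(lapply(seq_along(gate_meta), function(i)
                     rep(i + 1L, length(gate_meta[[i]]$theta)))) else integer(0)),
    x = all_pts[, 1], y = all_pts[, 2], z = all_pts[, 3],
    vdw_radius = a_r,
    mass = 12.011,
    element = "C"
  )
  snap <- snapshot(atoms)
  attr(snap, "toy") <- list(spec = spec, gates = gate_meta)
  snap
}

# gate ring centres for one channel at opening radius r
gate_positions_ <- function(gate, r, pseudo_atom_radius) {
  d <- r + pseudo_atom_radius
  gate$z_gate * matrix(gate$axis, length(gate$theta), 3, byrow = TRUE) +
    d * (cos(gate$theta) %o% gate$e1 + sin(gate$theta) %o% gate$e2)
}

# apply per-channel opening radii to a toy structure's coordinate matrix
apply_gate_radii_ <- function(coords, toy, radii, clamp = TRUE) {
  for (ci in seq_along(toy$gates)) {
    g <- toy$gates[[ci]]
    r <- radii[ci]
    if (clamp) r <- max(0, r)
    if (r > g$max_radius + 1e-9)
      abort(sprintf(
        "requested gate radius %.3f A exceeds geometric maximum %.3f A of channel %d",
        r, g$max_radius, ci))
    coords[g$rows, ] <- gate_positions_(g, r, toy$spec$pseudo_atom_radius)
  }
  coords
}

#' Realize a gated trajectory from radius series
#'
#' Per frame, the gate ring atoms lining each channel are displaced radially
#' so the channel's minimal free radius equals that frame's series value
#' (clamped at 0); all other atoms stay fixed. Values above the channel's
#' geometric maximum (its built `free_radius`) raise an error.
#'
#' @param toy_structure Snapshot from [build_toy_structure()].
#' @param series Numeric matrix (frames x channels), or a vector / list of
#'   per-channel vectors of equal length, of target free radii in A.
#' @param replicate_id,condition,frame_spacing Ensemble metadata.
#' @return A `td_ensemble` of materialised snapshots.
#' @export
realize_trajectory <- function(toy_structure, series, replicate_id = "rep1",
                               condition = "default", frame_spacing = 0.02) {
  toy <- attr(toy_structure, "toy")
  if (is.null(toy)) abort("`toy_structure` must come from build_toy_structure()")
  series <- as_series_matrix_(series, length(toy$gates))
  coords <- cbind(toy_structure$x, toy_structure$y, toy_structure$z)
  snaps <- vector("list", nrow(series))
  for (f in seq_len(nrow(series))) {
    cf <- apply_gate_radii_(coords, toy, series[f, ])
    a <- toy_structure
    a$x <- cf[, 1]; a$y <- cf[, 2]; a$z <- cf[, 3]
    snaps[[f]] <- a
  }
  ensemble(snaps, replicate_id = replicate_id, condition = condition,
           frame_spacing = frame_spacing)
}

as_series_matrix_ <- function(series, n_channels) {
  if (is.list(series) && !is.data.frame(series)) {
    len <- unique(lengths(series))
    if (length(len) != 1) abort("all channel series must have equal length")
    series <- do.call(cbind, series)
  }
  if (is.vector(series)) series <- matrix(series, ncol = 1)
  series <- as.matrix(series)
  if (ncol(series) != n_channels)
    abort(sprintf("need one radius series per channel (%d), got %d",
                  n_channels, ncol(series)))
  if (nrow(series) < 1) abort("series must contain at least one frame")
  series
}

#' Compact gated ensemble
#'
#' Stores a toy structure once together with per-frame gate radii instead of
#' materialising every snapshot; [detect_tunnels()] streams frames from it,
#' and [as_ensemble()] materialises it when explicit snapshots are needed.
#'
#' @param toy_structure Snapshot from [build_toy_structure()].
#' @param series Frames x channels matrix of gate radii, A.
#' @param replicate_id,condition,frame_spacing Ensemble metadata.
#' @param ground_truth Optional tibble of generator ground truth.
#' @return A `td_gated_ensemble`.
#' @export
gated_ensemble <- function(toy_structure, series, replicate_id = "rep1",
                           condition = "default", frame_spacing = 0.02,
                           ground_truth = NULL) {
  toy <- attr(toy_structure, "toy")
  if (is.null(toy)) abort("`toy_structure` must come from build_toy_structure()")
  series <- as_series_matrix_(series, length(toy$gates))
  for (ci in seq_along(toy$gates)) {
    mx <- toy$gates[[ci]]$max_radius
    if (any(series[, ci] > mx + 1e-9))
      abort(sprintf("series for channel %d exceeds geometric maximum %.3f A", ci, mx))
  }
  structure(
    list(structure = toy_structure, series = series,
         replicate_id = replicate_id, condition = condition,
         frame_spacing = frame_spacing, ground_truth = ground_truth),
    class = "td_gated_ensemble"
  )
}

#' @export
print.td_gated_ensemble <- function(x, ...) {
  cat(sprintf(
    "<gated ensemble> %s / %s: %d frames x %d channel(s), dt = %g ns\n",
    x$condition, x$replicate_id, nrow(x$series), ncol(x$series), x$frame_spacing))
  invisible(x)
}

#' @rdname gated_ensemble
#' @param x A `td_gated_ensemble`.
#' @param ... Unused.
#' @export
as_ensemble <- function(x, ...) UseMethod("as_ensemble")

#' @export
as_ensemble.td_gated_ensemble <- function(x, ...) {
  realize_trajectory(x$structure, x$series, replicate_id = x$replicate_id,
                     condition = x$condition, frame_spacing = x$frame_spacing)
}

#' @export
as_ensemble.td_ensemble <- function(x, ...) x

#' @export
get_snapshot.td_gated_ensemble <- function(x, i) {
  toy <- attr(x$structure, "toy")
  coords <- cbind(x$structure$x, x$structure$y, x$structure$z)
  cf <- apply_gate_radii_(coords, toy, x$series[i, ])
  a <- x$structure
  a$x <- cf[, 1]; a$y <- cf[, 2]; a$z <- cf[, 3]
  new_snapshot_(as_tibble(a), i - 1L, (i - 1L) * x$frame_spacing)
}
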