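# Shared fixtures, built in code at test time.

# minimal atom tibble around given coordinates
make_atoms <- function(xyz, vdw = 1.7, mass = 12.011, name = "C",
                       residue_name = "TOY", residue_id = 1L) {
  xyz <- matrix(xyz, ncol = 3)
  tibble::tibble(
    serial = seq_len(nrow(xyz)),
    name = name, residue_name = residue_name,
    residue_id = as.integer(residue_id),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    vdw_radius = vdw, mass = mass, element = "C"
  )
}

make_snapshot <- function(xyz, ...) snapshot(make_atoms(xyz, ...))

# write a small PDB file from an atom tibble (fixed-width, for read tests)
write_test_pdb <- function(atoms, path, model_xyz = NULL) {
  fmt <- function(a) {
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            a$serial, a$name, a$residue_name, "A", a$residue_id,
            a$x, a$y, a$z, a$element)
  }
  if (is.null(model_xyz)) {
    writeLines(c(fmt(atoms), "END"), path)
  } else {
    blocks <- unlist(lapply(seq_along(model_xyz), function(m) {
      a <- atoms
      a$x <- model_xyz[[m]][, 1]; a$y <- model_xyz[[m]][, 2]
      a$z <- model_xyz[[m]][, 3]
      c(sprintf("MODEL     %4d", m), fmt(a), "ENDMDL")
    }))
    writeLines(c(blocks, "END"), path)
  }
  path
}

# brute-force free radius at arbitrary points (independent oracle)
brute_free_radius <- function(points, coords, vdw) {
  points <- matrix(points, ncol = 3)
  apply(points, 1, function(p) {
    min(sqrt(colSums((t(coords) - p)^2)) - vdw)
  })
}

# minimal straight-spine profile tibble for clustering tests
make_profile <- function(frame_index, tunnel_id, offset = c(0, 0, 0),
                         n_spheres = 6, radius = 1.2, cost = 1,
                         direction = c(0, 0, 1), replicate_id = "rep1",
                         condition = "A", step = 2) {
  direction <- direction / sqrt(sum(direction^2))
  centers <- t(vapply(seq_len(n_spheres) - 1,
                      function(i) offset + i * step * direction,
                      numeric(3)))
  tibble::tibble(
    condition = condition, replicate_id = replicate_id,
    frame_index = as.integer(frame_index), tunnel_id = as.integer(tunnel_id),
    sphere_index = seq_len(n_spheres) - 1L,
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    radius = radius, cost = cost
  )
}

# bottleneck series tibble from a plain vector (NA = absent)
make_series <- function(values, supercluster_id = 1L, condition = "A",
                        replicate_id = "rep1", frame_spacing = 0.02) {
  tibble::tibble(
    supercluster_id = supercluster_id, condition = condition,
    replicate_id = replicate_id,
    frame_index = seq_along(values) - 1L,
    time = (seq_along(values) - 1L) * frame_spacing,
    bottleneck = values,
    length = ifelse(is.na(values), NA_real_, 10)
  )
}

toy_one_channel <- function(free_radius = 1.5) {
  toy_structure_spec(channels = list(channel(c(0, 0, 1), free_radius)))
}
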