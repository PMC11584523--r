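test_that("start point is the mass-weighted centre of the selected residues", {
  # single atom: identity
  s1 <- make_snapshot(c(1, 2, 3), residue_name = "TRP", residue_id = 109L)
  expect_equal(unname(compute_start_point(s1, "TRP:109")), c(1, 2, 3))
  # two equal masses: midpoint
  s2 <- make_snapshot(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(unname(compute_start_point(
    s2, tibble::tibble(residue_name = "TOY", residue_id = 1L),
    heavy_only = FALSE))[1], 1)
  # masses 12 at x=0 and 1 at x=13: weighted mean 13/13 = 1
  a <- make_atoms(rbind(c(0, 0, 0), c(13, 0, 0)))
  a$mass <- c(12, 1)
  expect_equal(unname(compute_start_point(snapshot(a), "TOY:1"))[1], 1)
  expect_error(compute_start_point(s1, "HIS:272"), "HIS 272 not found")
})

test_that("free-radius field equals the brute-force minimum over atoms", {
  set.seed(123)
  for (rep in 1:5) {
    n_atoms <- 20
    coords <- matrix(runif(3 * n_atoms, -8, 8), ncol = 3)
    vdw <- runif(n_atoms, 1.2, 2.0)
    a <- make_atoms(coords)
    a$vdw_radius <- vdw
    f <- free_radius_field(snapshot(a), detection_params(grid_spacing = 1.0))
    centers <- expand.grid(
      x = f$origin[1] + f$spacing * (seq_len(f$dims[1]) - 1),
      y = f$origin[2] + f$spacing * (seq_len(f$dims[2]) - 1),
      z = f$origin[3] + f$spacing * (seq_len(f$dims[3]) - 1)
    )
    # expand.grid varies x fastest, matching the field's linear layout
    truth <- brute_free_radius(as.matrix(centers), coords, vdw)
    expect_lt(max(abs(as.vector(f$values) - truth)), 1e-9)
  }
})

test_that("field values reproduce single-atom closed forms", {
  s <- make_snapshot(c(0, 0, 0)) # one carbon, vdw 1.7
  f <- free_radius_field(s, detection_params(grid_spacing = 1.0))
  at <- function(p) {
    idx <- round((p - f$origin) / f$spacing) + 1
    f$values[idx[1], idx[2], idx[3]]
  }
  expect_equal(at(c(3, 0, 0)), 3 - 1.7, tolerance = 1e-12)
  expect_equal(at(c(0, 0, 0)), -1.7, tolerance = 1e-12)
})

test_that("bulk classification flood-fills from the boundary only", {
  s <- build_toy_structure(toy_structure_spec())
  f <- free_radius_field(s, detection_params(grid_spacing = 1.0))
  bulk <- classify_bulk(f)
  at <- function(p) {
    idx <- round((p - f$origin) / f$spacing) + 1
    list(bulk = bulk[idx[1], idx[2], idx[3]],
         free = f$values[idx[1], idx[2], idx[3]])
  }
  # far corner: bulk
  expect_true(at(f$origin)$bulk)
  # the sealed cavity centre is wide (free radius > 3 A) but disconnected
  # from the boundary: interior, not bulk
  centre <- at(c(0, 0, 0))
  expect_gt(centre$free, 3)
  expect_false(centre$bulk)
  # wall voxels are not bulk
  expect_false(at(c(0, 0, 8.4))$bulk)
})

test_that("detection respects the probe constraint", {
  # channel narrower than the probe: nothing found
  s <- build_toy_structure(toy_one_channel(0.5))
  prof <- find_tunnels(s, c(0, 0, 0), detection_params(grid_spacing = 0.5))
  expect_equal(nrow(prof), 0)
  # same geometry, smaller probe: found
  prof2 <- find_tunnels(s, c(0, 0, 0),
                        detection_params(probe_radius = 0.3,
                                         shell_radius = 3,
                                         grid_spacing = 0.5))
  expect_gt(nrow(prof2), 0)
})

test_that("start-point contracts: bulk start errors, buried-under-probe snaps", {
  s <- build_toy_structure(toy_one_channel(1.5))
  expect_error(find_tunnels(s, c(0, 0, 30), detection_params(grid_spacing = 1)),
               "not buried")
  # start inside an atom of the inner wall: snapped with a warning
  wall_atom <- c(s$x[1], s$y[1], s$z[1])
  expect_warning(
    find_tunnels(s, wall_atom, detection_params(grid_spacing = 1.0)),
    "snapped")
})

test_that("returned tunnels satisfy the geometric invariants", {
  s <- build_toy_structure(default_study_spec())
  params <- detection_params(grid_spacing = 1.0)
  prof <- find_tunnels(s, c(0, 0, 0), params)
  geo <- profile_geometry(prof)
  start <- c(0, 0, 0)
  for (i in seq_len(nrow(geo))) {
    expect_gte(geo$bottleneck_radius[i], params$probe_radius)
    straight <- sqrt(sum((c(geo$exit_x[i], geo$exit_y[i], geo$exit_z[i]) -
                            start)^2))
    expect_gte(geo$length[i] + 1e-9, straight)
  }
  expect_true(all(prof$radius >= params$probe_radius))
  # tunnels are sorted by ascending cost
  expect_equal(geo$cost, sort(geo$cost))
})

test_that("detection is deterministic and atom-order independent", {
  s <- build_toy_structure(toy_one_channel(1.5))
  params <- detection_params(grid_spacing = 0.5)
  p1 <- find_tunnels(s, c(0, 0, 0), params)
  p2 <- find_tunnels(s, c(0, 0, 0), params)
  expect_identical(p1, p2)
  set.seed(9)
  perm <- sample(nrow(s))
  s_perm <- snapshot(s[perm, setdiff(names(s), "element")])
  p3 <- find_tunnels(s_perm, c(0, 0, 0), params)
  expect_equal(as.data.frame(p1), as.data.frame(p3), tolerance = 1e-12)
})

test_that("detected bottleneck converges to truth as the grid refines", {
  s <- build_toy_structure(toy_one_channel(1.5))
  errs <- vapply(c(1.0, 0.5, 0.25), function(h) {
    geo <- profile_geometry(
      find_tunnels(s, c(0, 0, 0), detection_params(grid_spacing = h)))
    abs(geo$bottleneck_radius[1] - 1.5)
  }, 0)
  expect_true(all(errs <= c(1.0, 0.5, 0.25) + 1e-9))
  expect_lte(errs[3], errs[1] + 1e-9)
})

test_that("grid Dijkstra matches an independent shortest-path oracle", {
  skip_if_not_installed("igraph")
  set.seed(77)
  dims <- c(12L, 11L, 10L)
  for (rep in 1:3) {
    field <- array(runif(prod(dims), 0.5, 3), dims)
    allowed <- array(runif(prod(dims)) > 0.2, dims)
    start0 <- 0L # voxel (1,1,1)
    field[1] <- 1; allowed[1] <- TRUE
    res <- tunneldyn:::cpp_grid_dijkstra(field, dims, 0.5, start0,
                                         probe_radius = 0.7,
                                         cost_exponent = 2, allowed = allowed)
    # oracle: igraph over the same 26-connected graph
    ok <- allowed & field >= 0.7
    idx <- which(ok)
    pos <- arrayInd(idx, dims)
    id_of <- array(NA_integer_, dims)
    id_of[idx] <- seq_along(idx)
    offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, ]
    edges <- NULL; weights <- NULL
    for (k in seq_len(nrow(offs))) {
      nb <- sweep(pos, 2, offs[k, ], "+")
      good <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      from <- which(good)
      to_idx <- nb[good, , drop = FALSE]
      to_lin <- to_idx[, 1] + dims[1] * (to_idx[, 2] - 1 +
                                           dims[2] * (to_idx[, 3] - 1))
      to <- id_of[to_lin]
      keep <- !is.na(to)
      step <- 0.5 * sqrt(sum(offs[k, ]^2))
      edges <- rbind(edges, cbind(from[keep], to[keep]))
      weights <- c(weights, step * field[to_lin[keep]]^-2)
    }
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    d_oracle <- igraph::distances(g, v = id_of[1], mode = "out",
                                  weights = weights)[1, ]
    d_mine <- res$dist[idx]
    reach <- is.finite(d_oracle)
    expect_equal(which(is.finite(d_mine)), which(reach))
    expect_lt(max(abs(d_mine[reach] - d_oracle[reach])), 1e-9)
  }
})

test_that("profile geometry computes bottleneck and polyline length", {
  prof <- tibble::tibble(
    tunnel_id = 1L, sphere_index = 0:2,
    x = c(0, 0, 0), y = c(0, 0, 0), z = c(0, 2, 5),
    radius = c(1.2, 0.9, 1.5)
  )
  geo <- profile_geometry(prof)
  expect_equal(geo$bottleneck_radius, 0.9)
  expect_equal(geo$length, 5)
  # right-angle spine: length 7 exceeds the straight-line 5
  prof2 <- tibble::tibble(
    tunnel_id = 1L, sphere_index = 0:2,
    x = c(0, 3, 3), y = c(0, 0, 4), z = c(0, 0, 0), radius = 1
  )
  expect_equal(profile_geometry(prof2)$length, 7)
  # fewer than 2 spheres is an error
  expect_error(profile_geometry(prof[1, ]), "at least 2 spheres")
})

test_that("chunked and unchunked ensemble detection are identical", {
  s <- build_toy_structure(toy_one_channel(2.0))
  radii <- matrix(c(1.6, 0.5, 1.2, 1.9, 0.3, 1.4, 1.0, 1.8, 0.6, 1.1),
                  ncol = 1)
  ge <- gated_ensemble(s, radii)
  params <- detection_params(grid_spacing = 1.0)
  p_all <- detect_tunnels(ge, params = params)
  p_chunk <- detect_tunnels(ge, params = params, chunk_size = 3)
  expect_identical(p_all, p_chunk)
})
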