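test_that("tunnel distance is symmetric, zero on identity, offset on parallels", {
  a <- make_profile(0, 1)
  expect_equal(tunnel_distance(a, a), 0)
  b <- make_profile(0, 2, offset = c(3, 0, 0)) # parallel, offset 3 A
  expect_equal(tunnel_distance(a, b), 3)
  expect_equal(tunnel_distance(a, b), tunnel_distance(b, a))
  expect_error(tunnel_distance(a[1, ], a), "at least 2")
})

test_that("tunnel distance equals an independent resample-and-average oracle", {
  set.seed(31)
  for (rep in 1:20) {
    m1 <- matrix(cumsum(runif(15, -1, 2)), ncol = 3)
    m2 <- matrix(cumsum(runif(12, -1, 2)), ncol = 3)
    k <- 20
    oracle <- local({
      rs <- function(m) {
        seg <- sqrt(rowSums(diff(m)^2))
        arc <- c(0, cumsum(seg))
        at <- seq(0, max(arc), length.out = k)
        sapply(1:3, function(j) approx(arc, m[, j], at)$y)
      }
      p1 <- rs(m1); p2 <- rs(m2)
      mean(sqrt(rowSums((p1 - p2)^2)))
    })
    expect_equal(tunnel_distance(m1, m2, k), oracle, tolerance = 1e-9)
  }
})

test_that("within-trajectory clustering separates well-spaced bundles", {
  # bundle 1 near the z axis, bundle 2 offset by 20 A
  prof <- dplyr::bind_rows(
    make_profile(0, 1), make_profile(1, 1, offset = c(0.4, 0, 0)),
    make_profile(2, 1, offset = c(0, 0.5, 0)),
    make_profile(0, 2, offset = c(20, 0, 0)),
    make_profile(2, 2, offset = c(20.3, 0, 0))
  )
  cl <- cluster_within_trajectory(prof, n_frames = 10)
  expect_equal(dplyr::n_distinct(cl$cluster_id), 2)
  # id 1 is the more frequent bundle
  occ <- dplyr::distinct(cl, cluster_id, occurrence_fraction)
  expect_equal(occ$occurrence_fraction[occ$cluster_id == 1], 0.3)
  # bundle membership matches the construction
  got <- cl$cluster_id[order(cl$frame_index, cl$tunnel_id)]
  expect_equal(got, c(1L, 2L, 1L, 1L, 2L))
})

test_that("clustering matches exhaustive average linkage on few tunnels", {
  set.seed(5)
  offsets <- list(c(0, 0, 0), c(1, 0, 0), c(7, 0, 0), c(8, 0.5, 0),
                  c(30, 0, 0))
  prof <- dplyr::bind_rows(lapply(seq_along(offsets), function(i)
    make_profile(i - 1, 1, offset = offsets[[i]])))
  cl <- cluster_within_trajectory(prof, n_frames = 5,
                                  cluster_params(within_threshold = 4.5))
  # oracle: full distance matrix + stats::hclust directly
  d <- matrix(0, 5, 5)
  for (i in 1:4) for (j in (i + 1):5) {
    d[i, j] <- d[j, i] <- tunnel_distance(
      make_profile(0, 1, offset = offsets[[i]]),
      make_profile(0, 1, offset = offsets[[j]]))
  }
  oracle <- cutree(hclust(as.dist(d), method = "average"), h = 4.5)
  got <- cl$cluster_id[order(cl$frame_index)]
  expect_equal(length(unique(got)), length(unique(oracle)))
  expect_equal(outer(got, got, "=="), outer(oracle, oracle, "=="))
})

test_that("a single tunnel forms one cluster with the right occurrence", {
  cl <- cluster_within_trajectory(make_profile(4, 1), n_frames = 20)
  expect_equal(cl$cluster_id, 1L)
  expect_equal(cl$occurrence_fraction, 1 / 20)
})

test_that("within a cluster and frame only the cheapest tunnel survives", {
  prof <- dplyr::bind_rows(
    make_profile(0, 1, cost = 2),
    make_profile(0, 2, offset = c(0.2, 0, 0), cost = 1)
  )
  cl <- cluster_within_trajectory(prof, n_frames = 4)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$tunnel_id, 2L)
})

test_that("clustering is invariant under permutation of input rows", {
  set.seed(13)
  prof <- dplyr::bind_rows(
    lapply(0:9, function(f) make_profile(f, 1, offset = runif(3, 0, 0.5))),
    lapply(c(1, 3, 7), function(f)
      make_profile(f, 2, offset = c(18, 0, 0) + runif(3, 0, 0.5)))
  )
  cl1 <- cluster_within_trajectory(prof, n_frames = 10)
  cl2 <- cluster_within_trajectory(prof[sample(nrow(prof)), ], n_frames = 10)
  expect_equal(as.data.frame(cl1), as.data.frame(cl2))
})

test_that("the rare-cluster filter is strictly greater than 5%", {
  # one tunnel in 101 of 2000 frames (5.05%): retained;
  # one in exactly 100 of 2000 (5.00%): dropped
  prof <- dplyr::bind_rows(
    lapply(0:100, function(f) make_profile(f, 1)),
    lapply(0:99, function(f) make_profile(f, 2, offset = c(20, 0, 0)))
  )
  cl <- cluster_within_trajectory(prof, n_frames = 2000)
  kept <- filter_rare(cl, n_frames = 2000)
  occ <- dplyr::distinct(kept, cluster_id, occurrence_fraction)
  expect_equal(nrow(occ), 1)
  expect_equal(occ$occurrence_fraction, 101 / 2000)
  expect_equal(filter_rare(cl[0, ], 2000), cl[0, ])
})

test_that("geometrically identical clusters from two replicates merge", {
  p1 <- dplyr::bind_rows(lapply(0:5, function(f)
    make_profile(f, 1, replicate_id = "r1", n_spheres = 5)))
  p2 <- dplyr::bind_rows(lapply(0:5, function(f)
    make_profile(f, 1, replicate_id = "r2", n_spheres = 5)))
  prof <- dplyr::bind_rows(p1, p2)
  cl <- cluster_within_trajectory(prof, n_frames = 6)
  sc <- merge_superclusters(cl, prof)
  expect_equal(dplyr::n_distinct(sc$supercluster_id), 1)
  expect_equal(nrow(sc), nrow(cl)) # tunnel count conserved through the merge
})

test_that("short or narrow tunnels are excluded from the merge", {
  long_ok <- dplyr::bind_rows(lapply(0:3, function(f)
    make_profile(f, 1, n_spheres = 6, step = 2)))        # length 10
  too_short <- dplyr::bind_rows(lapply(0:3, function(f)
    make_profile(f, 2, offset = c(20, 0, 0), n_spheres = 3, step = 1.5,
                 radius = 1.2)))                          # length 3 < 5
  too_narrow <- dplyr::bind_rows(lapply(0:3, function(f)
    make_profile(f, 3, offset = c(-20, 0, 0), n_spheres = 6,
                 radius = 0.65)))                         # BR 0.65 < 0.7
  prof <- dplyr::bind_rows(long_ok, too_short, too_narrow)
  cl <- cluster_within_trajectory(prof, n_frames = 4)
  sc <- merge_superclusters(cl, prof)
  expect_equal(dplyr::n_distinct(sc$supercluster_id), 1)
  expect_true(all(sc$length >= 5 & sc$bottleneck_radius >= 0.7))
  # everything filtered -> warning and empty result
  cl2 <- cluster_within_trajectory(too_short, n_frames = 4)
  expect_warning(sc2 <- merge_superclusters(cl2, too_short), "no superclusters")
  expect_equal(nrow(sc2), 0)
})

test_that("bottleneck series marks undetected frames as absent", {
  prof <- dplyr::bind_rows(make_profile(0, 1, radius = 1.1),
                           make_profile(2, 1, radius = 0.9))
  cl <- cluster_within_trajectory(prof, n_frames = 4)
  sc <- merge_superclusters(cl, prof)
  ser <- bottleneck_series(sc, n_frames = 4, frame_spacing = 0.02)
  expect_equal(nrow(ser), 4)
  expect_equal(ser$bottleneck, c(1.1, NA, 0.9, NA))
  expect_equal(ser$time, c(0, 0.02, 0.04, 0.06))
})
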