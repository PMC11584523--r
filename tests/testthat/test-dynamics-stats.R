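test_that("detection frequency counts present frames strictly above threshold", {
  expect_equal(detection_frequency(make_series(rep(1.0, 100)))$detection_frequency,
               1.0)
  expect_equal(detection_frequency(make_series(c(1, 2, NA, 3)))$detection_frequency,
               0.75)
  # a value exactly at the threshold is not detected (strict >)
  expect_equal(detection_frequency(make_series(c(0.7, 1.0)))$detection_frequency,
               0.5)
  expect_error(detection_frequency(make_series(numeric(0))), "empty")
})

test_that("bottleneck summaries use detected frames only", {
  s <- br_summary(make_series(c(1.0, 2.0)))
  expect_equal(s$mean_br, 1.5)
  expect_equal(s$max_br, 2.0)
  s1 <- br_summary(make_series(1.3))
  expect_equal(s1$mean_br, 1.3)
  expect_equal(s1$max_br, 1.3)
  s2 <- br_summary(make_series(c(1.0, NA, 3.0)))
  expect_equal(s2$mean_br, 2.0)
  # no detected frames: absent, not zero
  s3 <- br_summary(make_series(c(NA_real_, NA_real_)))
  expect_true(is.na(s3$mean_br) && is.na(s3$max_br))
})

test_that("bottleneck histograms normalise over detected frames", {
  h <- br_histogram(make_series(c(0.75, 0.85)),
                    bin_edges = c(0.7, 0.8, 0.9, 1.0, 1.1, 1.2))
  expect_equal(h$frequency[h$bin_lo == 0.7], 0.5)
  expect_equal(h$frequency[h$bin_lo == 0.8], 0.5)
  h2 <- br_histogram(make_series(rep(1.01, 5)))
  expect_equal(sum(h2$frequency), 1)
  expect_equal(h2$frequency[h2$bin_lo == 1.0], 1)
})

test_that("bottleneck histograms equal a brute-force recount and sum to 1", {
  set.seed(8)
  vals <- c(runif(500, 0.7, 3.5), rep(NA, 100))[sample(600)]
  edges <- seq(0.7, 3.0, by = 0.1)
  h <- br_histogram(make_series(vals), edges)
  present <- vals[!is.na(vals)]
  for (i in seq_len(nrow(h))) {
    expected <- sum(present >= h$bin_lo[i] &
                      present < h$bin_hi[i]) / length(present)
    expect_equal(h$frequency[i], expected)
  }
  expect_equal(sum(h$frequency), 1) # overflow bin included
})

test_that("open-state runs follow the run-length and boundary contracts", {
  runs <- open_state_runs(make_series(c(1.5, 1.5, 1.0, 1.6)))
  expect_equal(runs$duration, c(0.04, 0.02))
  expect_equal(runs$censored, c(TRUE, TRUE)) # both touch a series boundary
  # a value exactly at 1.4 A is open (>=)
  runs2 <- open_state_runs(make_series(c(1.0, 1.4, 1.0)))
  expect_equal(runs2$duration, 0.02)
  expect_false(runs2$censored)
  # absent frames close a run
  runs3 <- open_state_runs(make_series(c(1.0, 1.6, NA, 1.6, 1.0)))
  expect_equal(runs3$duration, c(0.02, 0.02))
  # all closed: no runs
  expect_equal(nrow(open_state_runs(make_series(c(1.0, 1.2)))), 0)
})

test_that("run durations account for every open frame under include policy", {
  set.seed(21)
  for (rep in 1:50) {
    vals <- runif(200, 0.7, 2.1)
    vals[runif(200) < 0.3] <- NA
    ser <- make_series(vals)
    runs <- open_state_runs(ser)
    open_frames <- sum(!is.na(vals) & vals >= 1.4)
    expect_equal(sum(runs$duration), 0.02 * open_frames, tolerance = 1e-12)
  }
})

test_that("dwell histograms average per-replicate frequencies", {
  runs <- dplyr::bind_rows(
    tibble::tibble(condition = "A", replicate_id = c("r1", "r1", "r1"),
                   duration = c(0.02, 0.02, 0.04), censored = FALSE),
    tibble::tibble(condition = "A", replicate_id = c("r2", "r2", "r2"),
                   duration = c(0.02, 0.02, 0.04), censored = FALSE)
  )
  dh <- dwell_histogram(runs, bin_edges = c(0.02, 0.03, 0.05))
  expect_equal(dh$sd_frequency, rep(0, nrow(dh))) # identical replicates
  expect_equal(dh$mean_frequency[dh$bin_lo == 0.02], 2 / 3)
  expect_equal(dh$mean_frequency[dh$bin_lo == 0.03], 1 / 3)
  # censored runs are excluded under the default policy
  runs$censored[1] <- TRUE
  dh2 <- dwell_histogram(runs, bin_edges = c(0.02, 0.03, 0.05))
  expect_equal(dh2$mean_frequency[dh2$bin_lo == 0.02],
               mean(c(1 / 2, 2 / 3)))
  # a replicate with zero runs contributes an all-zero histogram
  reps <- tibble::tibble(condition = "A", replicate_id = c("r1", "r2", "r3"))
  expect_message(
    dh3 <- dwell_histogram(runs, bin_edges = c(0.02, 0.03, 0.05),
                           censoring_policy = "include", replicates = reps),
    "all-zero")
  expect_equal(unique(dh3$n_replicates), 3)
})

test_that("dwell histograms match analytic exponential bin masses", {
  m <- gating_model(k_open = 5, k_close = 5, noise_sd = 0, seed = 17)
  sim <- simulate_gating(m, 1.5e5, frame_spacing = 0.02)
  seg <- attr(sim, "segments")
  dwells <- seg$duration[seg$state == "open" & !seg$censored]
  runs <- tibble::tibble(condition = "A", replicate_id = "r1",
                         duration = dwells, censored = FALSE)
  edges <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  dh <- dwell_histogram(runs, bin_edges = edges)
  # closed form: P(edge_i <= T < edge_{i+1}) for T ~ Exp(k_close); dwells
  # below the first edge fall outside all bins, and the histogram normalises
  # by the total dwell count, so bin masses are exactly the exponential ones
  pmass <- diff(c(stats::pexp(edges, m$k_close), 1))
  n <- length(dwells)
  for (i in seq_along(pmass)) {
    se <- sqrt(pmass[i] * (1 - pmass[i]) / n)
    expect_lt(abs(dh$mean_frequency[i] - pmass[i]), 3 * se + 1e-6)
  }
})

test_that("discovery curves reproduce a hand-computed step function", {
  sc <- tibble::tibble(
    condition = "A",
    replicate_id = c("r1", "r1", "r2", "r2", "r2"),
    supercluster_id = c(1L, 2L, 1L, 2L, 3L),
    frame_index = c(5L, 25L, 0L, 10L, 30L),
    tunnel_id = 1L, bottleneck_radius = 1, length = 10, cost = 1,
    cluster_id = 1L
  )
  dc <- discovery_curve(sc, frame_spacing = 0.02)
  # hand-computed: r1 first detections at 0.1, 0.5; r2 at 0, 0.2, 0.6
  expect_equal(dc$saturation$saturation_time, c(0.5, 0.6))
  expect_equal(dc$saturation$n_superclusters, c(2L, 3L))
  cv <- dc$curve
  expect_equal(cv$time, c(0, 0.1, 0.2, 0.5, 0.6))
  # per-replicate counts on the grid: r1 = (0,1,1,2,2), r2 = (1,1,2,2,3)
  expect_equal(cv$mean_count, c(0.5, 1, 1.5, 2, 2.5))
  expect_equal(cv$min_count, c(0, 1, 1, 2, 2))
  expect_equal(cv$max_count, c(1, 1, 2, 2, 3))
  # non-decreasing in t for every envelope
  expect_true(all(diff(cv$mean_count) >= 0))
  expect_true(all(diff(cv$min_count) >= 0))
  expect_true(all(diff(cv$max_count) >= 0))
})

test_that("discovery curves are invariant to replicate order", {
  sc <- tibble::tibble(
    condition = "A",
    replicate_id = c("r2", "r1", "r2", "r1"),
    supercluster_id = c(1L, 1L, 2L, 2L),
    frame_index = c(3L, 7L, 11L, 2L),
    tunnel_id = 1L, bottleneck_radius = 1, length = 10, cost = 1,
    cluster_id = 1L
  )
  d1 <- discovery_curve(sc, 0.02)
  d2 <- discovery_curve(sc[order(sc$replicate_id), ], 0.02)
  expect_equal(d1$curve, d2$curve)
})

test_that("distinct supercluster counts per condition are monotone under union", {
  sc <- tibble::tibble(
    condition = c("A", "A", "A", "B"),
    replicate_id = c("a1", "a1", "a2", "b1"),
    supercluster_id = c(1L, 2L, 5L, 1L)
  )
  counts <- count_distinct_superclusters(sc)
  expect_equal(counts$n_superclusters[counts$condition == "A"], 3L)
  expect_equal(counts$n_superclusters[counts$condition == "B"], 1L)
  union_count <- dplyr::n_distinct(sc$supercluster_id)
  expect_true(all(counts$n_superclusters <= union_count))
  empty <- count_distinct_superclusters(sc[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("gated series statistics recover the generator's kinetics", {
  # noise-free gate with r_open 1.6, r_closed 0.9: a threshold between the
  # two state radii classifies every frame correctly, so detection frequency
  # estimates the stationary open fraction
  m <- gating_model(k_open = 5, k_close = 5, r_open = 1.6, r_closed = 0.9,
                    noise_sd = 0, seed = 23)
  sim <- simulate_gating(m, 2e4, frame_spacing = 0.02)
  ser <- make_series(sim$radius)
  freq <- detection_frequency(ser, detection_threshold = 1.4)$detection_frequency
  rho <- exp(-(m$k_open + m$k_close) * 0.02)
  se <- sqrt(0.25 / 2e4 * (1 + rho) / (1 - rho))
  expect_lt(abs(freq - 0.5), 3 * se)

  # mean observed dwell matches the frame-sampled chain, not the
  # continuous-time 1/k_close: the sampled process is Markov with
  # P(open -> closed in one frame) = pi_closed * (1 - exp(-(ko+kc) dt)),
  # so sampled run durations are geometric with mean dt/p
  runs <- open_state_runs(ser, open_threshold = 1.4)
  runs <- runs[!runs$censored, ]
  p_oc <- 0.5 * (1 - rho)
  expected <- 0.02 / p_oc # 0.2207 ns, above the continuous-time 0.2 ns
  se_run <- sd(runs$duration) / sqrt(nrow(runs))
  expect_lt(abs(mean(runs$duration) - expected), 3 * se_run)
})
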