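#' Two-state Markov gating model
#'
#' Continuous-time two-state (open/closed) gating of a channel bottleneck:
#' holding times are exponential with rates `k_open` (closed to open) and
#' `k_close` (open to closed), the bottleneck free radius is `r_open` or
#' `r_closed` plus Gaussian observation noise truncated at zero. When both
#' rates are positive the stationary open fraction is
#' `k_open / (k_open + k_close)` and the mean open dwell is `1 / k_close`.
#'
#' @param k_open,k_close Transition rates, 1/ns (both >= 0).
#' @param r_open,r_closed Bottleneck free radii of the two states, A
#'   (`r_open > r_closed >= 0`).
#' @param noise_sd Gaussian radius noise SD, A (>= 0). Kept small relative to
#'   the state separation by default so truncation bias is negligible.
#' @param seed Optional integer seed for reproducible simulation.
#' @return A `td_gating_model` list.
#' @export
gating_model <- function(k_open = 10, k_close = 10, r_open = 1.6,
                         r_closed = 0.4, noise_sd = 0.1, seed = NULL) {
  check_number_(k_open, "k_open", 0)
  check_number_(k_close, "k_close", 0)
  check_number_(noise_sd, "noise_sd", 0)
  check_number_(r_closed, "r_closed", 0)
  if (!(r_open > r_closed)) abort("r_open must exceed r_closed")
  structure(
    list(k_open = k_open, k_close = k_close, r_open = r_open,
         r_closed = r_closed, noise_sd = noise_sd, seed = seed),
    class = "td_gating_model"
  )
}

#' Simulate gated bottleneck dynamics
#'
#' Exact continuous-time simulation of the two-state Markov gate: exponential
#' holding times are drawn until the trajectory covers `n_frames` frames,
#' then the state is sampled on the regular frame grid (so sub-frame
#' excursions are aliased exactly as a trajectory saved at fixed intervals
#' would alias them). The observed radius adds truncated Gaussian noise to
#' the state radius. The continuous-time segments are returned alongside the
#' sampled series: dwell-recovery checks need the exact holding times, which
#' frame sampling biases.
#'
#' @param model A [gating_model()].
#' @param n_frames Number of frames (>= 1).
#' @param frame_spacing Frame interval, ns (default 0.02, i.e. 20 ps).
#' @param initial_state Optional `"open"` or `"closed"`; defaults to a draw
#'   from the stationary distribution (required when both rates are zero).
#' @return A tibble with columns `frame_index`, `time` (ns), `state`
#'   (`"open"`/`"closed"`), `true_radius` (noise-free, A) and `radius`
#'   (observed, A), carrying attributes `segments` (tibble `state`,
#'   `t_start`, `t_end`, `duration`, `censored`) and `model`.
#' @export
#' @examples
#' g <- simulate_gating(gating_model(seed = 1), n_frames = 100)
#' head(g)
#' attr(g, "segments")[1:3, ]
simulate_gating <- function(model, n_frames, frame_spacing = 0.02,
                            initial_state = NULL) {
  if (!inherits(model, "td_gating_model")) abort("`model` must be a td_gating_model")
  if (n_frames < 1) abort("n_frames must be >= 1")
  check_number_(frame_spacing, "frame_spacing", 0, strict = TRUE)
  if (model$k_open == 0 && model$k_close == 0 && is.null(initial_state))
    abort("both rates are zero: an initial_state must be given")
  with_seed_(model$seed, {
    t_end_total <- (n_frames - 1) * frame_spacing
    p_open <- if (model$k_open + model$k_close > 0)
      model$k_open / (model$k_open + model$k_close) else NA_real_
    state0 <- initial_state %||% if (runif(1) < p_open) "open" else "closed"
    if (!state0 %in% c("open", "closed"))
      abort('initial_state must be "open" or "closed"')
    rate_of <- function(s) if (s == "open") model$k_close else model$k_open
    # holding rates alternate deterministically from the initial state, so
    # exponential holding times can be drawn in vectorised blocks
    durations <- numeric(0)
    if (rate_of(state0) == 0) {
      durations <- Inf
    } else {
      block <- max(64, ceiling(
        1.5 * t_end_total * max(model$k_open, model$k_close) / 2 + 10))
      repeat {
        k <- length(durations)
        rates <- ifelse((k + seq_len(block)) %% 2 == 1,
                        rate_of(state0),
                        rate_of(if (state0 == "open") "closed" else "open"))
        if (any(rates == 0)) {
          # the opposite state is absorbing: one finite dwell, then forever
          durations <- c(rexp(1, rate_of(state0)), Inf)
          break
        }
        durations <- c(durations, rexp(block, rates))
        if (sum(durations) > t_end_total) break
      }
    }
    ends <- cumsum(durations)
    n_seg <- which(ends > t_end_total)[1]
    durations <- durations[seq_len(n_seg)]
    seg_start <- c(0, head(cumsum(durations), -1))
    seg_state <- rep(c(state0, if (state0 == "open") "closed" else "open"),
                     length.out = n_seg)
    seg_end <- c(seg_start[-1], min(ends[n_seg], t_end_total))
    segments <- tibble(
      state = seg_state, t_start = seg_start, t_end = seg_end,
      duration = seg_end - seg_start,
      censored = seq_along(seg_state) == 1L |
        seq_along(seg_state) == length(seg_state)
    )
    times <- (seq_len(n_frames) - 1) * frame_spacing
    seg_idx <- findInterval(times, seg_start)
    states <- seg_state[seg_idx]
    true_radius <- ifelse(states == "open", model$r_open, model$r_closed)
    radius <- pmax(0, true_radius + rnorm(n_frames, 0, model$noise_sd))
    out <- tibble(
      frame_index = seq_len(n_frames) - 1L, time = times,
      state = states, true_radius = true_radius, radius = radius
    )
    attr(out, "segments") <- segments
    attr(out, "model") <- model
    attr(out, "open_fraction_theory") <- p_open
    out
  })
}

#' Ground-truth summaries of a simulated gating series
#'
#' @param sim Output of [simulate_gating()].
#' @return One-row tibble: theoretical stationary open fraction, empirical
#'   open fraction of the sampled frames, and the empirical mean open dwell
#'   computed from the uncensored continuous-time open segments.
#' @export
gating_ground_truth <- function(sim) {
  seg <- attr(sim, "segments")
  open_seg <- seg[seg$state == "open" & !seg$censored, , drop = FALSE]
  tibble(
    open_fraction_theory = attr(sim, "open_fraction_theory"),
    open_fraction_empirical = mean(sim$state == "open"),
    mean_open_dwell = if (nrow(open_seg) > 0) mean(open_seg$duration) else NA_real_,
    n_open_dwells = nrow(open_seg)
  )
}

#' Generate a synthetic two-condition gating study
#'
#' Emulates the study design of a few independent trajectory replicates per
#' condition: a shared toy structure with gated channels, independent gating
#' simulations per replicate and channel (conditions may carry different
#' rates, emulating e.g. a water-model effect), observation at fixed frame
#' spacing. Replicate seeds are derived deterministically from `seed`.
#'
#' @param spec Toy structure spec; must declare as many channels as `models`.
#' @param models Named list (one element per condition) of lists of
#'   [gating_model()]s, one per channel. Model seeds are overridden by the
#'   derived per-replicate seeds.
#' @param replicates_per_condition Replicates per condition (>= 1; at least 2
#'   are needed downstream for condition comparisons).
#' @param n_frames Frames per replicate.
#' @param frame_spacing Frame interval, ns.
#' @param seed Integer master seed.
#' @return List with `ensembles` (list of [gated_ensemble()]s) and
#'   `ground_truth` (per condition x replicate x channel tibble with
#'   theoretical open fractions and empirical dwell summaries).
#' @export
generate_study_ensemble <- function(spec = default_study_spec(),
                                    models = default_study_models(),
                                    replicates_per_condition = 3,
                                    n_frames = 2000, frame_spacing = 0.02,
                                    seed = 1) {
  if (replicates_per_condition < 1) abort("replicates_per_condition must be >= 1")
  if (is.null(names(models)) || any(!nzchar(names(models))))
    abort("`models` must be a named list, one element per condition")
  structure0 <- build_toy_structure(spec)
  n_channels <- length(spec$channels)
  ensembles <- list()
  truth <- list()
  counter <- 0L
  for (cond in names(models)) {
    cond_models <- models[[cond]]
    if (length(cond_models) != n_channels)
      abort(sprintf("condition %s needs %d gating models (one per channel)",
                    cond, n_channels))
    for (rep_i in seq_len(replicates_per_condition)) {
      rep_id <- sprintf("%s_rep%d", cond, rep_i)
      series <- matrix(0, n_frames, n_channels)
      for (ch_i in seq_len(n_channels)) {
        counter <- counter + 1L
        m <- cond_models[[ch_i]]
        m$seed <- (seed * 1000L + counter) %% .Machine$integer.max
        sim <- simulate_gating(m, n_frames, frame_spacing)
        # observation noise is truncated at the channel's geometric maximum,
        # just as it is truncated at zero: the gate cannot open further
        series[, ch_i] <- pmin(sim$radius, spec$channels[[ch_i]]$free_radius)
        truth[[length(truth) + 1L]] <- mutate(
          gating_ground_truth(sim),
          condition = cond, replicate_id = rep_id, channel = ch_i,
          k_open = m$k_open, k_close = m$k_close,
          .before = 1
        )
      }
      ensembles[[length(ensembles) + 1L]] <- gated_ensemble(
        structure0, series, replicate_id = rep_id, condition = cond,
        frame_spacing = frame_spacing
      )
    }
  }
  list(ensembles = ensembles, ground_truth = bind_rows(truth))
}

#' Default toy study conditions
#'
#' Two antipodal channels with a 2.0 A geometric maximum opening, and two
#' conditions whose gating rates differ for the first channel. Open/closed
#' radii (1.6 / 0.4 A) straddle the 0.7 A detection probe so closed frames
#' are genuinely undetectable, and mean dwells (50-100 ps) match the
#' dominant tunnel-gating timescale at 20 ps sampling.
#'
#' @return `default_study_spec()`: a [toy_structure_spec()];
#'   `default_study_models()`: a named list of per-channel model lists.
#' @export
default_study_spec <- function() {
  toy_structure_spec(channels = list(
    channel(c(0, 0, 1), 2.0),
    channel(c(0, 0, -1), 2.0)
  ))
}

#' @rdname default_study_spec
#' @export
default_study_models <- function() {
  list(
    A = list(gating_model(k_open = 10, k_close = 10),
             gating_model(k_open = 5, k_close = 15)),
    B = list(gating_model(k_open = 10, k_close = 20),
             gating_model(k_open = 5, k_close = 15))
  )
}
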