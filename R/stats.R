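series_keys_ <- function(series) {
  intersect(c("supercluster_id", "condition", "replicate_id"), names(series))
}

#' Tunnel detection frequency
#'
#' Fraction of frames in which the tunnel is present with a bottleneck
#' radius strictly greater than `detection_threshold` (absent frames count
#' as not detected).
#'
#' @param series Bottleneck series tibble (see [bottleneck_series()]); any
#'   tibble with a `bottleneck` column and the usual identifier columns
#'   works.
#' @param detection_threshold Detection threshold, A (default 0.7, the
#'   probe radius).
#' @return Tibble with one row per supercluster x replicate:
#'   `detection_frequency` in `[0, 1]` and `n_frames`.
#' @export
detection_frequency <- function(series, detection_threshold = 0.7) {
  if (nrow(series) == 0) abort("empty series")
  series %>%
    group_by(dplyr::across(dplyr::all_of(series_keys_(series)))) %>%
    summarise(
      detection_frequency = mean(!is.na(.data$bottleneck) &
                                   .data$bottleneck > detection_threshold),
      n_frames = n(), .groups = "drop"
    )
}

#' Bottleneck-radius summaries over detected frames
#'
#' Mean and maximum bottleneck radius, and mean tunnel length, over the
#' frames in which the tunnel was detected. A replicate without any
#' detected frame yields `NA` (absent, not zero).
#'
#' @param series Bottleneck series tibble.
#' @return Tibble per supercluster x replicate: `mean_br`, `max_br`,
#'   `mean_length` (A) and `n_detected`.
#' @export
br_summary <- function(series) {
  if (nrow(series) == 0) abort("empty series")
  has_len <- "length" %in% names(series)
  series %>%
    group_by(dplyr::across(dplyr::all_of(series_keys_(series)))) %>%
    summarise(
      n_detected = sum(!is.na(.data$bottleneck)),
      mean_br = mean(.data$bottleneck, na.rm = TRUE),
      max_br = suppressWarnings(max(.data$bottleneck, na.rm = TRUE)),
      mean_length = if (has_len) mean(.data$length[!is.na(.data$bottleneck)])
                    else NA_real_,
      .groups = "drop"
    ) %>%
    mutate(dplyr::across(c("mean_br", "max_br", "mean_length"),
                         ~ ifelse(.data$n_detected > 0 & is.finite(.x),
                                  .x, NA_real_)))
}

#' Normalized bottleneck-radius histogram
#'
#' Counts of detected-frame bottleneck radii in half-open bins
#' `[edge_i, edge_{i+1})`, normalised by the number of detected frames.
#' Values at or above the last edge are collected in a final open overflow
#' bin so the masses always sum to 1.
#'
#' @param series Bottleneck series tibble.
#' @param bin_edges Strictly increasing bin edges, A (default 0.7 to 3.0 by
#'   0.1).
#' @return Tibble per group and bin: `bin_lo`, `bin_hi` (Inf for the
#'   overflow bin) and `frequency`.
#' @export
br_histogram <- function(series, bin_edges = seq(0.7, 3.0, by = 0.1)) {
  if (any(diff(bin_edges) <= 0)) abort("bin_edges must be strictly increasing")
  edges <- c(bin_edges, Inf)
  series %>%
    filter(!is.na(.data$bottleneck)) %>%
    group_by(dplyr::across(dplyr::all_of(series_keys_(series)))) %>%
    summarise(
      bin = list(seq_len(length(edges) - 1L)),
      counts = list(tabulate(findInterval(.data$bottleneck, edges,
                                          left.open = FALSE),
                             nbins = length(edges) - 1L)),
      n_detected = n(), .groups = "drop"
    ) %>%
    tidyr::unnest(c("bin", "counts")) %>%
    mutate(bin_lo = edges[.data$bin], bin_hi = edges[.data$bin + 1L],
           frequency = .data$counts / .data$n_detected) %>%
    select(-"bin", -"counts")
}

#' Open-state runs (dwell events)
#'
#' Maximal runs of consecutive frames whose bottleneck radius is at least
#' `open_threshold` (a value exactly at the threshold is open; an absent
#' frame is closed, since an undetected tunnel has no bottleneck at all).
#' The duration of a run of `L` frames is `L x frame_spacing`, so a single
#' open frame lasts one frame interval. Runs touching either end of the
#' series are flagged as censored: their true duration is only bounded from
#' below.
#'
#' @param series Bottleneck series tibble.
#' @param open_threshold Open-state threshold, A (default 1.4).
#' @param frame_spacing Frame interval, ns; inferred from the `time` column
#'   when present.
#' @return Tibble of runs: identifier columns, `start_frame`,
#'   `n_open_frames`, `duration` (ns), `censored`.
#' @export
open_state_runs <- function(series, open_threshold = 1.4,
                            frame_spacing = NULL) {
  if (nrow(series) == 0) abort("empty series")
  if (is.null(frame_spacing)) {
    if (!"time" %in% names(series))
      abort("frame_spacing must be given when the series has no time column")
    steps <- sort(unique(series$time))
    frame_spacing <- min(diff(steps))
  }
  keys <- series_keys_(series)
  series %>%
    arrange(dplyr::across(dplyr::all_of(c(keys, "frame_index")))) %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::group_modify(function(d, g) {
      open <- !is.na(d$bottleneck) & d$bottleneck >= open_threshold
      r <- rle(open)
      run_end <- cumsum(r$lengths)
      run_start <- run_end - r$lengths + 1L
      is_open <- which(r$values)
      if (length(is_open) == 0) {
        return(tibble(start_frame = integer(0), n_open_frames = integer(0),
                      duration = numeric(0), censored = logical(0)))
      }
      tibble(
        start_frame = d$frame_index[run_start[is_open]],
        n_open_frames = r$lengths[is_open],
        duration = r$lengths[is_open] * frame_spacing,
        censored = run_start[is_open] == 1L | run_end[is_open] == nrow(d)
      )
    }) %>%
    ungroup()
}

#' Default dwell-time bin ladder
#'
#' Geometric ladder of dwell bin edges from one frame interval up past 8 ns
#' (0.02, 0.04, 0.08, ... ns): dwell durations span orders of magnitude, so
#' log-spaced bins resolve both the dominant sub-0.1 ns events and the rare
#' multi-ns openings.
#'
#' @param frame_spacing Frame interval, ns.
#' @param t_max Upper end of the ladder, ns.
#' @return Numeric vector of bin edges.
#' @export
default_dwell_bins <- function(frame_spacing = 0.02, t_max = 8) {
  frame_spacing * 2^(0:ceiling(log2(t_max / frame_spacing) + 1))
}

#' Across-replicate dwell-duration histogram
#'
#' Per replicate, the normalised histogram of open-state dwell durations
#' over `bin_edges`; then the mean and standard deviation across replicates
#' of each bin mass, per condition. Censored runs are excluded under the
#' default policies `"flag"` and `"drop"` (uncensored dwell statistics) and
#' kept under `"include"`.
#'
#' @param runs Run tibble from [open_state_runs()].
#' @param bin_edges Strictly increasing dwell bin edges, ns (see
#'   [default_dwell_bins()]); durations at or above the last edge fall in a
#'   final open bin.
#' @param censoring_policy `"flag"`, `"drop"` or `"include"`.
#' @param replicates Optional tibble of `condition`, `replicate_id`: a
#'   replicate with zero runs contributes an all-zero histogram (reported
#'   via a message) rather than being dropped.
#' @return Tibble per condition (x supercluster if present) and bin:
#'   `bin_lo`, `bin_hi`, `mean_frequency`, `sd_frequency`, `n_replicates`.
#' @export
dwell_histogram <- function(runs, bin_edges = default_dwell_bins(),
                            censoring_policy = c("flag", "drop", "include"),
                            replicates = NULL) {
  censoring_policy <- match.arg(censoring_policy)
  if (any(diff(bin_edges) <= 0)) abort("bin_edges must be strictly increasing")
  if (censoring_policy != "include") runs <- filter(runs, !.data$censored)
  keys <- intersect(c("supercluster_id", "condition"), names(runs))
  rep_keys <- intersect(c("supercluster_id", "condition", "replicate_id"),
                        names(runs))
  replicates <- replicates %||%
    distinct(runs, dplyr::across(dplyr::all_of(rep_keys)))
  edges <- c(bin_edges, Inf)
  nb <- length(edges) - 1L
  per_rep <- replicates %>%
    left_join(mutate(runs, .run = TRUE), by = rep_keys) %>%
    group_by(dplyr::across(dplyr::all_of(rep_keys))) %>%
    dplyr::group_modify(function(d, g) {
      dur <- d$duration[!is.na(d$.run)]
      if (length(dur) == 0) {
        inform(paste0("replicate without open-state runs: all-zero histogram (",
                      paste(unlist(g), collapse = " / "), ")"))
        freq <- rep(0, nb)
      } else {
        freq <- tabulate(findInterval(dur, edges), nbins = nb) / length(dur)
      }
      tibble(bin = seq_len(nb), bin_lo = edges[-length(edges)],
             bin_hi = edges[-1], frequency = freq)
    }) %>%
    ungroup()
  per_rep %>%
    group_by(dplyr::across(dplyr::all_of(c(keys, "bin", "bin_lo", "bin_hi")))) %>%
    summarise(mean_frequency = mean(.data$frequency),
              sd_frequency = sd(.data$frequency),
              n_replicates = n(), .groups = "drop") %>%
    select(-"bin")
}

#' Cluster discovery curve
#'
#' Per replicate, the cumulative number of distinct superclusters first
#' observed by time `t` (a step function); across replicates, the mean and
#' the min/max envelope on the union grid of first-detection times. The
#' saturation time of a replicate is its last first-detection time — the
#' time after which no new cluster was identified.
#'
#' @param superclusters Membership tibble from [merge_superclusters()].
#' @param frame_spacing Frame interval, ns.
#' @param t_end Optional trajectory end time for padding the curve, ns.
#' @return A `td_discovery` list: `curve` (per condition: `time`,
#'   `mean_count`, `min_count`, `max_count`) and `saturation` (per
#'   replicate: `saturation_time`, `n_superclusters`).
#' @export
discovery_curve <- function(superclusters, frame_spacing = 0.02,
                            t_end = NULL) {
  if (nrow(superclusters) == 0) abort("no superclusters")
  firsts <- superclusters %>%
    group_by(.data$condition, .data$replicate_id, .data$supercluster_id) %>%
    summarise(first_time = min(.data$frame_index) * frame_spacing,
              .groups = "drop")
  saturation <- firsts %>%
    group_by(.data$condition, .data$replicate_id) %>%
    summarise(saturation_time = max(.data$first_time),
              n_superclusters = n(), .groups = "drop")
  curve <- firsts %>%
    group_by(.data$condition) %>%
    dplyr::group_modify(function(d, g) {
      grid <- sort(unique(c(0, d$first_time, t_end)))
      reps <- unique(d$replicate_id)
      counts <- vapply(reps, function(r) {
        ft <- sort(d$first_time[d$replicate_id == r])
        vapply(grid, function(t) sum(ft <= t), 0)
      }, numeric(length(grid)))
      counts <- matrix(counts, nrow = length(grid))
      tibble(time = grid,
             mean_count = rowMeans(counts),
             min_count = apply(counts, 1, min),
             max_count = apply(counts, 1, max))
    }) %>%
    ungroup()
  structure(list(curve = curve, saturation = saturation),
            class = "td_discovery")
}

#' @export
print.td_discovery <- function(x, ...) {
  cat("<discovery curve>\n")
  print(x$saturation)
  invisible(x)
}

#' Count distinct superclusters per condition
#'
#' @param superclusters Membership tibble from [merge_superclusters()].
#' @return Tibble: `condition`, `n_superclusters` (superclusters with at
#'   least one member tunnel from any replicate of that condition).
#' @export
count_distinct_superclusters <- function(superclusters) {
  if (nrow(superclusters) == 0)
    return(tibble(condition = character(0), n_superclusters = integer(0)))
  superclusters %>%
    group_by(.data$condition) %>%
    summarise(n_superclusters = n_distinct(.data$supercluster_id),
              .groups = "drop")
}
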