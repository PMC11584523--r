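#' Replicate-level aggregation
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of a
#' per-replicate metric; the SD is absent (`NA`) for a single replicate.
#'
#' @param values Numeric vector of per-replicate values.
#' @return One-row tibble: `mean`, `sd`, `n`.
#' @export
aggregate_replicates <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("no values to aggregate")
  tibble(mean = mean(values),
         sd = if (length(values) >= 2) sd(values) else NA_real_,
         n = length(values))
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p value — the robust default for comparing 3-4 replicate
#' means per condition. With fewer than two observations on either side the
#' cell is untestable (the field's "exclamation mark" convention) rather
#' than an error. When both samples have zero variance the standard error
#' vanishes: equal means give t = 0, p = 1; different means give the
#' limiting p = 0 (reported with t = +/-Inf and pooled df) instead of a
#' division blow-up.
#'
#' @param a,b Numeric samples.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `untestable`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) {
    return(tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                  untestable = TRUE))
  }
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  dm <- mean(a) - mean(b)
  if (se2 == 0) {
    if (dm == 0) {
      return(tibble(statistic = 0, df = na + nb - 2, p_value = 1,
                    untestable = FALSE))
    }
    return(tibble(statistic = sign(dm) * Inf, df = na + nb - 2, p_value = 0,
                  untestable = FALSE))
  }
  t_stat <- dm / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  tibble(statistic = t_stat, df = df,
         p_value = 2 * pt(-abs(t_stat), df), untestable = FALSE)
}

#' Build a per-replicate metric table
#'
#' Computes the per-supercluster, per-replicate tunnel metrics (detection
#' frequency, mean and maximum bottleneck radius, mean length) from a
#' bottleneck series and reshapes them into the long metric table used by
#' [compare_conditions()]. Metrics undefined for a replicate (no detected
#' frames) are `NA`.
#'
#' @param series Bottleneck series tibble (see [bottleneck_series()]).
#' @param detection_threshold Detection threshold, A.
#' @return Tibble: `condition`, `replicate_id`, `supercluster_id`,
#'   `metric`, `value`.
#' @export
metric_table <- function(series, detection_threshold = 0.7) {
  freq <- detection_frequency(series, detection_threshold)
  geom <- br_summary(series)
  freq %>%
    select(-"n_frames") %>%
    left_join(select(geom, -"n_detected"),
              by = series_keys_(series)) %>%
    tidyr::pivot_longer(c("detection_frequency", "mean_br", "max_br",
                          "mean_length"),
                        names_to = "metric", values_to = "value") %>%
    select(dplyr::any_of(c("condition", "replicate_id", "supercluster_id",
                           "metric", "value")))
}

#' Compare two conditions metric by metric
#'
#' For every supercluster x metric cell: per-condition replicate mean and
#' SD, Welch t test across replicates, and a significance flag at level
#' `alpha`. Cells where either condition contributes fewer than two
#' replicate values (e.g. a tunnel found in one replicate only) are marked
#' untestable, never silently dropped.
#'
#' @param metrics Metric table (see [metric_table()]).
#' @param alpha Significance level (default 0.05).
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()]; `"none"` (default) matches raw per-metric
#'   reporting, `"holm"` is available.
#' @return A `td_comparison` object; see [tidy()] and [glance()] methods.
#' @export
compare_conditions <- function(metrics, alpha = 0.05, p_adjust = "none") {
  conds <- sort(unique(metrics$condition))
  if (length(conds) != 2)
    abort(sprintf("exactly 2 conditions required, got %d", length(conds)))
  cells <- metrics %>%
    group_by(.data$supercluster_id, .data$metric) %>%
    dplyr::group_modify(function(d, g) {
      a <- d$value[d$condition == conds[1] & !is.na(d$value)]
      b <- d$value[d$condition == conds[2] & !is.na(d$value)]
      agg <- function(v) {
        if (length(v) == 0) tibble(mean = NA_real_, sd = NA_real_, n = 0L)
        else aggregate_replicates(v)
      }
      aa <- agg(a); bb <- agg(b)
      tt <- welch_t(a, b)
      tibble(mean_a = aa$mean, sd_a = aa$sd, n_a = aa$n,
             mean_b = bb$mean, sd_b = bb$sd, n_b = bb$n,
             statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
             untestable = tt$untestable)
    }) %>%
    ungroup() %>%
    mutate(p_adjusted = stats::p.adjust(.data$p_value, method = p_adjust),
           significant = !.data$untestable & !is.na(.data$p_adjusted) &
             .data$p_adjusted < alpha)
  structure(
    list(cells = cells, conditions = conds, alpha = alpha,
         p_adjust = p_adjust),
    class = "td_comparison"
  )
}

#' @export
print.td_comparison <- function(x, ...) {
  cat(sprintf("<condition comparison> %s vs %s, alpha = %g%s\n",
              x$conditions[1], x$conditions[2], x$alpha,
              if (x$p_adjust != "none") paste0(" (", x$p_adjust, "-adjusted)")
              else ""))
  cat(sprintf("  %d cells: %d significant, %d untestable\n",
              nrow(x$cells), sum(x$cells$significant),
              sum(x$cells$untestable)))
  invisible(x)
}

#' Tidy a condition comparison
#'
#' @param x A `td_comparison`.
#' @param ... Unused.
#' @return `tidy()`: the per-cell tibble (one row per supercluster x
#'   metric); `glance()`: a one-row summary.
#' @export
tidy.td_comparison <- function(x, ...) x$cells

#' @rdname tidy.td_comparison
#' @export
glance.td_comparison <- function(x, ...) {
  tibble(
    condition_a = x$conditions[1], condition_b = x$conditions[2],
    alpha = x$alpha, n_cells = nrow(x$cells),
    n_significant = sum(x$cells$significant),
    n_untestable = sum(x$cells$untestable)
  )
}

#' Write and read comparison reports
#'
#' `render_report()` writes the comparison as both CSV (flat cell table
#' with an explicit `untestable` marker column and a `note` for untestable
#' cells) and JSON (full object); `read_report()` reconstructs the
#' comparison object from the JSON so the round trip is the identity.
#'
#' @param report A `td_comparison`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return `render_report()`: the paths, invisibly; `read_report()`: a
#'   `td_comparison`.
#' @export
render_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!inherits(report, "td_comparison")) abort("`report` must be a td_comparison")
  if (!is.null(csv_path)) {
    flat <- mutate(report$cells,
                   note = ifelse(.data$untestable,
                                 "untestable: found in fewer than 2 replicates",
                                 ""))
    readr::write_csv(flat, csv_path, progress = FALSE, na = "NA")
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(conditions = report$conditions, alpha = report$alpha,
           p_adjust = report$p_adjust, cells = report$cells),
      json_path, auto_unbox = TRUE, digits = NA, na = "null", null = "null"
    )
  }
  invisible(c(csv = csv_path, json = json_path))
}

#' @rdname render_report
#' @param json_path Path written by `render_report()`.
#' @export
read_report <- function(json_path) {
  obj <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  cells <- as_tibble(obj$cells)
  for (col in c("mean_a", "sd_a", "mean_b", "sd_b", "statistic", "df",
                "p_value", "p_adjusted")) {
    cells[[col]] <- as.numeric(cells[[col]])
  }
  cells$n_a <- as.integer(cells$n_a)
  cells$n_b <- as.integer(cells$n_b)
  cells$supercluster_id <- as.integer(cells$supercluster_id)
  structure(
    list(cells = cells, conditions = obj$conditions, alpha = obj$alpha,
         p_adjust = obj$p_adjust),
    class = "td_comparison"
  )
}
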