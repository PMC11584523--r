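#' Read and write tunnel-profile tables
#'
#' A profile table is the flat interchange format for per-sphere tunnel
#' profiles: comma-separated with one row per spine sphere and columns
#' `replicate_id`, `frame_index`, `tunnel_id`, `sphere_index`, `x`, `y`, `z`,
#' `radius` (coordinates and radii in Angstrom; `sphere_index` runs
#' contiguously from 0 along each tunnel spine). Extra columns (e.g.
#' `condition`, `cost`) round-trip unchanged.
#'
#' @param path File path.
#' @return `read_profile_table()` returns a validated tibble;
#'   `write_profile_table()` returns `path` invisibly.
#' @export
read_profile_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_profile_table(tab)
}

#' @rdname read_profile_table
#' @param table Profile tibble, e.g. from [detect_tunnels()].
#' @export
write_profile_table <- function(table, path) {
  validate_profile_table(table)
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_profile_table
#' @export
validate_profile_table <- function(table) {
  req <- c("replicate_id", "frame_index", "tunnel_id", "sphere_index",
           "x", "y", "z", "radius")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols) > 0)
    abort(paste0("profile table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  tab <- as_tibble(table)
  tab$frame_index <- as.integer(tab$frame_index)
  tab$tunnel_id <- as.integer(tab$tunnel_id)
  tab$sphere_index <- as.integer(tab$sphere_index)
  if (any(tab$radius <= 0, na.rm = TRUE)) abort("sphere radius must be > 0")
  bad <- tab %>%
    group_by(.data$replicate_id, .data$frame_index, .data$tunnel_id) %>%
    summarise(ok = identical(sort(.data$sphere_index),
                             seq_len(n()) - 1L), .groups = "drop") %>%
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "sphere_index must be contiguous from 0 within a tunnel (first offender: replicate %s, frame %d, tunnel %d)",
      bad$replicate_id[1], bad$frame_index[1], bad$tunnel_id[1]))
  }
  tab
}

#' Read a flat key=value run configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numbers where possible, comma-separated values become vectors.
#'
#' @param path File path.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad)) abort(paste0("malformed config line: ", lines[which(bad)[1]]))
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  parse_one <- function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  }
  setNames(lapply(vals, parse_one), keys)
}
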