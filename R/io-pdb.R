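#' Van der Waals radius and atomic mass tables
#'
#' Element-based Bondi van der Waals radii (Angstrom) and standard atomic
#' masses (Dalton) for the elements occurring in the twenty standard amino
#' acids (H, C, N, O, S) plus the other elements commonly present in
#' protein structures (P, halogens). The table is the single source of truth
#' for radius assignment during tunnel detection and can be overridden by
#' passing a modified copy to [read_pdb_frames()]: rows are matched by the
#' `element` column.
#'
#' @return A tibble with columns `element`, `vdw_radius` (A) and `mass` (Da).
#' @export
#' @examples
#' default_radius_table()
default_radius_table <- function() {
  tibble(
    element    = c("H",    "C",     "N",     "O",     "S",    "P",     "F",
                   "CL",   "BR",    "I"),
    vdw_radius = c(1.20,   1.70,    1.55,    1.52,    1.80,   1.80,    1.47,
                   1.75,   1.85,    1.98),
    mass       = c(1.008,  12.011,  14.007,  15.999,  32.06,  30.974,  18.998,
                   35.45,  79.904,  126.904)
  )
}

# Resolve element symbols from a PDB element column, falling back to the
# atom-name convention (leading digits stripped, first alphabetic character;
# two-letter halogens recognised). Unknown atoms raise rather than default.
resolve_elements_ <- function(name, elesy, radius_table) {
  ele <- toupper(trimws(elesy %||% rep("", length(name))))
  nm <- toupper(trimws(name))
  fallback <- sub("^[0-9']+", "", nm)
  two <- substr(fallback, 1, 2)
  one <- substr(fallback, 1, 1)
  guess <- ifelse(two %in% c("CL", "BR"), two, one)
  ele[is.na(ele) | ele == ""] <- guess[is.na(ele) | ele == ""]
  bad <- !(ele %in% radius_table$element)
  if (any(bad)) {
    abort(sprintf(
      "unknown element for atom name(s): %s; extend the radius table to cover them",
      paste(unique(nm[bad]), collapse = ", ")
    ))
  }
  ele
}

new_snapshot_ <- function(atoms, frame_index, time) {
  attr(atoms, "frame_index") <- as.integer(frame_index)
  attr(atoms, "time") <- as.numeric(time)
  class(atoms) <- unique(c("td_snapshot", class(atoms)))
  atoms
}

#' Construct a structure snapshot
#'
#' A snapshot is one trajectory frame: a tibble of atoms (serial, name,
#' residue identity, coordinates in Angstrom, van der Waals radius, mass)
#' carrying `frame_index` and `time` (ns) attributes.
#'
#' @param atoms Data frame with columns `serial`, `name`, `residue_name`,
#'   `residue_id`, `x`, `y`, `z`, `vdw_radius`, `mass`.
#' @param frame_index Non-negative integer frame number.
#' @param time Frame time in ns.
#' @return A `td_snapshot` tibble.
#' @export
snapshot <- function(atoms, frame_index = 0L, time = 0) {
  req <- c("serial", "name", "residue_name", "residue_id", "x", "y", "z",
           "vdw_radius", "mass")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0)
    abort(paste0("atoms is missing column(s): ", paste(missing_cols, collapse = ", ")))
  atoms <- as_tibble(atoms)
  if (anyDuplicated(atoms$serial))
    abort("atom serials must be unique within a snapshot")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    abort("atom positions must be finite")
  if (any(atoms$vdw_radius <= 0)) abort("vdw_radius must be > 0")
  if (any(atoms$mass <= 0)) abort("mass must be > 0")
  if (frame_index < 0) abort("frame_index must be non-negative")
  if (time < 0) abort("time must be non-negative")
  new_snapshot_(atoms, frame_index, time)
}

#' @export
print.td_snapshot <- function(x, ...) {
  cat(sprintf("<snapshot> frame %d, t = %g ns, %d atoms\n",
              frame_index(x), frame_time(x), nrow(x)))
  NextMethod()
}

#' Snapshot and ensemble accessors
#'
#' @param x A `td_snapshot` or `td_ensemble`.
#' @return `frame_index()` and `frame_time()` return the frame number and time
#'   of a snapshot; `frame_spacing()`, `replicate_id()` and `condition_label()`
#'   return ensemble metadata; `n_frames()` the number of snapshots;
#'   `get_snapshot()` one materialised snapshot.
#' @name ensemble-accessors
NULL

#' @rdname ensemble-accessors
#' @export
frame_index <- function(x) attr(x, "frame_index")

#' @rdname ensemble-accessors
#' @export
frame_time <- function(x) attr(x, "time")

#' @rdname ensemble-accessors
#' @export
frame_spacing <- function(x) attr(x, "frame_spacing")

#' @rdname ensemble-accessors
#' @export
replicate_id <- function(x) attr(x, "replicate_id")

#' @rdname ensemble-accessors
#' @export
condition_label <- function(x) attr(x, "condition")

#' @rdname ensemble-accessors
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.td_ensemble <- function(x) nrow(x)

#' @export
n_frames.td_gated_ensemble <- function(x) nrow(x$series)

#' @rdname ensemble-accessors
#' @param i Frame position (1-based).
#' @export
get_snapshot <- function(x, i) UseMethod("get_snapshot")

#' @export
get_snapshot.td_ensemble <- function(x, i) {
  new_snapshot_(x$atoms[[i]], x$frame_index[i], x$time[i])
}

#' Construct a snapshot ensemble
#'
#' An ensemble is an ordered collection of snapshots from one trajectory
#' replicate, stored as a tibble with one row per frame (`frame_index`,
#' `time`, and an `atoms` list-column) plus replicate metadata. Frame times
#' are `frame_index * frame_spacing`.
#'
#' @param snapshots List of snapshots (see [snapshot()]) or atom tibbles.
#' @param replicate_id Replicate label.
#' @param condition Condition label (e.g. a water-model name).
#' @param frame_spacing Time between frames, ns (default 0.02, i.e. 20 ps).
#' @return A `td_ensemble` tibble.
#' @export
ensemble <- function(snapshots, replicate_id = "rep1", condition = "default",
                     frame_spacing = 0.02) {
  check_number_(frame_spacing, "frame_spacing", 0, strict = TRUE)
  if (length(snapshots) == 0) abort("ensemble must contain at least one snapshot")
  atoms <- lapply(snapshots, function(s) {
    s <- as_tibble(s)
    attr(s, "frame_index") <- NULL
    attr(s, "time") <- NULL
    class(s) <- setdiff(class(s), "td_snapshot")
    s
  })
  out <- tibble(
    frame_index = seq_along(atoms) - 1L,
    time = (seq_along(atoms) - 1L) * frame_spacing,
    atoms = atoms
  )
  attr(out, "replicate_id") <- replicate_id
  attr(out, "condition") <- condition
  attr(out, "frame_spacing") <- frame_spacing
  class(out) <- unique(c("td_ensemble", class(out)))
  out
}

#' Read PDB snapshot files into an ensemble
#'
#' Parses one or more PDB files (ATOM/HETATM records; multi-MODEL files give
#' one snapshot per MODEL block) into a [ensemble()]. Van der Waals radii and
#' masses are assigned per element from `radius_table`; an atom whose element
#' is not covered raises an error rather than silently defaulting. Where
#' alternate locations are present, the first altloc wins (reported via a
#' message). Frames are ordered by file (lexicographic order of the supplied
#' paths) and MODEL number.
#'
#' @param paths Character vector of PDB file paths.
#' @param replicate_id,condition,frame_spacing Ensemble metadata; see
#'   [ensemble()].
#' @param radius_table Element table; see [default_radius_table()].
#' @param include_hydrogens Keep hydrogen atoms if present (default TRUE;
#'   all-atom snapshots are analysed as written).
#' @return A `td_ensemble`.
#' @export
read_pdb_frames <- function(paths, replicate_id = "rep1", condition = "default",
                            frame_spacing = 0.02,
                            radius_table = default_radius_table(),
                            include_hydrogens = TRUE) {
  paths <- sort(as.character(paths))
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files) > 0)
    abort(paste0("file not found: ", paste(missing_files, collapse = ", ")))
  snaps <- list()
  for (path in paths) {
    lines <- readLines(path, warn = FALSE)
    atom_lines <- grepl("^(ATOM  |HETATM)", lines)
    if (!any(atom_lines))
      abort(paste0("no ATOM records in ", path))
    # malformed coordinate fields fail loudly, naming the line
    coord_txt <- substr(lines[atom_lines], 31, 54)
    bad <- which(is.na(suppressWarnings(as.numeric(substr(coord_txt, 1, 8)))) |
                   is.na(suppressWarnings(as.numeric(substr(coord_txt, 9, 16)))) |
                   is.na(suppressWarnings(as.numeric(substr(coord_txt, 17, 24)))))
    if (length(bad) > 0) {
      abort(sprintf("malformed ATOM record at line %d of %s",
                    which(atom_lines)[bad[1]], path))
    }
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    at <- pdb$atom
    alt <- at$alt
    alt[is.na(alt)] <- ""
    if (any(alt != "")) {
      inform(paste0("alternate locations present in ", path, "; first altloc wins"))
      keep <- which(alt == "" | alt == min(alt[alt != ""]))
      at <- at[keep, , drop = FALSE]
      cols <- as.vector(t(cbind(keep * 3 - 2, keep * 3 - 1, keep * 3)))
      pdb$xyz <- pdb$xyz[, cols, drop = FALSE]
    }
    ele <- resolve_elements_(at$elety, at$elesy, radius_table)
    ri <- match(ele, radius_table$element)
    n_models <- nrow(pdb$xyz)
    for (m in seq_len(n_models)) {
      xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
      atoms <- tibble(
        serial = as.integer(at$eleno),
        name = trimws(at$elety),
        residue_name = trimws(at$resid),
        residue_id = as.integer(at$resno),
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        vdw_radius = radius_table$vdw_radius[ri],
        mass = radius_table$mass[ri],
        element = ele
      )
      if (!include_hydrogens) atoms <- atoms[atoms$element != "H", , drop = FALSE]
      snaps[[length(snaps) + 1L]] <- atoms
    }
  }
  ensemble(snaps, replicate_id = replicate_id, condition = condition,
           frame_spacing = frame_spacing)
}

#' Write an ensemble to a multi-model PDB file
#'
#' Serialises every snapshot of the ensemble as a MODEL/ENDMDL block in one
#' PDB file (fixed-width 8.3 coordinate columns, so round-tripping through
#' [read_pdb_frames()] preserves coordinates to 1e-3 A).
#'
#' @param ens A `td_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_frames <- function(ens, path) {
  if (!inherits(ens, "td_ensemble")) abort("`ens` must be a td_ensemble")
  if (nrow(ens) == 0) abort("cannot write an empty ensemble")
  a1 <- ens$atoms[[1]]
  xyz <- do.call(rbind, lapply(ens$atoms, function(a) c(rbind(a$x, a$y, a$z))))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz, type = "ATOM",
    eleno = a1$serial, elety = a1$name, resid = a1$residue_name,
    chain = "A", resno = a1$residue_id,
    elesy = if (is.null(a1$element)) NULL else a1$element
  )
  invisible(path)
}
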