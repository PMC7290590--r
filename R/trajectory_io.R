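#' Write / read the native frame format
#'
#' The native trajectory format is a diff-able tab-separated table, one row
#' per frame, preceded by `#`-prefixed metadata lines (format version, seed,
#' a JSON echo of the configuration and of each snapshot's generation
#' parameters).  Numbers are serialised with six decimal places.  The
#' membrane snapshot table is written alongside (same format idea) and
#' `read_frames()` reassembles the full bundle, validating column presence,
#' numeric types and the frame invariants; malformed input produces a format
#' error naming the offending row and column.
#'
#' @param bundle a [trajectory_bundle()].
#' @param path output path for the frames TSV.
#' @param membrane_path output path for the membrane TSV; defaults to the
#'   frames path with a `_membrane.tsv` suffix.
#' @return `write_frames()`: `path`, invisibly.  `read_frames()`: a
#'   `trajectory_bundle`.
#' @export
write_frames <- function(bundle, path,
                         membrane_path = default_membrane_path(path)) {
  stopifnot(inherits(bundle, "trajectory_bundle"))
  fr <- bundle$frames
  meta <- c(
    "# memtitrate-frames",
    paste0("# format_version=", bundle$metadata$format_version),
    paste0("# seed=", if (is.null(bundle$metadata$seed)) "NA" else bundle$metadata$seed),
    paste0("# membrane_file=", basename(membrane_path)),
    if (!is.null(bundle$metadata$config))
      paste0("# config=", jsonlite::toJSON(unclass(bundle$metadata$config),
                                           auto_unbox = TRUE, digits = NA)))
  cols <- c("replicate_id", "replica_id", "step", "time", "pH", "prot_state",
            "group_x", "group_y", "group_z", "snapshot_id")
  writeLines(c(meta, paste(cols, collapse = "\t")), path)
  if (nrow(fr)) {
    body <- data.table::data.table(
      fr$replicate_id, fr$replica_id, fr$step,
      sprintf("%.6f", fr$time), sprintf("%.6f", fr$pH), fr$prot_state,
      sprintf("%.6f", fr$group_x), sprintf("%.6f", fr$group_y),
      sprintf("%.6f", fr$group_z), fr$snapshot_id)
    data.table::fwrite(body, path, sep = "\t", col.names = FALSE,
                       quote = FALSE, append = TRUE)
  }
  write_membrane(bundle$snapshots, membrane_path)
  invisible(path)
}

default_membrane_path <- function(path) {
  sub("(\\.[A-Za-z0-9]+)?$", "_membrane.tsv", path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path, membrane_path = NULL) {
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  head_lines <- readLines(path, n = 50L)
  meta <- grep("^#", head_lines, value = TRUE)
  kv <- parse_meta(meta)
  if (is.null(membrane_path)) {
    if (is.null(kv$membrane_file))
      stop_format("frames file does not name its membrane_file and no membrane_path given")
    membrane_path <- file.path(dirname(path), kv$membrane_file)
  }
  tab <- data.table::fread(path, sep = "\t", header = TRUE, skip = length(meta),
                           colClasses = list(character = "snapshot_id"),
                           data.table = FALSE, showProgress = FALSE)
  cols <- c("replicate_id", "replica_id", "step", "time", "pH", "prot_state",
            "group_x", "group_y", "group_z", "snapshot_id")
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    stop_format(paste0("frames file missing column(s): ",
                       paste(miss, collapse = ", ")))
  if (!nrow(tab)) {
    tab <- data.frame(replicate_id = integer(), replica_id = integer(),
                      step = integer(), time = numeric(), pH = numeric(),
                      prot_state = integer(), group_x = numeric(),
                      group_y = numeric(), group_z = numeric(),
                      snapshot_id = character(), stringsAsFactors = FALSE)
  }
  for (cc in setdiff(cols, "snapshot_id")) {
    if (!is.numeric(tab[[cc]]))
      stop_format(paste0("non-numeric value in column '", cc, "', row ",
                         which(is.na(suppressWarnings(as.numeric(tab[[cc]]))))[1]))
    if (anyNA(tab[[cc]]))
      stop_format(paste0("missing value in column '", cc, "', row ",
                         which(is.na(tab[[cc]]))[1]))
  }
  bad <- which(!(tab$prot_state %in% c(0, 1)))
  if (length(bad))
    stop_format(paste0("prot_state outside {0,1} in column 'prot_state', row ",
                       bad[1]))
  snapshots <- read_membrane(membrane_path)
  unknown <- which(!(tab$snapshot_id %in% names(snapshots)))
  if (length(unknown))
    stop_format(paste0("unknown snapshot_id in column 'snapshot_id', row ",
                       unknown[1]))
  tab$replicate_id <- as.integer(tab$replicate_id)
  tab$replica_id <- as.integer(tab$replica_id)
  tab$step <- as.integer(tab$step)
  tab$prot_state <- as.integer(tab$prot_state)
  cfg <- NULL
  if (!is.null(kv$config)) {
    cfg <- jsonlite::fromJSON(kv$config, simplifyVector = TRUE)
    class(cfg) <- "sim_config"
  }
  bundle <- trajectory_bundle(tab, unname(snapshots), config = cfg,
                              seed = if (!is.null(kv$seed) && kv$seed != "NA")
                                       as.integer(kv$seed))
  bundle$metadata$format_version <-
    if (!is.null(kv$format_version)) as.integer(kv$format_version) else 1L
  bundle
}

parse_meta <- function(meta_lines) {
  kv <- list()
  for (ln in meta_lines) {
    ln <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq > 0)
      kv[[substr(ln, 1, eq - 1)]] <- substr(ln, eq + 1, nchar(ln))
  }
  kv
}

#' Write / read the native membrane snapshot format
#'
#' Tab-separated atom table (`snapshot_id`, `atom_id`, `element`, `leaflet`,
#' `x`, `y`, `z`) with one `#`-prefixed JSON metadata line per snapshot
#' carrying the box and the analytic-surface generation parameters (kept for
#' oracle tests).
#'
#' @param snapshots a `membrane_snapshot` or list of them.
#' @param path file path.
#' @return `write_membrane()`: `path`, invisibly; `read_membrane()`: a named
#'   list of `membrane_snapshot` objects.
#' @export
write_membrane <- function(snapshots, path) {
  if (inherits(snapshots, "membrane_snapshot")) snapshots <- list(snapshots)
  meta <- vapply(snapshots, function(s) {
    paste0("# snapshot=", jsonlite::toJSON(
      c(list(snapshot_id = s$snapshot_id, box_x = s$box_x, box_y = s$box_y),
        s$metadata), auto_unbox = TRUE, digits = NA))
  }, "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# memtitrate-membrane", "# format_version=1", meta), con)
  writeLines(paste(c("snapshot_id", "atom_id", "element", "leaflet",
                     "x", "y", "z"), collapse = "\t"), con)
  for (s in snapshots) {
    a <- s$atoms
    writeLines(paste(s$snapshot_id, a$atom_id, a$element, a$leaflet,
                     sprintf("%.6f", a$x), sprintf("%.6f", a$y),
                     sprintf("%.6f", a$z), sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_membrane
#' @export
read_membrane <- function(path) {
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  snap_meta <- lapply(grep("^# snapshot=", meta, value = TRUE), function(ln) {
    jsonlite::fromJSON(sub("^# snapshot=", "", ln), simplifyVector = TRUE)
  })
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("snapshot_id", "atom_id", "element", "leaflet", "x", "y", "z")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_format(paste0("membrane file missing column(s): ",
                       paste(miss, collapse = ", ")))
  for (cc in c("x", "y", "z"))
    if (!is.numeric(tab[[cc]]) || anyNA(tab[[cc]]))
      stop_format(paste0("non-numeric value in membrane column '", cc, "'"))
  names(snap_meta) <- vapply(snap_meta, function(m) m$snapshot_id, "")
  out <- lapply(split(tab, tab$snapshot_id), function(a) {
    id <- a$snapshot_id[1]
    mm <- snap_meta[[id]]
    if (is.null(mm))
      stop_format(paste0("membrane file lacks metadata for snapshot ", id))
    a <- a[order(a$atom_id), c("atom_id", "element", "leaflet", "x", "y", "z")]
    rownames(a) <- NULL
    structure(list(snapshot_id = id, box_x = mm$box_x, box_y = mm$box_y,
                   atoms = a,
                   metadata = mm[setdiff(names(mm),
                                         c("snapshot_id", "box_x", "box_y"))]),
              class = "membrane_snapshot")
  })
  out
}

#' Read a membrane snapshot from a GROMACS coordinate file
#'
#' Minimal fixed-column reader for the GROMACS `.gro` format (title line,
#' atom count, one fixed-width line per atom with residue/atom names and nm
#' coordinates, box line).  Atoms whose names match `phosphate_atom_names`
#' are selected as the phosphate-group reference set; coordinates are
#' converted from nm to Angstrom and leaflets are assigned by z relative to
#' the mean phosphate z.  The atom-name list is force-field specific and must
#' be chosen by the user for real data; the default matches the names written
#' by [write_structure()].
#'
#' @param path path to a `.gro` file.
#' @param phosphate_atom_names character vector of atom names to select
#'   (phosphorus plus the phosphate oxygens).
#' @param snapshot_id identifier for the returned snapshot.
#' @return a `membrane_snapshot` (metadata records the source file only; no
#'   analytic surface parameters are available for real data).
#' @export
read_structure <- function(path, phosphate_atom_names = c("P", "O1", "O2",
                                                          "O3", "O4"),
                           snapshot_id = "structure") {
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  lines <- readLines(path)
  if (length(lines) < 3) stop_format("structure file too short")
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms)) stop_format("unparsable atom count on line 2")
  if (length(lines) < natoms + 3)
    stop_format(paste0("atom-count mismatch: header says ", natoms,
                       " atoms but file has ", length(lines) - 3, " atom lines"))
  atom_lines <- lines[3:(2 + natoms)]
  name <- trimws(substr(atom_lines, 11, 15))
  xs <- suppressWarnings(as.numeric(substr(atom_lines, 21, 28)))
  ys <- suppressWarnings(as.numeric(substr(atom_lines, 29, 36)))
  zs <- suppressWarnings(as.numeric(substr(atom_lines, 37, 44)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad))
    stop_format(paste0("unparsable coordinate on atom line ", bad[1]))
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[natoms + 3]),
                                              "\\s+")[[1]]))
  if (length(box) < 3 || anyNA(box[1:3]))
    stop_format("unparsable box line")
  keep <- name %in% phosphate_atom_names
  if (!any(keep)) stop_format("no phosphate-group atoms selected")
  x <- xs[keep] * 10; y <- ys[keep] * 10; z <- zs[keep] * 10  # nm -> A
  element <- ifelse(grepl("^P", name[keep]), "P", "O")
  leaflet <- ifelse(z >= mean(z), "upper", "lower")
  structure(list(snapshot_id = snapshot_id,
                 box_x = box[1] * 10, box_y = box[2] * 10,
                 atoms = data.frame(atom_id = seq_along(x), element = element,
                                    leaflet = leaflet, x = x, y = y, z = z,
                                    stringsAsFactors = FALSE),
                 metadata = list(source = path)),
            class = "membrane_snapshot")
}

#' Export a membrane snapshot to a GROMACS coordinate file
#'
#' Inverse adapter for [read_structure()]: writes the phosphate-group atom
#' cloud as a `.gro` file (A converted to nm).  Phosphorus atoms are named
#' `P` and oxygens cycle through `O1`, `O2`, ...; one residue per atom.
#'
#' @param snapshot a `membrane_snapshot`.
#' @param path output path.
#' @param box_z box height in Angstrom (the lateral box comes from the
#'   snapshot).
#' @return `path`, invisibly.
#' @export
write_structure <- function(snapshot, path, box_z = 80) {
  a <- snapshot$atoms
  is_o <- a$element == "O"
  nm <- a$element
  nm[is_o] <- paste0("O", (seq_len(sum(is_o)) - 1) %% 4 + 1)
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   a$atom_id %% 100000L, "MEM", nm, a$atom_id %% 100000L,
                   a$x / 10, a$y / 10, a$z / 10)
  writeLines(c(paste0("memtitrate membrane snapshot ", snapshot$snapshot_id),
               sprintf("%5d", nrow(a)), lines,
               sprintf("%10.5f%10.5f%10.5f", snapshot$box_x / 10,
                       snapshot$box_y / 10, box_z / 10)),
             path)
  invisible(path)
}
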