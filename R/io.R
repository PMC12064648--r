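# Readers and writers for PDB (single and multi-model) and XYZ.
# Internal units are angstroms throughout; sources that store nanometres
# are converted once, here, under `units = "nm"`.

PDB_KNOWN_2LETTER <- c("NA", "CL", "MG", "FE", "ZN", "BR", "MN", "CU", "SE")

# parse the ATOM/HETATM lines of one model into an atom data.frame;
# lineno carries original file line numbers for error messages
parse_pdb_atoms <- function(lines, lineno) {
  pad <- formatC(lines, width = 80, flag = "-")
  serial <- suppressWarnings(as.integer(substr(pad, 7, 11)))
  name <- trimws(substr(pad, 13, 16))
  altloc <- substr(pad, 17, 17)
  resname <- trimws(substr(pad, 18, 20))
  chain <- substr(pad, 22, 22)
  resid <- suppressWarnings(as.integer(substr(pad, 23, 26)))
  x <- suppressWarnings(as.numeric(substr(pad, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(pad, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(pad, 47, 54)))
  occ <- suppressWarnings(as.numeric(substr(pad, 55, 60)))
  occ[is.na(occ)] <- 1
  elem <- trimws(substr(pad, 77, 78))
  bad <- is.na(x) | is.na(y) | is.na(z) | is.na(resid)
  if (any(bad)) {
    stop("malformed PDB record at line ", lineno[which(bad)[1]], ": '",
         trimws(lines[which(bad)[1]]), "'")
  }
  elem <- ifelse(nzchar(elem), toupper(elem),
                 infer_element(substr(pad, 13, 16)))
  data.frame(serial = serial, name = toupper(name), altloc = altloc,
             element = elem, resname = resname, resid = resid,
             chain = chain, x = x, y = y, z = z, occ = occ,
             stringsAsFactors = FALSE)
}

# atom-name heuristic used when the element column is blank: a two-letter
# element left-justified in the 4-char name field (NA, CL, FE, ...) wins;
# otherwise the first alphabetic character (digits prefix hydrogens, 1HB2)
infer_element <- function(name4) {
  two <- toupper(substr(name4, 1, 2))
  first_alpha <- toupper(sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1",
                             trimws(name4)))
  ifelse(substr(name4, 1, 1) != " " & two %in% PDB_KNOWN_2LETTER,
         two, first_alpha)
}

# altloc rule: within each (chain, resid, icode-free atom name) group keep
# the highest-occupancy conformer; ties resolved to altloc 'A', then first
# record seen.  Deterministic by construction.
resolve_altloc <- function(atoms) {
  if (all(atoms$altloc %in% c(" ", ""))) {
    atoms$altloc <- NULL
    return(atoms)
  }
  key <- paste(atoms$chain, atoms$resid, atoms$name, sep = "\r")
  ord <- order(key,
               -atoms$occ,
               atoms$altloc != "A",
               seq_len(nrow(atoms)),
               method = "radix")
  keep_first <- !duplicated(key[ord])
  sel <- sort(ord[keep_first])   # restore file order
  atoms <- atoms[sel, , drop = FALSE]
  atoms$altloc <- NULL
  rownames(atoms) <- NULL
  atoms
}

#' Read a PDB structure
#'
#' Parses fixed-width ATOM/HETATM records.  The element is taken from the
#' element column when present, otherwise inferred from the atom name.
#' When alternate locations exist, the highest-occupancy conformer is kept
#' (ties go to altloc 'A').  For multi-model files, the first model is
#' returned; use [read_trajectory()] for all models.
#'
#' @param path path to a PDB file.
#' @return an [md_structure()].
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1)]
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  atoms <- parse_pdb_atoms(lines[is_atom], which(is_atom))
  atoms <- resolve_altloc(atoms)
  md_structure(atoms)
}

format_pdb_name <- function(name, element) {
  # 1-letter elements with short names start in column 14
  ifelse(nchar(name) < 4 & nchar(element) == 1,
         sprintf(" %-3s", name), sprintf("%-4s", name))
}

pdb_atom_lines <- function(atoms, xyz) {
  rec <- ifelse(toupper(atoms$resname) %in%
                  c(SOLVENT_RESNAMES, "LIG", "TPP", "NAP"),
                "HETATM", "ATOM  ")
  sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, atoms$serial %% 100000,
          format_pdb_name(atoms$name, atoms$element),
          atoms$resname, atoms$chain, atoms$resid,
          xyz[, 1], xyz[, 2], xyz[, 3], atoms$occ, 0,
          formatC(atoms$element, width = 2))
}

#' Write a structure to a PDB file
#' @param structure an `md_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  lines <- c(pdb_atom_lines(structure$atoms, coords(structure)), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a trajectory
#'
#' Supported formats: multi-model PDB (`MODEL`/`ENDMDL` blocks; topology
#' from model 1 unless supplied) and XYZ (repeated
#' count/comment/element-x-y-z blocks; topology required).  DCD is not
#' implemented; convert binary trajectories to one of the text formats
#' first.  Frame times are synthesized as 0, 1, 2, ... ns when the source
#' carries none.
#'
#' @param path trajectory file.
#' @param format `"pdb"` or `"xyz"`; default guessed from the extension.
#' @param topology optional `md_structure`; mandatory for XYZ.
#' @param units `"angstrom"` (default) or `"nm"`; nm sources are converted
#'   to angstroms on read.
#' @return an [md_trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz"),
                            topology = NULL,
                            units = c("angstrom", "nm")) {
  format <- match.arg(format)
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "xyz") "xyz" else if (ext %in% c("pdb", "ent"))
      "pdb" else stop("cannot guess trajectory format from '", ext,
                      "'; pass format=")
  }
  scale <- if (units == "nm") 10 else 1
  traj <- switch(format,
                 pdb = read_traj_pdb(path, topology),
                 xyz = read_traj_xyz(path, topology))
  if (scale != 1) traj$coords <- traj$coords * scale
  traj
}

read_traj_pdb <- function(path, topology) {
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  if (!length(model_starts)) {
    s <- read_pdb(path)
    top <- if (is.null(topology)) s else topology
    if (n_atoms(top) != n_atoms(s)) {
      stop("topology atom count (", n_atoms(top),
           ") does not match file (", n_atoms(s), ")")
    }
    return(md_trajectory(top, list(coords(s))))
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) < length(model_starts)) {
    stop("truncated trajectory: frame ", length(model_starts),
         " lacks ENDMDL")
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  frame_of <- findInterval(which(is_atom), model_starts)
  atom_lines <- lines[is_atom]
  nf <- length(model_starts)
  counts <- tabulate(frame_of, nbins = nf)

  # topology: parse model 1 in full
  first <- atom_lines[frame_of == 1]
  atoms1 <- resolve_altloc(parse_pdb_atoms(first, which(is_atom)[frame_of == 1]))
  top <- if (is.null(topology)) md_structure(atoms1) else topology
  na <- n_atoms(top)
  bad <- which(counts != na)
  if (length(bad)) {
    stop("frame ", bad[1], " has ", counts[bad[1]],
         " atoms; topology has ", na)
  }
  pad <- formatC(atom_lines, width = 54, flag = "-")
  x <- suppressWarnings(as.numeric(substr(pad, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(pad, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(pad, 47, 54)))
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    bad_i <- which(is.na(x) | is.na(y) | is.na(z))[1]
    stop("malformed coordinate record at line ", which(is_atom)[bad_i])
  }
  coords <- array(0, dim = c(na, 3, nf))
  coords[, 1, ] <- x
  coords[, 2, ] <- y
  coords[, 3, ] <- z
  md_trajectory(top, coords)
}

read_traj_xyz <- function(path, topology) {
  if (is.null(topology)) stop("XYZ trajectories require a topology")
  lines <- readLines(path, warn = FALSE)
  na <- n_atoms(topology)
  block <- na + 2
  nonempty <- length(lines)
  while (nonempty > 0 && !nzchar(trimws(lines[nonempty]))) {
    nonempty <- nonempty - 1
  }
  lines <- lines[seq_len(nonempty)]
  if (length(lines) %% block != 0) {
    stop("truncated XYZ trajectory: frame ",
         length(lines) %/% block + 1, " is incomplete")
  }
  nf <- length(lines) %/% block
  coords <- array(0, dim = c(na, 3, nf))
  for (f in seq_len(nf)) {
    off <- (f - 1) * block
    cnt <- suppressWarnings(as.integer(trimws(lines[off + 1])))
    if (is.na(cnt) || cnt != na) {
      stop("frame ", f, " atom count (", lines[off + 1],
           ") does not match topology (", na, ")")
    }
    body <- lines[off + 2 + seq_len(na)]
    parts <- strsplit(trimws(body), "\\s+")
    m <- matrix(suppressWarnings(
      as.numeric(unlist(lapply(parts, `[`, 2:4)))), ncol = 3, byrow = TRUE)
    if (anyNA(m)) stop("malformed XYZ coordinates in frame ", f)
    coords[, , f] <- m
  }
  md_trajectory(topology, coords)
}

#' Write a trajectory
#'
#' Multi-model PDB (`MODEL`/`ENDMDL`) or XYZ blocks, coordinates in
#' angstroms with 3 decimal places.
#'
#' @param traj an `md_trajectory`.
#' @param path output path.
#' @param format `"pdb"` or `"xyz"`; default from the extension.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "xyz") "xyz" else "pdb"
  }
  atoms <- traj$topology$atoms
  nf <- n_frames(traj)
  out <- vector("list", nf)
  if (format == "pdb") {
    for (f in seq_len(nf)) {
      out[[f]] <- c(sprintf("MODEL     %4d", f),
                    pdb_atom_lines(atoms, traj$coords[, , f]),
                    "ENDMDL")
    }
    lines <- c(unlist(out), "END")
  } else {
    for (f in seq_len(nf)) {
      xyz <- traj$coords[, , f]
      out[[f]] <- c(sprintf("%d", nrow(atoms)),
                    sprintf("frame %d t= %.6f ns", f, traj$times[f]),
                    sprintf("%-2s %12.6f %12.6f %12.6f", atoms$element,
                            xyz[, 1], xyz[, 2], xyz[, 3]))
    }
    lines <- unlist(out)
  }
  writeLines(lines, path)
  invisible(path)
}
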