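# Structure container and atom-level bookkeeping.
#
# An md_structure is a list with
#   $atoms    data.frame: serial, name, element, resname, resid, chain,
#             x, y, z, occ, radius, mass   (one row per atom, file order)
#   $residues data.frame: chain, resid, resname (ordered distinct residues)
# Atom order is authoritative and never changed by any operation.

ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, NA. = 22.990, CL = 35.45, MG = 24.305, K = 39.098,
  CA. = 40.078, FE = 55.845, ZN = 65.38, F = 18.998
)

#' Construct a structure from an atom table
#'
#' Low-level constructor used by the readers and the synthetic generators.
#' The residue table is derived as the ordered set of distinct
#' (chain, resid) pairs in atom order.
#'
#' @param atoms data.frame with at least columns `name`, `element`,
#'   `resname`, `resid`, `chain`, `x`, `y`, `z`.  Missing `serial`, `occ`,
#'   `radius`, `mass` columns are filled with defaults.
#' @return An object of class `md_structure`.
#' @export
md_structure <- function(atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  need <- c("name", "element", "resname", "resid", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) {
    stop("atom table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$radius)) atoms$radius <- NA_real_
  if (is.null(atoms$mass)) {
    atoms$mass <- unname(ATOMIC_MASSES[element_key(atoms$element)])
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, residues = derive_residues(atoms)),
            class = "md_structure")
}

# monatomic-ion elements share symbols with atom names (NA, CA); the mass
# table disambiguates with a trailing dot
element_key <- function(el) {
  el <- toupper(el)
  ifelse(el == "NA", "NA.", ifelse(el == "CA", "CA.", el))
}

derive_residues <- function(atoms) {
  key <- paste(atoms$chain, atoms$resid, sep = "\r")
  first <- !duplicated(key)
  data.frame(chain = atoms$chain[first], resid = atoms$resid[first],
             resname = atoms$resname[first], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf("md_structure: %d atoms, %d residues (%s)\n",
              nrow(x$atoms), nrow(x$residues),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

n_atoms <- function(structure) nrow(structure$atoms)

#' Coordinates of a structure as an n x 3 matrix
#' @param structure an `md_structure`
#' @return numeric matrix with columns x, y, z (angstroms).
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == n_atoms(structure), ncol(xyz) == 3)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

## ---- van der Waals radius sets -------------------------------------------

#' Van der Waals radius sets
#'
#' Returns a named radius set used by [assign_radii()].  The default
#' `"bondi"` set carries the standard Bondi radii (angstroms): H 1.20,
#' C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, Na 2.27, plus halogens and
#' common metals.  Elements outside the table fall back to
#' `default_radius`.
#'
#' @param name radius-set name; only `"bondi"` is shipped.
#' @param default_radius radius (angstroms) used for elements not in the
#'   table; default 1.50.
#' @return list with fields `name`, `radii` (named numeric vector) and
#'   `default_radius`, class `radius_set`.
#' @export
radius_set <- function(name = "bondi", default_radius = 1.50) {
  name <- match.arg(name, "bondi")
  radii <- c(
    H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    NA. = 2.27, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    MG = 1.73, K = 2.75, ZN = 1.39
  )
  stopifnot(all(radii > 0), default_radius > 0)
  structure(list(name = name, radii = radii,
                 default_radius = default_radius),
            class = "radius_set")
}

#' Assign van der Waals radii to every atom
#'
#' Fills the `radius` column of the atom table from a [radius_set()].
#' Elements missing from the set receive the set's default radius and a
#' warning names them.  Coordinates and atom order are untouched.
#'
#' @param structure an `md_structure` with elements inferred.
#' @param rset a [radius_set()]; default Bondi.
#' @return the structure with all `radius` values set (> 0).
#' @export
assign_radii <- function(structure, rset = radius_set()) {
  stopifnot(inherits(structure, "md_structure"), inherits(rset, "radius_set"))
  key <- element_key(structure$atoms$element)
  r <- unname(rset$radii[key])
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("no vdW radius for element(s) ",
            paste(sort(unique(structure$atoms$element[unknown])),
                  collapse = ", "),
            "; using default ", rset$default_radius, " A")
    r[unknown] <- rset$default_radius
  }
  structure$atoms$radius <- r
  structure
}

## ---- selections ----------------------------------------------------------

SOLVENT_RESNAMES <- c("HOH", "SOL", "WAT", "TIP", "TIP3", "SPC")

#' Select atoms of a structure
#'
#' A small selection grammar: clauses joined by `and`, each clause one of
#' \describe{
#'   \item{`all`}{every atom}
#'   \item{`heavy`}{non-hydrogen atoms}
#'   \item{`calpha`}{atoms named CA (alias `ca`)}
#'   \item{`resid 333-335` / `resid 297 298 323`}{residue-id ranges or lists}
#'   \item{`chain A`}{chain identifier}
#'   \item{`name CA CB`}{atom names}
#'   \item{`resname GLY`}{residue names}
#'   \item{`protein`}{drops solvent residues (HOH/SOL/WAT/...) and
#'     monoatomic ions}
#' }
#'
#' @param structure an `md_structure`.
#' @param spec selection string, e.g. `"resid 333-335 and heavy"`.
#' @return object of class `md_selection`: list with integer `indices`
#'   (1-based atom rows, topology order, unique) and `label` (the spec).
#'   An empty result is allowed but raises a warning.
#' @export
select_atoms <- function(structure, spec) {
  stopifnot(inherits(structure, "md_structure"), is.character(spec),
            length(spec) == 1)
  atoms <- structure$atoms
  keep <- rep(TRUE, nrow(atoms))
  clauses <- strsplit(trimws(spec), "\\s+and\\s+")[[1]]
  if (!length(clauses)) stop("empty selection spec")
  for (cl in clauses) {
    toks <- strsplit(trimws(cl), "\\s+")[[1]]
    kw <- tolower(toks[1])
    args <- toks[-1]
    keep <- keep & switch(kw,
      all = rep(TRUE, nrow(atoms)),
      heavy = toupper(atoms$element) != "H",
      ca = ,
      calpha = atoms$name == "CA",
      protein = !is_solvent_or_ion(atoms),
      resid = atoms$resid %in% parse_id_list(args, cl),
      chain = {
        if (!length(args)) stop("selection clause needs a value: '", cl, "'")
        atoms$chain %in% args
      },
      name = {
        if (!length(args)) stop("selection clause needs a value: '", cl, "'")
        atoms$name %in% toupper(args)
      },
      resname = {
        if (!length(args)) stop("selection clause needs a value: '", cl, "'")
        atoms$resname %in% toupper(args)
      },
      stop("cannot parse selection token '", toks[1], "' in '", spec, "'")
    )
  }
  idx <- which(keep)
  if (!length(idx)) warning("selection '", spec, "' matched no atoms")
  structure(list(indices = idx, label = spec), class = "md_selection")
}

is_solvent_or_ion <- function(atoms) {
  solvent <- toupper(atoms$resname) %in% SOLVENT_RESNAMES
  # monoatomic ion: residue with a single atom whose name equals its element
  key <- paste(atoms$chain, atoms$resid, sep = "\r")
  n_per <- as.integer(table(key)[key])
  ion <- n_per == 1 & toupper(atoms$name) == toupper(atoms$element) &
    toupper(atoms$element) %in% c("NA", "CL", "K", "MG", "CA", "ZN", "FE")
  solvent | ion
}

parse_id_list <- function(args, clause) {
  if (!length(args)) stop("selection clause needs a value: '", clause, "'")
  parts <- unlist(strsplit(args, ","))
  parts <- parts[nzchar(parts)]
  ids <- integer(0)
  for (p in parts) {
    if (grepl("^-?[0-9]+--?[0-9]+$", p)) {
      m <- regmatches(p, regexec("^(-?[0-9]+)-(-?[0-9]+)$", p))[[1]]
      ids <- c(ids, seq.int(as.integer(m[2]), as.integer(m[3])))
    } else if (grepl("^-?[0-9]+$", p)) {
      ids <- c(ids, as.integer(p))
    } else {
      stop("cannot parse residue id token '", p, "' in '", clause, "'")
    }
  }
  unique(ids)
}

#' @export
print.md_selection <- function(x, ...) {
  cat(sprintf("md_selection '%s': %d atoms\n", x$label, length(x$indices)))
  invisible(x)
}

# resolve a selection-or-string argument against a topology
as_selection <- function(structure, sel) {
  if (inherits(sel, "md_selection")) {
    if (length(sel$indices) &&
        max(sel$indices) > n_atoms(structure)) {
      stop("selection indices exceed topology atom count")
    }
    return(sel)
  }
  select_atoms(structure, sel)
}

#' Patch definition
#'
#' Names the residue patch whose solvent exposure is tracked.  The default
#' is the tau fibril-interface GGG patch, residues 333-335 (0N4R
#' numbering, as in the 5O3L fibril structure).
#'
#' @param resids integer residue ids (author numbering).
#' @param chain chain id, or NA to match any chain.
#' @param label free label for reports.
#' @return object of class `patch_definition`.
#' @export
patch_definition <- function(resids = 333:335, chain = NA_character_,
                             label = "GGG") {
  stopifnot(length(resids) >= 1, !anyNA(resids))
  structure(list(resids = as.integer(resids), chain = chain, label = label),
            class = "patch_definition")
}

# atom rows of the patch; errors listing any residue id absent from topology
patch_atom_indices <- function(structure, patch) {
  stopifnot(inherits(patch, "patch_definition"))
  atoms <- structure$atoms
  in_chain <- if (is.na(patch$chain)) rep(TRUE, nrow(atoms))
              else atoms$chain == patch$chain
  present <- unique(atoms$resid[in_chain])
  missing <- setdiff(patch$resids, present)
  if (length(missing)) {
    stop("patch residue(s) not in topology: ",
         paste(missing, collapse = ", "))
  }
  which(in_chain & atoms$resid %in% patch$resids)
}
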