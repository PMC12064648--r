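# Residue-ligand contact analysis: per-frame contact detection from
# minimum atom-atom distances, per-segment relative contact frequencies,
# and the gained/lost differential between trajectory halves.

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

# one-letter-code + number labels ("K298"); unknown residue names keep
# their 3-letter code
residue_labels <- function(resname, resid) {
  one <- AA3TO1[toupper(resname)]
  one[is.na(one)] <- resname[is.na(one)]
  paste0(one, resid)
}

#' Minimum residue-ligand distance in one frame
#'
#' Minimum over all (residue-atom, ligand-atom) pairs of the Euclidean
#' distance.
#'
#' @param xyz n x 3 frame coordinates (angstroms).
#' @param residue_idx integer atom rows of the residue.
#' @param ligand_idx integer atom rows of the ligand.
#' @return distance in angstroms.
#' @export
residue_ligand_min_distance <- function(xyz, residue_idx, ligand_idx) {
  if (!length(residue_idx) || !length(ligand_idx)) {
    stop("empty selection: both residue and ligand atoms are required")
  }
  xyz <- as.matrix(xyz)
  .residue_min_dist_cpp(xyz, as.integer(residue_idx - 1L),
                        0L, length(residue_idx),
                        as.integer(ligand_idx - 1L))[1]
}

#' Residue-ligand contact matrix over a trajectory
#'
#' A residue is in contact with the ligand in a frame when the minimum
#' distance between its atoms (of the chosen class) and the ligand atoms
#' is at or below the cutoff (the tie at exactly the cutoff counts as a
#' contact).  Solvent residues and the ligand's own residues are never
#' rows of the matrix.
#'
#' @param traj an `md_trajectory`.
#' @param ligand `md_selection` or selection string naming the ligand
#'   atoms; must be disjoint from the protein residues analysed.
#' @param cutoff contact cutoff in angstroms; default 4.5 (a standard
#'   heavy-atom protein-ligand convention).
#' @param atom_class `"heavy"` (default) or `"all"`: which protein atoms
#'   enter the minimum distance.
#' @return object of class `contact_matrix`: fields `residues`
#'   (data.frame chain/resid/resname/label), `in_contact` (residues x
#'   frames logical matrix), `min_dist` (same shape, angstroms), `cutoff`,
#'   `atom_class`, `times`.
#' @export
contact_matrix <- function(traj, ligand, cutoff = 4.5,
                           atom_class = c("heavy", "all")) {
  atom_class <- match.arg(atom_class)
  stopifnot(inherits(traj, "md_trajectory"), cutoff > 0)
  top <- traj$topology
  lig <- as_selection(top, ligand)
  if (!length(lig$indices)) stop("ligand selection is empty")
  atoms <- top$atoms
  prot_rows <- setdiff(which(!is_solvent_or_ion(atoms)), lig$indices)
  if (atom_class == "heavy") {
    prot_rows <- prot_rows[toupper(atoms$element[prot_rows]) != "H"]
  }
  if (!length(prot_rows)) stop("no protein atoms outside the ligand")
  lig_res <- unique(paste(atoms$chain[lig$indices],
                          atoms$resid[lig$indices]))
  prot_res <- paste(atoms$chain[prot_rows], atoms$resid[prot_rows])
  if (any(prot_res %in% lig_res)) {
    stop("ligand selection overlaps protein residues; ",
         "contacts would be self-contacts")
  }
  # group protein atoms by residue, in topology order
  key <- paste(atoms$chain[prot_rows], atoms$resid[prot_rows], sep = "\r")
  first <- !duplicated(key)
  res_tab <- data.frame(chain = atoms$chain[prot_rows][first],
                        resid = atoms$resid[prot_rows][first],
                        resname = atoms$resname[prot_rows][first],
                        stringsAsFactors = FALSE)
  res_tab$label <- residue_labels(res_tab$resname, res_tab$resid)
  grp <- match(key, key[first])
  ord <- order(grp, seq_along(grp))
  prot_rows <- prot_rows[ord]
  grp <- grp[ord]
  start0 <- as.integer(c(0, cumsum(tabulate(grp)))[seq_len(nrow(res_tab))])
  end0 <- as.integer(cumsum(tabulate(grp)))
  nf <- n_frames(traj)
  md <- matrix(NA_real_, nrow(res_tab), nf)
  for (f in seq_len(nf)) {
    md[, f] <- .residue_min_dist_cpp(frame_coords(traj, f),
                                     as.integer(prot_rows - 1L),
                                     start0, end0,
                                     as.integer(lig$indices - 1L))
  }
  structure(list(residues = res_tab, in_contact = md <= cutoff,
                 min_dist = md, cutoff = cutoff, atom_class = atom_class,
                 times = traj$times),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "contact_matrix: %d residues x %d frames, cutoff %.2f A (%s atoms)\n",
    nrow(x$residues), ncol(x$in_contact), x$cutoff, x$atom_class))
  invisible(x)
}

#' Export a contact matrix to TSV (residue rows, frame columns, 0/1)
#' @param cm a `contact_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contact_matrix_tsv <- function(cm, path) {
  m <- matrix(as.integer(cm$in_contact), nrow = nrow(cm$residues))
  df <- cbind(data.frame(residue = cm$residues$label,
                         stringsAsFactors = FALSE),
              as.data.frame(m))
  names(df)[-1] <- paste0("frame_", seq_len(ncol(m)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-segment relative contact frequencies
#'
#' For each segment, the fraction of its frames in which each residue is
#' in contact with the ligand (a plain fraction in `[0, 1]`).  Setting
#' `normalize = TRUE` additionally divides by the maximum residue
#' frequency within the segment (off by default).
#'
#' @param cm a [contact_matrix()].
#' @param segmentation `"halves"` or a list of frame vectors (see
#'   [segment_frames()]); the split rule is shared with [segment_stats()].
#' @param normalize divide by the per-segment maximum frequency.
#' @return list of `contact_profile` objects, one per segment, each a
#'   list with `residues`, `frequency`, `segment`, `frames`.
#' @export
contact_frequency <- function(cm, segmentation = "halves",
                              normalize = FALSE) {
  stopifnot(inherits(cm, "contact_matrix"))
  segs <- segment_frames(ncol(cm$in_contact), segmentation)
  lapply(names(segs), function(nm) {
    fr <- segs[[nm]]
    freq <- rowMeans(cm$in_contact[, fr, drop = FALSE])
    if (normalize && max(freq) > 0) freq <- freq / max(freq)
    structure(list(residues = cm$residues, frequency = unname(freq),
                   segment = nm, frames = fr),
              class = "contact_profile")
  })
}

#' @export
print.contact_profile <- function(x, ...) {
  top <- order(x$frequency, decreasing = TRUE)
  top <- top[x$frequency[top] > 0][1:min(5, sum(x$frequency > 0))]
  cat(sprintf("contact_profile '%s': %d residues over %d frames\n",
              x$segment, length(x$frequency), length(x$frames)))
  if (length(top) && !anyNA(top)) {
    cat("  top contacts:",
        paste(sprintf("%s (%.2f)", x$residues$label[top],
                      x$frequency[top]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.contact_profile <- function(x, ...) {
  barplot(x$frequency, names.arg = x$residues$resid, las = 2,
          cex.names = 0.5, ylab = "contact frequency",
          main = x$segment, ...)
  invisible(x)
}

#' Gained and lost contacts between two segments
#'
#' Residues whose contact frequency increased by at least
#' `gain_threshold` from the first to the second profile are "gained";
#' those that decreased by at least `loss_threshold` are "lost".  The
#' full per-residue frequency difference is reported for all residues.
#'
#' @param first,second `contact_profile` objects over identical residue
#'   lists (e.g. the two halves from [contact_frequency()]).
#' @param gain_threshold,loss_threshold frequency-change thresholds in
#'   `[0, 1]`; defaults 0.25.
#' @return object of class `differential_contacts`: `table` (data.frame
#'   residue label, resid, freq_first, freq_second, delta), `gained` and
#'   `lost` (character labels), `gained_resid`/`lost_resid` (integer
#'   ids), thresholds.
#' @export
differential_contacts <- function(first, second, gain_threshold = 0.25,
                                  loss_threshold = 0.25) {
  stopifnot(inherits(first, "contact_profile"),
            inherits(second, "contact_profile"),
            gain_threshold > 0, loss_threshold > 0)
  if (!identical(first$residues$resid, second$residues$resid) ||
      !identical(first$residues$chain, second$residues$chain)) {
    stop("the two profiles cover different residue lists")
  }
  delta <- second$frequency - first$frequency
  tab <- data.frame(residue = first$residues$label,
                    chain = first$residues$chain,
                    resid = first$residues$resid,
                    freq_first = first$frequency,
                    freq_second = second$frequency,
                    delta = delta, stringsAsFactors = FALSE)
  gained <- delta >= gain_threshold
  lost <- -delta >= loss_threshold
  structure(list(table = tab,
                 gained = tab$residue[gained],
                 lost = tab$residue[lost],
                 gained_resid = tab$resid[gained],
                 lost_resid = tab$resid[lost],
                 gain_threshold = gain_threshold,
                 loss_threshold = loss_threshold),
            class = "differential_contacts")
}

#' @export
print.differential_contacts <- function(x, ...) {
  cat(sprintf(
    "differential_contacts (gain >= %.2f, loss >= %.2f):\n",
    x$gain_threshold, x$loss_threshold))
  cat("  gained:", if (length(x$gained)) paste(x$gained, collapse = ", ")
      else "(none)", "\n")
  cat("  lost:  ", if (length(x$lost)) paste(x$lost, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
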