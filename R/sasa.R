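# Shrake-Rupley solvent-accessible surface area and the patch-exposure
# analysis built on it: per-frame patch area, threshold classification,
# and per-segment stability statistics.

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by test points on probe-expanded spheres.  Test points
#' are a deterministic golden-section spiral (no RNG), so results are
#' reproducible bit-for-bit.  A point is accessible when it lies outside
#' every other atom's probe-expanded sphere; the atom's area is the
#' accessible fraction times `4*pi*(r + probe)^2`.
#'
#' @param xyz n x 3 coordinate matrix (angstroms), or an `md_structure`
#'   with radii assigned.
#' @param radii per-atom van der Waals radii; taken from the structure
#'   when `xyz` is an `md_structure`.
#' @param probe_radius probe sphere radius; default 1.40 (water).
#' @param n_sphere_points test points per atom, >= 92; default 960.
#' @param method `"cell"` (cell-list neighbour search, default) or
#'   `"all_pairs"` (reference path).  Both give identical areas.
#' @return numeric vector of per-atom areas (square angstroms).
#' @export
shrake_rupley_sasa <- function(xyz, radii = NULL, probe_radius = 1.4,
                               n_sphere_points = 960,
                               method = c("cell", "all_pairs")) {
  method <- match.arg(method)
  if (inherits(xyz, "md_structure")) {
    if (is.null(radii)) radii <- xyz$atoms$radius
    xyz <- coords(xyz)
  }
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, n_sphere_points >= 92, probe_radius >= 0)
  if (is.null(radii) || length(radii) != nrow(xyz)) {
    stop("per-atom radii are required (assign_radii first?)")
  }
  if (anyNA(radii)) {
    stop("atom ", which(is.na(radii))[1],
         " has no radius; run assign_radii() first")
  }
  stopifnot(all(radii > 0))
  fn <- if (method == "cell") .sasa_cell_list_cpp else .sasa_all_pairs_cpp
  fn(xyz, as.numeric(radii), probe_radius, as.integer(n_sphere_points))
}

#' Unit-sphere quadrature points used by the SASA kernel
#' @param n number of points.
#' @return n x 3 matrix of unit vectors on the golden-section spiral.
#' @export
sphere_points <- function(n = 960) .sphere_points_cpp(as.integer(n))

#' Surface area of a residue patch in one frame
#'
#' Sum of per-atom SASA over all atoms of the patch residues, computed in
#' the context of the full structure: every atom present occludes,
#' including ligand atoms unless `exclude` drops them.
#'
#' @param structure an `md_structure` with radii assigned (coordinates of
#'   the frame of interest).
#' @param patch a [patch_definition()].
#' @param probe_radius,n_sphere_points,method passed to
#'   [shrake_rupley_sasa()].
#' @param exclude optional `md_selection` (or spec string) of atoms to
#'   remove from the occlusion context (e.g. the ligand).
#' @return patch area in square angstroms.
#' @export
patch_area <- function(structure, patch = patch_definition(),
                       probe_radius = 1.4, n_sphere_points = 960,
                       method = "cell", exclude = NULL) {
  if (!is.null(exclude)) {
    drop <- as_selection(structure, exclude)$indices
    if (length(drop)) {
      structure$atoms <- structure$atoms[-drop, , drop = FALSE]
      structure$residues <- derive_residues(structure$atoms)
    }
  }
  idx <- patch_atom_indices(structure, patch)
  a <- shrake_rupley_sasa(coords(structure), structure$atoms$radius,
                          probe_radius, n_sphere_points, method)
  sum(a[idx])
}

#' Patch-exposure time series with threshold classification
#'
#' Computes the patch surface area for every frame and labels each frame
#' exposed when the area is at or above the threshold (the tie at exactly
#' the threshold counts as exposed; a strictly smaller area is buried).
#' The conventional threshold for the 3-glycine fibril-interface patch is
#' 100 square angstroms.
#'
#' @param traj an `md_trajectory` (radii are assigned to the topology on
#'   the fly if missing).
#' @param patch a [patch_definition()].
#' @param threshold exposure threshold, square angstroms; default 100.
#' @param probe_radius,n_sphere_points,method passed to
#'   [shrake_rupley_sasa()].
#' @param exclude optional selection removed from the occlusion context
#'   (e.g. the ligand), resolved once against the topology.
#' @return object of class `exposure_series`: fields `times`, `areas`,
#'   `exposed`, `threshold`, `patch`.
#' @export
exposure_series <- function(traj, patch = patch_definition(),
                            threshold = 100, probe_radius = 1.4,
                            n_sphere_points = 960, method = "cell",
                            exclude = NULL) {
  stopifnot(inherits(traj, "md_trajectory"), threshold >= 0)
  top <- traj$topology
  if (anyNA(top$atoms$radius)) top <- assign_radii(top)
  keep <- seq_len(n_atoms(top))
  if (!is.null(exclude)) {
    drop <- as_selection(top, exclude)$indices
    if (length(drop)) keep <- setdiff(keep, drop)
  }
  sub <- top
  sub$atoms <- top$atoms[keep, , drop = FALSE]
  sub$residues <- derive_residues(sub$atoms)
  idx <- patch_atom_indices(sub, patch)
  radii <- sub$atoms$radius
  areas <- vapply(seq_len(n_frames(traj)), function(f) {
    a <- shrake_rupley_sasa(traj$coords[keep, , f], radii, probe_radius,
                            n_sphere_points, method)
    sum(a[idx])
  }, numeric(1))
  structure(list(times = traj$times, areas = areas,
                 exposed = areas >= threshold, threshold = threshold,
                 patch = patch,
                 probe_radius = probe_radius,
                 n_sphere_points = n_sphere_points),
            class = "exposure_series")
}

#' @export
print.exposure_series <- function(x, ...) {
  cat(sprintf(
    "exposure_series '%s': %d frames, mean %.1f A^2, %.1f%% exposed (>= %g A^2)\n",
    x$patch$label, length(x$areas), mean(x$areas),
    100 * mean(x$exposed), x$threshold))
  invisible(x)
}

#' @export
plot.exposure_series <- function(x, ...) {
  plot(x$times, x$areas, type = "n", xlab = "time (ns)",
       ylab = sprintf("patch area (A^2)"), ...)
  points(x$times[!x$exposed], x$areas[!x$exposed], col = "red", pch = 20,
         cex = 0.4)
  points(x$times[x$exposed], x$areas[x$exposed], col = "black", pch = 20,
         cex = 0.4)
  abline(h = x$threshold, lty = 2)
  invisible(x)
}

#' Export an exposure series to TSV
#' @param series an `exposure_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_exposure_tsv <- function(series, path) {
  df <- data.frame(time_ns = sprintf("%.6f", series$times),
                   area_A2 = sprintf("%.6f", series$areas),
                   exposed = as.integer(series$exposed))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-segment exposure statistics
#'
#' Mean, sample SD (n-1 denominator) and fraction of exposed frames per
#' trajectory segment.  The default segmentation is halves (extra frame
#' to the first half for odd counts), shared with the contact analysis.
#'
#' @param series an `exposure_series`.
#' @param segmentation `"halves"` or a list of frame-index vectors (see
#'   [segment_frames()]).
#' @return data.frame of class `segment_stats`: segment, frame_start,
#'   frame_end (half-open, 1-based start / exclusive end), n_frames,
#'   mean_area, sd_area, fraction_exposed.
#' @export
segment_stats <- function(series, segmentation = "halves") {
  stopifnot(inherits(series, "exposure_series"))
  segs <- segment_frames(length(series$areas), segmentation)
  rows <- lapply(names(segs), function(nm) {
    fr <- segs[[nm]]
    a <- series$areas[fr]
    data.frame(segment = nm, frame_start = fr[1],
               frame_end = fr[length(fr)] + 1L, n_frames = length(fr),
               mean_area = mean(a),
               sd_area = if (length(a) > 1) stats::sd(a) else 0,
               fraction_exposed = mean(series$exposed[fr]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("segment_stats", class(out))
  out
}

#' Compare two exposure series segment by segment
#'
#' Reports, per matching segment, the differences (a minus b) in mean
#' area, area SD and fraction of exposed frames.  Both series must share
#' the threshold and probe settings; no hypothesis test is performed.
#'
#' @param series_a,series_b `exposure_series` objects.
#' @param segmentation shared segmentation (default `"halves"`).
#' @return data.frame: segment, delta_mean, delta_sd,
#'   delta_fraction_exposed.
#' @export
compare_exposure <- function(series_a, series_b, segmentation = "halves") {
  stopifnot(inherits(series_a, "exposure_series"),
            inherits(series_b, "exposure_series"))
  if (series_a$threshold != series_b$threshold ||
      series_a$probe_radius != series_b$probe_radius ||
      series_a$n_sphere_points != series_b$n_sphere_points) {
    stop("series were computed with different threshold/probe settings")
  }
  sa <- segment_stats(series_a, segmentation)
  sb <- segment_stats(series_b, segmentation)
  if (!identical(sa$segment, sb$segment)) {
    stop("segmentation mismatch between the two series")
  }
  data.frame(segment = sa$segment,
             delta_mean = sa$mean_area - sb$mean_area,
             delta_sd = sa$sd_area - sb$sd_area,
             delta_fraction_exposed =
               sa$fraction_exposed - sb$fraction_exposed,
             stringsAsFactors = FALSE)
}
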