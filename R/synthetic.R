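# Seeded coarse-grained trajectory generators with recorded ground truth.
#
# The chain is a bead-per-residue solenoid (9 beads per turn, 3.8 A bond
# length) of carbon-like pseudo-C-alpha beads.  Three scenarios emulate the
# statistical structure the analyses assume:
#   * compaction        -- radius of gyration drops between two regimes
#   * two-regime patch exposure -- variable/lower-mean first half,
#                          stable/higher-mean second half of the patch SASA
#   * ligand switch     -- a 5-bead polyphosphate-like ligand tethered to
#                          residue group A before the switch frame and
#                          group B after it
# Ground-truth statistics are always the realized values recomputed from
# the generated coordinates, never the requested targets.

HELIX_BEADS_PER_TURN <- 9L
HELIX_RISE <- 0.7          # A per bead; one turn = 6.3 A, safely self-avoiding
BOND_LENGTH <- 3.8         # A, pseudo-C-alpha virtual bond

#' Parameters for the synthetic-trajectory generators
#'
#' Defaults mirror the tau K18 study system: 129 residues numbered
#' 244-372, a 3-residue fibril-interface patch at 333-335, per-half patch
#' area targets of 113 and 121 square angstroms with SDs 24 and 11, and a
#' ligand whose tethered residue group switches at the trajectory
#' midpoint.
#'
#' @param n_residues chain length; default 129.
#' @param first_resid first residue id (author numbering); default 244.
#' @param n_frames frames to generate; default 2000.
#' @param seed RNG seed (one global Mersenne-Twister stream per
#'   generator invocation).
#' @param bead_radius bead van der Waals radius in angstroms; default
#'   1.70 (the Bondi carbon radius, so radii survive a PDB round trip).
#' @param dt_ns time step between frames, ns; default 0.5 (a
#'   one-microsecond trajectory at 2000 frames).
#' @param switch_frame last frame of the first regime; default
#'   `ceiling(n_frames / 2)` so regimes coincide with the halves
#'   segmentation.
#' @param patch_resids patch residue ids; default 333:335.
#' @param exposure_mean,exposure_sd per-regime patch-area targets
#'   (square angstroms); defaults c(113, 121) and c(24, 11).
#' @param rg_mean,rg_sd per-regime radius-of-gyration targets
#'   (angstroms); defaults c(22, 15) and c(0.4, 0.4).
#' @param group_a,group_b residue-id sets for the ligand tether before
#'   and after the switch; defaults c(250, 251) and c(298, 307).
#' @param tether_distance minimum ligand-to-tethered-bead distance,
#'   angstroms; default 3.0 (inside the 4.5 contact cutoff).
#' @param ligand_noise SD of the rigid per-frame ligand jitter,
#'   angstroms; default 0.3.
#' @param ou_phi lag-1 autocorrelation of the mean-reverting
#'   (Ornstein-Uhlenbeck) driver processes; default 0.8.
#' @return object of class `generator_params`.
#' @export
generator_params <- function(n_residues = 129L, first_resid = 244L,
                             n_frames = 2000L, seed = 1L,
                             bead_radius = 1.70, dt_ns = 0.5,
                             switch_frame = NULL,
                             patch_resids = 333:335,
                             exposure_mean = c(113, 121),
                             exposure_sd = c(24, 11),
                             rg_mean = c(22, 15), rg_sd = c(0.4, 0.4),
                             group_a = c(250L, 251L),
                             group_b = c(298L, 307L),
                             tether_distance = 3.0, ligand_noise = 0.3,
                             ou_phi = 0.8) {
  if (is.null(switch_frame)) switch_frame <- ceiling(n_frames / 2)
  stopifnot(n_residues >= 4, n_frames >= 2,
            switch_frame >= 1, switch_frame < n_frames,
            bead_radius > 0, all(exposure_sd >= 0), all(rg_sd >= 0),
            length(exposure_mean) == 2, length(exposure_sd) == 2,
            length(rg_mean) == 2, length(rg_sd) == 2,
            tether_distance > 0, ligand_noise >= 0,
            ou_phi >= 0, ou_phi < 1)
  structure(list(n_residues = as.integer(n_residues),
                 first_resid = as.integer(first_resid),
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 bead_radius = bead_radius, dt_ns = dt_ns,
                 switch_frame = as.integer(switch_frame),
                 patch_resids = as.integer(patch_resids),
                 exposure_mean = exposure_mean, exposure_sd = exposure_sd,
                 rg_mean = rg_mean, rg_sd = rg_sd,
                 group_a = as.integer(group_a),
                 group_b = as.integer(group_b),
                 tether_distance = tether_distance,
                 ligand_noise = ligand_noise, ou_phi = ou_phi),
            class = "generator_params")
}

# solenoid base coordinates: exact 3.8 A bonds, 9 beads/turn
helix_coords <- function(n) {
  theta <- 2 * pi / HELIX_BEADS_PER_TURN
  chord_xy <- sqrt(BOND_LENGTH^2 - HELIX_RISE^2)
  R <- chord_xy / (2 * sin(theta / 2))
  i <- seq_len(n) - 1
  cbind(x = R * cos(i * theta), y = R * sin(i * theta), z = i * HELIX_RISE)
}

#' Build the coarse-grained bead chain
#'
#' One carbon-like bead per residue (named CA, residue name GLY, chain A)
#' on a self-avoiding solenoid with exact 3.8-angstrom virtual bonds.
#' The construction is deterministic; `params$seed` matters only for the
#' trajectory generators built on top.
#'
#' @param params a [generator_params()].
#' @return an [md_structure()] with `radius` preset to
#'   `params$bead_radius`.
#' @export
make_bead_chain <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  n <- params$n_residues
  xyz <- helix_coords(n)
  atoms <- data.frame(
    serial = seq_len(n), name = "CA", element = "C", resname = "GLY",
    resid = seq.int(params$first_resid, length.out = n), chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
    radius = params$bead_radius, mass = 12.011,
    stringsAsFactors = FALSE)
  md_structure(atoms)
}

# mean-reverting (AR(1)) sample path with per-regime stationary mean/sd;
# re-initialized from the stationary law at each regime start
ou_path <- function(n_frames, switch_frame, means, sds, phi) {
  x <- numeric(n_frames)
  regime <- c(rep(1L, switch_frame), rep(2L, n_frames - switch_frame))
  innov_scale <- sqrt(1 - phi^2)
  for (t in seq_len(n_frames)) {
    r <- regime[t]
    if (t == 1 || regime[t - 1] != r) {
      x[t] <- means[r] + sds[r] * rnorm(1)
    } else {
      x[t] <- means[r] + phi * (x[t - 1] - means[r]) +
        sds[r] * innov_scale * rnorm(1)
    }
  }
  list(x = x, regime = regime)
}

# --- exposure steering -----------------------------------------------------
# Patch beads slide along their own radial (xy) direction by a common
# offset d: negative d tucks them into the solenoid channel (buried),
# positive d pushes them clear of the wall (exposed).  The map d -> patch
# SASA is measured once per invocation on a pilot grid and inverted, so
# the steering stays geometric and the requested area targets are reached
# through calibration rather than by prescribing areas directly.

displace_patch <- function(base_xyz, patch_idx, d) {
  xyz <- base_xyz
  u <- base_xyz[patch_idx, 1:2, drop = FALSE]
  u <- u / sqrt(rowSums(u^2))
  xyz[patch_idx, 1:2] <- xyz[patch_idx, 1:2] + d * u
  xyz
}

# monotone span of the burial coordinate: -9 tucks the patch against the
# far solenoid wall (deep burial), +8 is fully clear of the chain
PILOT_D_GRID <- seq(-9, 8, by = 0.5)

pilot_area_curve <- function(base_xyz, radii, patch_idx, probe,
                             n_points) {
  areas <- vapply(PILOT_D_GRID, function(d) {
    xyz <- displace_patch(base_xyz, patch_idx, d)
    a <- .sasa_all_pairs_cpp(xyz, radii, probe, as.integer(n_points))
    sum(a[patch_idx])
  }, numeric(1))
  # keep the monotone increasing envelope so inversion is well defined
  areas <- cummax(areas)
  stats::approxfun(PILOT_D_GRID, areas, rule = 2)
}

# choose (d_mean, d_sd) so that area(d), d ~ N(d_mean, d_sd^2), has the
# requested mean/SD; deterministic equal-probability quadrature
calibrate_regime <- function(curve, target_mean, target_sd) {
  lo <- curve(min(PILOT_D_GRID)); hi <- curve(max(PILOT_D_GRID))
  if (target_mean <= lo || target_mean >= hi) {
    stop("unattainable exposure target: mean ", target_mean,
         " A^2 outside the achievable range [", round(lo, 1), ", ",
         round(hi, 1), "]")
  }
  z <- stats::qnorm(seq(0.005, 0.995, length.out = 199))
  g <- PILOT_D_GRID
  dm <- g[which.min(abs(vapply(g, curve, 1) - target_mean))]
  ds <- if (target_sd > 0) 0.5 else 0
  h <- 0.25
  for (iter in 1:60) {
    slope <- (curve(dm + h) - curve(dm - h)) / (2 * h)
    if (slope <= 1e-6) slope <- 1e-6
    a <- curve(dm + ds * z)
    mu <- mean(a)
    dm <- dm + (target_mean - mu) / slope
    if (target_sd > 0) {
      sg <- sqrt(mean((a - mean(a))^2))
      if (sg > 1e-9) ds <- ds * min(2, max(0.5, target_sd / sg))
      else ds <- ds * 1.5
    }
  }
  c(d_mean = dm, d_sd = ds)
}

#' Simulate a two-regime patch-exposure trajectory
#'
#' The chain skeleton stays fixed; the patch beads slide radially under a
#' mean-reverting process whose stationary patch-area mean and SD per
#' regime are calibrated (by pilot sampling of the geometry-to-area map
#' at generation time) to the requested targets.  The regime switches at
#' `params$switch_frame`.  Ground truth records the realized per-half
#' sample mean/SD of the patch area, recomputed from the generated
#' coordinates.
#'
#' @param params a [generator_params()].
#' @param probe_radius,n_sphere_points surface settings used for the
#'   calibration pilot and the realized ground truth; defaults 1.4 / 960.
#' @return list with `trajectory` (an [md_trajectory()]) and `truth`
#'   (class `synthetic_truth`).
#' @export
simulate_exposure_trajectory <- function(params = generator_params(),
                                         probe_radius = 1.4,
                                         n_sphere_points = 960) {
  stopifnot(inherits(params, "generator_params"))
  with_generator_seed(params$seed)
  chain <- make_bead_chain(params)
  base_xyz <- coords(chain)
  patch_idx <- which(chain$atoms$resid %in% params$patch_resids)
  if (length(patch_idx) != length(params$patch_resids)) {
    stop("patch residues not all present in the chain")
  }
  radii <- chain$atoms$radius
  curve <- pilot_area_curve(base_xyz, radii, patch_idx, probe_radius,
                            n_sphere_points)
  cal1 <- calibrate_regime(curve, params$exposure_mean[1],
                           params$exposure_sd[1])
  cal2 <- calibrate_regime(curve, params$exposure_mean[2],
                           params$exposure_sd[2])
  path <- ou_path(params$n_frames, params$switch_frame,
                  c(cal1["d_mean"], cal2["d_mean"]),
                  c(cal1["d_sd"], cal2["d_sd"]), params$ou_phi)
  nf <- params$n_frames
  coords_arr <- array(0, dim = c(nrow(base_xyz), 3, nf))
  areas <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- displace_patch(base_xyz, patch_idx, path$x[f])
    coords_arr[, , f] <- xyz
    a <- .sasa_all_pairs_cpp(xyz, radii, probe_radius,
                             as.integer(n_sphere_points))
    areas[f] <- sum(a[patch_idx])
  }
  traj <- md_trajectory(chain, coords_arr,
                        times = (seq_len(nf) - 1) * params$dt_ns)
  halves <- segment_frames(nf, "halves")
  truth <- structure(list(
    scenario = "exposure",
    regime = path$regime,
    seed = params$seed,
    requested = list(mean = params$exposure_mean, sd = params$exposure_sd),
    realized_area_mean = vapply(halves, function(fr) mean(areas[fr]), 1),
    realized_area_sd = vapply(halves, function(fr) stats::sd(areas[fr]), 1),
    realized_fraction_exposed_100 =
      vapply(halves, function(fr) mean(areas[fr] >= 100), 1),
    areas = areas,
    params = unclass(params)), class = "synthetic_truth")
  list(trajectory = traj, truth = truth)
}

#' Simulate a compaction trajectory
#'
#' The solenoid telescopes along its axis: the per-frame axial scale is
#' solved so the realized radius of gyration follows a mean-reverting
#' process around `params$rg_mean[1]` before the switch frame and
#' `params$rg_mean[2]` after it.  Ground truth records the realized
#' per-regime Rg mean/SD recomputed from the coordinates.
#'
#' @param params a [generator_params()].
#' @return list with `trajectory` and `truth` (class `synthetic_truth`).
#' @export
simulate_compaction_trajectory <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  with_generator_seed(params$seed)
  chain <- make_bead_chain(params)
  base_xyz <- coords(chain)
  ctr <- colMeans(base_xyz)
  xyz0 <- sweep(base_xyz, 2, ctr)
  rg_xy2 <- mean(xyz0[, 1]^2 + xyz0[, 2]^2)
  rg_z2 <- mean(xyz0[, 3]^2)
  min_rg <- sqrt(rg_xy2) * 1.001
  if (any(params$rg_mean <= min_rg)) {
    stop("Rg target below the chain's radial floor (",
         round(min_rg, 2), " A)")
  }
  path <- ou_path(params$n_frames, params$switch_frame,
                  params$rg_mean, params$rg_sd, params$ou_phi)
  rg_t <- pmax(path$x, min_rg)
  s_t <- sqrt((rg_t^2 - rg_xy2) / rg_z2)
  nf <- params$n_frames
  coords_arr <- array(0, dim = c(nrow(xyz0), 3, nf))
  for (f in seq_len(nf)) {
    xyz <- xyz0
    xyz[, 3] <- xyz[, 3] * s_t[f]
    coords_arr[, , f] <- sweep(xyz, 2, ctr, `+`)
  }
  traj <- md_trajectory(chain, coords_arr,
                        times = (seq_len(nf) - 1) * params$dt_ns)
  realized <- vapply(seq_len(nf), function(f) {
    radius_of_gyration(coords_arr[, , f])
  }, numeric(1))
  reg <- path$regime
  truth <- structure(list(
    scenario = "compaction",
    regime = reg,
    seed = params$seed,
    requested = list(rg_mean = params$rg_mean, rg_sd = params$rg_sd),
    realized_rg_mean = c(first = mean(realized[reg == 1]),
                         second = mean(realized[reg == 2])),
    realized_rg_sd = c(first = stats::sd(realized[reg == 1]),
                       second = stats::sd(realized[reg == 2])),
    rg = realized,
    params = unclass(params)), class = "synthetic_truth")
  list(trajectory = traj, truth = truth)
}

# ligand bead positions tethered to a residue group: beads spread evenly
# along the segment between the first and last group bead, pushed radially
# (in xy, away from the solenoid axis) by the tether distance
ligand_site <- function(chain_xyz, group_idx, tether, n_beads = 5) {
  a <- chain_xyz[group_idx[1], ]
  b <- chain_xyz[group_idx[length(group_idx)], ]
  f <- seq(0, 1, length.out = n_beads)
  base <- outer(1 - f, a) + outer(f, b)
  u <- base[, 1:2, drop = FALSE]
  u <- u / sqrt(rowSums(u^2))
  base[, 1:2] <- base[, 1:2] + tether * u
  base
}

#' Simulate a mid-trajectory ligand-binding switch
#'
#' A 5-bead polyphosphate-like ligand (P-O-P-O-P, residue TPP, chain L)
#' sits within `tether_distance` of residue group A for every frame up to
#' the switch frame and of group B afterwards, with rigid Gaussian jitter
#' of SD `ligand_noise` per frame.  The protein chain stays fixed, so
#' gained contacts are exactly group B and lost contacts exactly group A.
#'
#' @param params a [generator_params()].
#' @return list with `trajectory` and `truth` (class `synthetic_truth`);
#'   the truth carries `gained_resid` = group B and `lost_resid` =
#'   group A plus the matching one-letter labels.
#' @export
simulate_ligand_switch_trajectory <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  if (length(intersect(params$group_a, params$group_b))) {
    stop("tether groups A and B must be disjoint")
  }
  with_generator_seed(params$seed)
  chain <- make_bead_chain(params)
  resids <- chain$atoms$resid
  idx_a <- match(params$group_a, resids)
  idx_b <- match(params$group_b, resids)
  if (anyNA(idx_a) || anyNA(idx_b)) {
    stop("tether group residues must be present in the chain")
  }
  chain_xyz <- coords(chain)
  site_a <- ligand_site(chain_xyz, idx_a, params$tether_distance)
  site_b <- ligand_site(chain_xyz, idx_b, params$tether_distance)

  lig_atoms <- data.frame(
    serial = params$n_residues + 1:5,
    name = c("P1", "O1", "P2", "O2", "P3"),
    element = c("P", "O", "P", "O", "P"),
    resname = "TPP", resid = 400L, chain = "L",
    x = site_a[, 1], y = site_a[, 2], z = site_a[, 3], occ = 1,
    radius = c(1.80, 1.52, 1.80, 1.52, 1.80),
    mass = c(30.974, 15.999, 30.974, 15.999, 30.974),
    stringsAsFactors = FALSE)
  top <- md_structure(rbind(chain$atoms, lig_atoms))

  nf <- params$n_frames
  na <- n_atoms(top)
  lig_rows <- params$n_residues + 1:5
  coords_arr <- array(0, dim = c(na, 3, nf))
  regime <- c(rep(1L, params$switch_frame),
              rep(2L, nf - params$switch_frame))
  for (f in seq_len(nf)) {
    site <- if (regime[f] == 1L) site_a else site_b
    jitter <- rnorm(3, sd = params$ligand_noise)
    xyz <- rbind(chain_xyz, sweep(site, 2, jitter, `+`))
    coords_arr[, , f] <- xyz
  }
  traj <- md_trajectory(top, coords_arr,
                        times = (seq_len(nf) - 1) * params$dt_ns)
  truth <- structure(list(
    scenario = "ligand_switch",
    regime = regime,
    seed = params$seed,
    gained_resid = sort(params$group_b),
    lost_resid = sort(params$group_a),
    gained = residue_labels(rep("GLY", length(params$group_b)),
                            sort(params$group_b)),
    lost = residue_labels(rep("GLY", length(params$group_a)),
                          sort(params$group_a)),
    ligand_spec = "resname TPP",
    params = unclass(params)), class = "synthetic_truth")
  list(trajectory = traj, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth '%s' (seed %d): %d frames, switch at %d\n",
              x$scenario, x$seed, length(x$regime),
              sum(x$regime == 1L)))
  invisible(x)
}

# one documented global RNG stream per generator invocation
with_generator_seed <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  invisible(seed)
}

#' Write the canonical fixture set
#'
#' Generates the three canonical synthetic trajectories (compaction,
#' two-regime exposure, ligand switch) and writes each as a multi-model
#' PDB next to a ground-truth JSON, plus a manifest with seeds and MD5
#' checksums.
#'
#' @param dir output directory (created if missing).
#' @param seed base seed; the three fixtures use `seed`, `seed + 1`,
#'   `seed + 2`.
#' @param n_frames frames per fixture, named or unnamed length-3 vector
#'   in the order compaction, exposure, ligand_switch; default
#'   c(500, 2000, 400).
#' @return the manifest as a named list (also written to
#'   `manifest.json`), invisibly.
#' @export
write_fixture_set <- function(dir, seed = 1L,
                              n_frames = c(compaction = 500L,
                                           exposure = 2000L,
                                           ligand_switch = 400L)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(names(n_frames))) {
    names(n_frames) <- c("compaction", "exposure", "ligand_switch")
  }
  jobs <- list(
    compaction = function(p) simulate_compaction_trajectory(p),
    exposure = function(p) simulate_exposure_trajectory(p),
    ligand_switch = function(p) simulate_ligand_switch_trajectory(p))
  manifest <- list(seed = seed, files = list())
  for (i in seq_along(jobs)) {
    nm <- names(jobs)[i]
    p <- generator_params(n_frames = n_frames[[nm]],
                          seed = as.integer(seed + i - 1L))
    res <- jobs[[i]](p)
    pdb <- file.path(dir, paste0(nm, ".pdb"))
    truth_path <- file.path(dir, paste0(nm, "_truth.json"))
    write_trajectory(res$trajectory, pdb, format = "pdb")
    write_truth_json(res$truth, truth_path)
    manifest$files[[nm]] <- list(
      trajectory = basename(pdb), truth = basename(truth_path),
      seed = p$seed,
      md5 = list(trajectory = unname(tools::md5sum(pdb)),
                 truth = unname(tools::md5sum(truth_path))))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

write_truth_json <- function(truth, path) {
  out <- unclass(truth)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
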