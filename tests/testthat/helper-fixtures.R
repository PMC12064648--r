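# Shared fixtures and independent oracles, all built in code.

# one fixed-width ATOM line (standard PDB columns)
pdb_atom_line <- function(serial, name, resname, chain, resid, x, y, z,
                          occ = 1, element = "", altloc = " ") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          altloc, resname, chain, resid, x, y, z, occ, 0, element)
}

# 3-residue / 7-atom glycine-like fixture with explicit elements
write_tiny_pdb <- function(path) {
  lines <- c(
    pdb_atom_line(1, "N",  "GLY", "A", 333, 1.0, 2.0, 3.0, element = "N"),
    pdb_atom_line(2, "CA", "GLY", "A", 333, 2.2, 2.5, 3.1, element = "C"),
    pdb_atom_line(3, "C",  "GLY", "A", 333, 3.5, 1.9, 2.8, element = "C"),
    pdb_atom_line(4, "CA", "GLY", "A", 334, 5.1, 2.8, 3.6, element = "C"),
    pdb_atom_line(5, "O",  "GLY", "A", 334, 6.0, 1.9, 3.5, element = "O"),
    pdb_atom_line(6, "CA", "GLY", "A", 335, 7.9, 3.1, 4.2, element = "C"),
    pdb_atom_line(7, "HA", "GLY", "A", 335, 8.4, 3.9, 4.7, element = "H"),
    "END")
  writeLines(lines, path)
  path
}

# HETATM record with a left-justified atom name (metal-ion convention)
pdb_het_line <- function(serial, name, resname, chain, resid, x, y, z,
                         element = "") {
  sprintf("HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resname, chain, resid, x, y, z, 1, 0, element)
}

random_coords <- function(n, spread = 10) {
  matrix(runif(3 * n, -spread, spread), ncol = 3)
}

random_rotation <- function() {
  # QR of a random Gaussian matrix, determinant fixed to +1
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# analytic accessible area of two equal probe-expanded spheres of radius
# R with centre distance d < 2R: each sphere loses a cap of height
# h = R - d/2, cap area 2*pi*R*h
two_sphere_area <- function(r_vdw, probe, d) {
  R <- r_vdw + probe
  if (d >= 2 * R) return(2 * 4 * pi * R^2)
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

# brute-force minimum RMSD over a ZYZ Euler rotation grid (step degrees)
# followed by Nelder-Mead refinement; independent of the SVD route.  Uses
# rmsd^2 = c - (2/n) * sum(H * R) with H the centred mixed moment matrix,
# so the grid search reduces to a dot product per rotation; the grid's
# nine R-element columns are precomputed once and shared across calls.
make_rotation_grid <- function(step_deg = 5) {
  step <- step_deg * pi / 180
  g1 <- seq(0, 2 * pi - step / 2, by = step)
  g2 <- seq(0, pi, by = step)
  ang <- expand.grid(a = g1, b = g2, c = g1)
  ca <- cos(ang$a); sa <- sin(ang$a)
  cb <- cos(ang$b); sb <- sin(ang$b)
  cc <- cos(ang$c); sc <- sin(ang$c)
  cols <- cbind(ca * cb * cc - sa * sc,   # R11
                sa * cb * cc + ca * sc,   # R21
                -sb * cc,                 # R31
                -ca * cb * sc - sa * cc,  # R12
                -sa * cb * sc + ca * cc,  # R22
                sb * sc,                  # R32
                ca * sb,                  # R13
                sa * sb,                  # R23
                cb)                       # R33
  list(ang = as.matrix(ang), cols = cols)
}

euler_zyz <- function(ang) {
  ca <- cos(ang); sa <- sin(ang)
  Rz1 <- matrix(c(ca[1], sa[1], 0, -sa[1], ca[1], 0, 0, 0, 1), 3)
  Ry <- matrix(c(ca[2], 0, -sa[2], 0, 1, 0, sa[2], 0, ca[2]), 3)
  Rz2 <- matrix(c(ca[3], sa[3], 0, -sa[3], ca[3], 0, 0, 0, 1), 3)
  Rz1 %*% Ry %*% Rz2
}

ROTATION_GRID_5DEG <- make_rotation_grid(5)

brute_min_rmsd <- function(mobile, reference, grid = ROTATION_GRID_5DEG) {
  n <- nrow(mobile)
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  H <- t(A) %*% B
  const <- (sum(A^2) + sum(B^2)) / n
  scores <- as.numeric(grid$cols %*% as.numeric(H))
  best <- grid$ang[which.max(scores), ]
  objective <- function(ang) -sum(H * euler_zyz(ang))
  opt <- optim(best, objective, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  msd <- const - 2 * (-opt$value) / n
  sqrt(max(msd, 0))
}

# double-loop residue-ligand minimum distance, the contacts oracle
brute_min_dist <- function(xyz, res_idx, lig_idx) {
  best <- Inf
  for (i in res_idx) for (j in lig_idx) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d < best) best <- d
  }
  best
}

small_params <- function(n_frames = 40, seed = 11, ...) {
  generator_params(n_frames = n_frames, seed = seed, ...)
}
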