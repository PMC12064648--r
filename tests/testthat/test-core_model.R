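test_that("single ATOM record parses into one atom and one residue", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, "CA", "GLY", "A", 333, 1.0, 2.0, 3.0,
                             element = "C"), "END"), path)
  s <- read_pdb(path)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(nrow(s$residues), 1)
  expect_equal(unname(coords(s)[1, ]), c(1.0, 2.0, 3.0))
  expect_equal(s$atoms$resid, 333)
  expect_equal(s$atoms$element, "C")
})

test_that("altloc keeps the highest-occupancy conformer, ties go to A", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 1, 0, 0, occ = 0.6,
                  element = "C", altloc = "A"),
    pdb_atom_line(2, "CA", "GLY", "A", 1, 9, 0, 0, occ = 0.4,
                  element = "C", altloc = "B"),
    pdb_atom_line(3, "CB", "ALA", "A", 2, 0, 5, 0, occ = 0.5,
                  element = "C", altloc = "B"),
    pdb_atom_line(4, "CB", "ALA", "A", 2, 0, 7, 0, occ = 0.5,
                  element = "C", altloc = "A"),
    "END"), path)
  s <- read_pdb(path)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x[1], 1)   # occupancy 0.6 wins
  expect_equal(s$atoms$y[2], 7)   # tie resolved to altloc A
})

test_that("parser agrees with an independent reference parser", {
  skip_if_not_installed("bio3d")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(path)
  s <- read_pdb(path)
  ref <- bio3d::read.pdb(path, verbose = FALSE)
  expect_equal(nrow(s$atoms), nrow(ref$atom))
  expect_equal(nrow(s$residues),
               length(unique(paste(ref$atom$chain, ref$atom$resno))))
  expect_equal(unname(coords(s)[, 1]), ref$atom$x)
  expect_equal(s$atoms$resid, ref$atom$resno)
})

test_that("malformed fixed-width records error with the line number", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, "CA", "GLY", "A", 1, 1, 2, 3,
                             element = "C"),
               "ATOM      2  CA  GLY A   2      bad.000   0.000"),
             path)
  expect_error(read_pdb(path), "line 2")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", empty)
  expect_error(read_pdb(empty), "no ATOM")
  expect_error(read_pdb("/nonexistent/file.pdb"), "not found")
})

test_that("multi-model PDB reads one frame per MODEL block", {
  path <- withr::local_tempfile(fileext = ".pdb")
  blocks <- unlist(lapply(1:3, function(m) {
    c(sprintf("MODEL     %4d", m),
      pdb_atom_line(1, "CA", "GLY", "A", 1, m, 2, 3, element = "C"),
      "ENDMDL")
  }))
  writeLines(c(blocks, "END"), path)
  traj <- read_trajectory(path, "pdb")
  expect_equal(n_frames(traj), 3)
  expect_equal(dim(traj$coords)[1], 1)
  expect_equal(traj$coords[1, 1, ], c(1, 2, 3))
  expect_equal(traj$times, c(0, 1, 2))
})

test_that("frame atom-count mismatch and truncation are reported", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL        1",
               pdb_atom_line(1, "CA", "GLY", "A", 1, 1, 2, 3, element = "C"),
               pdb_atom_line(2, "CA", "GLY", "A", 2, 4, 5, 6, element = "C"),
               "ENDMDL",
               "MODEL        2",
               pdb_atom_line(1, "CA", "GLY", "A", 1, 1, 2, 3, element = "C"),
               "ENDMDL"), path)
  expect_error(read_trajectory(path, "pdb"), "frame 2")
  trunc <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL        1",
               pdb_atom_line(1, "CA", "GLY", "A", 1, 1, 2, 3, element = "C"),
               "ENDMDL",
               "MODEL        2",
               pdb_atom_line(1, "CA", "GLY", "A", 1, 1, 2, 3, element = "C")),
             trunc)
  expect_error(read_trajectory(trunc, "pdb"), "frame 2")
})

test_that("XYZ and PDB trajectories round-trip to format precision", {
  p <- small_params(n_frames = 4)
  res <- simulate_compaction_trajectory(p)
  traj <- res$trajectory

  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, pdb)
  back <- read_trajectory(pdb)
  expect_equal(n_frames(back), 4)
  expect_equal(back$coords, traj$coords, tolerance = 1e-3)
  expect_equal(back$topology$atoms$resid, traj$topology$atoms$resid)

  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(traj, xyz)
  back2 <- read_trajectory(xyz, topology = traj$topology)
  expect_equal(max(abs(back2$coords - traj$coords)), 0, tolerance = 1e-6)
  # the two formats agree on the same frames
  expect_equal(back2$coords, back$coords, tolerance = 1e-3)
})

test_that("nm-unit sources are converted to angstroms on read", {
  p <- small_params(n_frames = 2)
  traj <- simulate_compaction_trajectory(p)$trajectory
  traj$coords <- traj$coords / 10   # pretend the file stores nm
  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(traj, xyz)
  back <- read_trajectory(xyz, topology = traj$topology, units = "nm")
  expect_equal(max(abs(back$coords - traj$coords * 10)), 0,
               tolerance = 1e-5)
})

test_that("radius assignment covers the Bondi table and defaults", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, element = "C"),
    pdb_atom_line(2, "HA", "GLY", "A", 1, 1, 0, 0, element = "H"),
    pdb_atom_line(3, "XX", "UNK", "A", 2, 2, 0, 0, element = "Xx"),
    "END"), path)
  s <- read_pdb(path)
  expect_warning(s <- assign_radii(s), "XX")
  expect_equal(s$atoms$radius, c(1.70, 1.20, 1.50))
  # assignment does not touch coordinates or order
  expect_equal(s$atoms$x, c(0, 1, 2))
})

test_that("element inference falls back to atom-name heuristics", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),       # C-alpha -> C
    pdb_atom_line(2, "1HB", "ALA", "A", 1, 1, 0, 0),      # hydrogen
    pdb_het_line(3, "NA", "NA", "A", 9, 2, 0, 0),         # sodium ion
    "END"), path)
  s <- read_pdb(path)
  expect_equal(s$atoms$element, c("C", "H", "NA"))
})

test_that("selection grammar resolves patch, classes and misses", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(path)
  s <- read_pdb(path)
  sel <- select_atoms(s, "resid 333-335 and heavy")
  expect_equal(sel$indices, 1:6)    # everything except the hydrogen
  expect_equal(select_atoms(s, "all")$indices, 1:7)
  expect_equal(select_atoms(s, "calpha")$indices, c(2, 4, 6))
  expect_equal(select_atoms(s, "resid 334 and name O")$indices, 5L)
  expect_warning(empty <- select_atoms(s, "resid 999"), "no atoms")
  expect_length(empty$indices, 0)
  expect_error(select_atoms(s, "resid 333-335 and wobble"), "wobble")
  # idempotence: re-selecting all of a subset returns the same set
  sub <- s
  sub$atoms <- s$atoms[sel$indices, , drop = FALSE]
  expect_equal(select_atoms(md_structure(sub$atoms), "all")$indices,
               seq_along(sel$indices))
})

test_that("solvent and monoatomic ions are excluded by 'protein'", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, element = "C"),
    pdb_atom_line(2, "O", "HOH", "A", 101, 5, 0, 0, element = "O"),
    pdb_het_line(3, "NA", "NA", "A", 102, 9, 0, 0, element = "NA"),
    "END"), path)
  s <- read_pdb(path)
  expect_equal(select_atoms(s, "protein")$indices, 1L)
  # but the ion stays selectable explicitly as a ligand
  expect_equal(select_atoms(s, "resname NA")$indices, 3L)
})
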