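test_that("superposition recovers identity, translations and rotations", {
  set.seed(42)
  ref <- random_coords(8)

  fit <- kabsch_superpose(ref, ref)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)

  shifted <- sweep(ref, 2, c(1, 2, 3), `+`)
  fit <- kabsch_superpose(shifted, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
  expect_equal(fit$translation, -c(1, 2, 3), tolerance = 1e-8)

  R0 <- random_rotation()
  rotated <- ref %*% R0
  fit <- kabsch_superpose(rotated, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  # mapping back must invert R0
  expect_equal(fit$rotation, t(R0), tolerance = 1e-8)
})

test_that("superposition rejects degenerate configurations", {
  expect_error(kabsch_superpose(matrix(1:6, 2), matrix(1:6, 2)), ">= 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("returned rotations are proper even for reflected inputs", {
  set.seed(7)
  for (i in 1:10) {
    ref <- random_coords(6)
    mirrored <- ref %*% diag(c(-1, 1, 1))
    fit <- kabsch_superpose(mirrored, ref)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    # a reflection cannot be undone by a proper rotation
    expect_gt(fit$rmsd, 0)
  }
})

test_that("RMSD is symmetric, nonnegative and zero iff congruent", {
  set.seed(1)
  a <- random_coords(7)
  b <- a + matrix(rnorm(21, sd = 0.3), ncol = 3)
  expect_equal(kabsch_superpose(a, b)$rmsd, kabsch_superpose(b, a)$rmsd,
               tolerance = 1e-9)
  expect_gt(kabsch_superpose(a, b)$rmsd, 0)
  moved <- sweep(a %*% random_rotation(), 2, rnorm(3), `+`)
  expect_equal(kabsch_superpose(moved, a)$rmsd, 0, tolerance = 1e-8)
})

test_that("rmsd_series is zero for rigid-motion frames and handles the
           two-point closed form", {
  p <- small_params(n_frames = 5)
  chain <- make_bead_chain(p)
  base <- coords(chain)
  set.seed(3)
  frames <- lapply(1:5, function(i) {
    sweep(base %*% random_rotation(), 2, rnorm(3, sd = 5), `+`)
  })
  traj <- md_trajectory(chain, frames)
  rs <- rmsd_series(traj, selection = "all")
  expect_equal(max(abs(rs$values)), 0, tolerance = 1e-8)

  # two atoms with the bond stretched from d to d + delta: rmsd = delta/2
  two <- md_structure(data.frame(
    name = "CA", element = "C", resname = "GLY", resid = 1:2, chain = "A",
    x = c(0, 3), y = 0, z = 0))
  delta <- c(0.4, 1.0)
  frames2 <- lapply(delta, function(d) cbind(c(0, 3 + d), c(0, 0), c(0, 0)))
  traj2 <- md_trajectory(two, frames2)
  rs2 <- rmsd_series(traj2, reference = two, selection = "all")
  expect_equal(rs2$values, delta / 2, tolerance = 1e-10)
})

test_that("rmsd_series validates selection consistency", {
  p <- small_params(n_frames = 3)
  traj <- simulate_compaction_trajectory(p)$trajectory
  smaller <- traj$topology
  smaller$atoms <- smaller$atoms[1:10, , drop = FALSE]
  smaller <- md_structure(smaller$atoms)
  expect_error(rmsd_series(traj, reference = smaller, selection = "all"),
               "reference")
})

test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(matrix(c(4, 5, 6), 1)), 0)
  d <- 3.7
  dumbbell <- cbind(c(0, d), 0, 0)
  expect_equal(radius_of_gyration(dumbbell), d / 2)
  s <- 2.5
  square <- cbind(c(0, s, s, 0), c(0, 0, s, s), 0)
  expect_equal(radius_of_gyration(square), s / sqrt(2))
  # mass weighting with equal masses equals uniform
  set.seed(5)
  pts <- random_coords(9)
  expect_equal(radius_of_gyration(pts, rep(2.5, 9)),
               radius_of_gyration(pts))
})

test_that("Rg and RMSD are invariant under global rigid motion", {
  set.seed(9)
  pts <- random_coords(12)
  R0 <- random_rotation()
  moved <- sweep(pts %*% R0, 2, c(10, -4, 2), `+`)
  expect_equal(radius_of_gyration(moved), radius_of_gyration(pts),
               tolerance = 1e-10)
})

test_that("rg_series recovers generator regimes and rejects empty selections", {
  p <- generator_params(n_frames = 200, seed = 21)
  res <- simulate_compaction_trajectory(p)
  rg <- rg_series(res$trajectory)
  reg <- res$truth$regime
  expect_equal(mean(rg$values[reg == 1]),
               unname(res$truth$realized_rg_mean["first"]),
               tolerance = 1e-6)
  expect_gt(mean(rg$values[reg == 1]), mean(rg$values[reg == 2]))
  expect_error(suppressWarnings(rg_series(res$trajectory, "resid 9999")),
               "empty")
})

test_that("density estimates are normalized and track regimes", {
  set.seed(2)
  x <- rnorm(500)
  d <- probability_density(x)
  expect_true(all(d$density >= 0))
  expect_equal(sum(diff(d$grid) * (head(d$density, -1) +
                                     tail(d$density, -1)) / 2),
               1, tolerance = 0.01)

  # clearly separated two-regime series gives a bimodal density
  y <- c(rnorm(400, 0, 0.5), rnorm(400, 10, 0.5))
  db <- probability_density(y)
  dens <- db$density
  peaks <- which(diff(sign(diff(dens))) == -2) + 1
  modes <- db$grid[peaks[dens[peaks] > max(dens) * 0.2]]
  expect_equal(length(modes), 2)
  expect_equal(sort(modes), c(0, 10), tolerance = 0.5)

  expect_warning(dc <- probability_density(rep(5, 10)), "constant")
  expect_equal(sum(diff(dc$grid) * (head(dc$density, -1) +
                                      tail(dc$density, -1)) / 2),
               1, tolerance = 0.01)

  h <- probability_density(x, method = "histogram", bins = 20)
  expect_equal(sum(diff(h$grid) * (head(h$density, -1) +
                                     tail(h$density, -1)) / 2),
               1, tolerance = 0.01)
})

test_that("series export writes labelled TSV", {
  ts <- md_timeseries(0:4, c(1, 2, 3, 2, 1), "Rg", "A")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_timeseries_tsv(ts, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_named(tab, c("time_ns", "value_A"))
  expect_equal(tab$value_A, c(1, 2, 3, 2, 1))
})
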