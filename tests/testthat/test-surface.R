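test_that("isolated and well-separated atoms match the analytic sphere", {
  r <- 1.70; probe <- 1.40; np <- 960
  a1 <- shrake_rupley_sasa(matrix(0, 1, 3), r, probe, np)
  exact <- 4 * pi * (r + probe)^2
  quantum <- exact / np
  expect_lt(abs(a1 - exact), quantum + 1e-9)

  far <- rbind(c(0, 0, 0), c(100, 0, 0))
  a2 <- shrake_rupley_sasa(far, c(r, r), probe, np)
  expect_equal(unname(a2), rep(a1, 2), tolerance = 1e-12)
})

test_that("two overlapping spheres match the spherical-cap closed form", {
  r <- 1.70; probe <- 1.40; R <- r + probe
  for (d in seq(1.0, 5.8, length.out = 10)) {
    got <- sum(shrake_rupley_sasa(rbind(c(0, 0, 0), c(d, 0, 0)),
                                  c(r, r), probe, 960))
    expect_equal(got, two_sphere_area(r, probe, d),
                 tolerance = 0.02 * two_sphere_area(r, probe, d))
  }
})

test_that("SASA is invariant under rigid motion and missing radii error", {
  set.seed(10)
  xyz <- random_coords(30, spread = 6)
  radii <- runif(30, 1.2, 1.9)
  base <- shrake_rupley_sasa(xyz, radii)
  # translation leaves the quadrature geometry untouched (at most a
  # borderline test point, one quadrature quantum, can flip)
  shifted <- sweep(xyz, 2, c(5, -3, 12), `+`)
  quantum <- 4 * pi * (max(radii) + 1.4)^2 / 960
  expect_lt(max(abs(shrake_rupley_sasa(shifted, radii) - base)),
            quantum + 1e-9)
  # rotation re-samples the spheres; totals agree to quadrature accuracy
  rotated <- xyz %*% random_rotation()
  expect_equal(sum(shrake_rupley_sasa(rotated, radii)), sum(base),
               tolerance = 0.005)
  expect_error(shrake_rupley_sasa(xyz, c(radii[-1], NA)), "radius")
})

test_that("adding a distant atom changes no existing area", {
  set.seed(11)
  xyz <- random_coords(20, spread = 5)
  radii <- rep(1.7, 20)
  base <- shrake_rupley_sasa(xyz, radii)
  xyz2 <- rbind(xyz, c(100, 100, 100))
  ext <- shrake_rupley_sasa(xyz2, c(radii, 1.7))
  expect_equal(ext[1:20], base, tolerance = 1e-12)
})

test_that("occlusion is monotone as a neighbour approaches", {
  r <- 1.7; probe <- 1.4
  ds <- seq(6.0, 1.0, by = -0.5)
  areas <- vapply(ds, function(d) {
    shrake_rupley_sasa(rbind(c(0, 0, 0), c(d, 0, 0)), c(r, r), probe)[1]
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("cell-list neighbour search equals the all-pairs path exactly", {
  set.seed(12)
  for (n in c(5, 60, 200)) {
    xyz <- random_coords(n, spread = n^(1 / 3) * 3)
    radii <- runif(n, 1.1, 2.2)
    expect_identical(
      shrake_rupley_sasa(xyz, radii, method = "cell"),
      shrake_rupley_sasa(xyz, radii, method = "all_pairs"))
  }
})

test_that("patch area decomposes additively and is context-aware", {
  p <- small_params(n_frames = 2)
  chain <- make_bead_chain(p)
  total <- sum(shrake_rupley_sasa(chain))
  all_res <- patch_definition(chain$atoms$resid, label = "all")
  expect_equal(patch_area(chain, all_res), total, tolerance = 1e-9)

  one <- patch_definition(300)
  idx <- which(chain$atoms$resid == 300)
  areas <- shrake_rupley_sasa(chain)
  expect_equal(patch_area(chain, one), sum(areas[idx]), tolerance = 1e-9)

  expect_error(patch_area(chain, patch_definition(c(333, 9999))), "9999")
})

test_that("a patch buried inside a dense cluster loses almost all area", {
  # three probe-sized beads at the origin, caged by a tight shell
  core <- rbind(c(-1.9, 0, 0), c(0, 0, 0), c(1.9, 0, 0))
  shell <- sphere_points(120) * 4.2
  atoms <- data.frame(
    name = "CA", element = "C",
    resname = c(rep("GLY", 3), rep("ALA", 120)),
    resid = c(333, 334, 335, rep(1, 120) + seq_len(120)),
    chain = "A",
    x = c(core[, 1], shell[, 1]), y = c(core[, 2], shell[, 2]),
    z = c(core[, 3], shell[, 3]), radius = 1.7)
  caged <- md_structure(atoms)
  patch <- patch_definition(333:335)
  buried <- patch_area(caged, patch)
  isolated <- patch_area(md_structure(atoms[1:3, ]), patch)
  expect_lt(buried, 0.05 * isolated)
})

test_that("exposure labels follow the >= threshold rule", {
  p <- small_params(n_frames = 12)
  res <- simulate_exposure_trajectory(p, n_sphere_points = 240)
  es <- exposure_series(res$trajectory, threshold = 100,
                        n_sphere_points = 240)
  expect_equal(es$exposed, es$areas >= 100)
  # re-thresholding at an achieved value makes that frame exposed (tie)
  thr <- es$areas[4]
  es2 <- exposure_series(res$trajectory, threshold = thr,
                         n_sphere_points = 240)
  expect_true(es2$exposed[4])
  expect_equal(es2$exposed, es2$areas >= thr)
})

test_that("segment statistics follow the documented split and formulas", {
  mk_series <- function(areas, threshold = 100) {
    structure(list(times = seq_along(areas) - 1, areas = areas,
                   exposed = areas >= threshold, threshold = threshold,
                   patch = patch_definition(), probe_radius = 1.4,
                   n_sphere_points = 960),
              class = "exposure_series")
  }
  const <- mk_series(rep(121, 10))
  st <- segment_stats(const)
  expect_equal(st$mean_area, c(121, 121))
  expect_equal(st$sd_area, c(0, 0))
  expect_equal(st$fraction_exposed, c(1, 1))
  expect_equal(st$frame_start, c(1, 6))
  expect_equal(st$frame_end, c(6, 11))

  # odd frame count: the extra frame goes to the first half
  st11 <- segment_stats(mk_series(rep(50, 11)))
  expect_equal(st11$n_frames, c(6, 5))

  # concatenated constants are recovered exactly, sample SD uses n-1
  two <- mk_series(c(rep(90, 5), rep(130, 5)))
  st2 <- segment_stats(two)
  expect_equal(st2$mean_area, c(90, 130))
  expect_equal(st2$sd_area, c(0, 0))
  expect_equal(st2$fraction_exposed, c(0, 1))
  vals <- c(1, 2, 3, 4)
  st3 <- segment_stats(mk_series(vals, threshold = 2.5),
                       segmentation = list(all = 1:4))
  expect_equal(st3$sd_area, sd(vals))
  expect_equal(st3$fraction_exposed, 0.5)

  expect_error(segment_stats(const, segmentation = list(a = 1:4)),
               "cover")
  expect_error(segment_stats(const, segmentation = list(a = 1:6, b = 5:10)),
               "overlap")
})

test_that("exposure comparison reports per-segment deltas", {
  p <- small_params(n_frames = 10)
  res <- simulate_exposure_trajectory(p, n_sphere_points = 240)
  es <- exposure_series(res$trajectory, n_sphere_points = 240)
  expect_equal(compare_exposure(es, es)$delta_mean, c(0, 0))

  shifted <- es
  shifted$areas <- es$areas - 30
  shifted$exposed <- shifted$areas >= shifted$threshold
  cmp <- compare_exposure(es, shifted)
  expect_equal(cmp$delta_mean, c(30, 30), tolerance = 1e-9)
  expect_equal(cmp$delta_sd, c(0, 0), tolerance = 1e-9)
  expect_true(all(cmp$delta_fraction_exposed >= 0))

  other <- exposure_series(res$trajectory, threshold = 90,
                           n_sphere_points = 240)
  expect_error(compare_exposure(es, other), "settings")
})

test_that("a WT-like generator is more exposed than a buried variant", {
  wt <- simulate_exposure_trajectory(
    generator_params(n_frames = 60, seed = 31), n_sphere_points = 240)
  mut <- simulate_exposure_trajectory(
    generator_params(n_frames = 60, seed = 32,
                     exposure_mean = c(80, 85), exposure_sd = c(15, 10)),
    n_sphere_points = 240)
  es_wt <- exposure_series(wt$trajectory, n_sphere_points = 240)
  es_mut <- exposure_series(mut$trajectory, n_sphere_points = 240)
  cmp <- compare_exposure(es_wt, es_mut)
  expect_true(all(cmp$delta_fraction_exposed > 0))
})
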