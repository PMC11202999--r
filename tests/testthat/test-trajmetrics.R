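random_coords <- function(n, seed) {
  set.seed(seed)
  matrix(runif(n * 3, -1, 1), n, 3)
}

test_that("RMSD of the reference against itself and against a rigid copy is zero", {
  ref <- random_coords(12, 1)
  moved <- apply_rigid_transform(ref)
  ens <- conformation_ensemble(list(ref, moved),
                               masses = runif(12, 1, 16))
  out <- rmsd_series(ens, reference_index = 1)
  expect_equal(out[1], 0, tolerance = 1e-12)
  expect_lt(out[2], 1e-10)
})

test_that("Kabsch RMSD matches a brute-force rigid-transform minimization", {
  # a dyad-plus-outlier toy: three atoms agree rigidly, one is displaced
  ref <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.3, 0.3, 0.5))
  mob <- ref
  mob[4, ] <- mob[4, ] + c(0.2, 0, 0)
  mob <- apply_rigid_transform(mob, angle = 1.1)
  w <- c(12, 12, 12, 16)
  ens <- conformation_ensemble(list(ref, mob), masses = w)
  kabsch <- rmsd_series(ens, 1)[2]
  oracle <- rigid_rmsd_oracle(mob, ref, w)
  expect_equal(kabsch, oracle, tolerance = 1e-4)
  # and on a larger random pair
  ref2 <- random_coords(8, 7)
  mob2 <- apply_rigid_transform(ref2 + matrix(rnorm(24, 0, 0.05), 8, 3))
  w2 <- runif(8, 1, 16)
  ens2 <- conformation_ensemble(list(ref2, mob2), masses = w2)
  expect_equal(rmsd_series(ens2, 1)[2], rigid_rmsd_oracle(mob2, ref2, w2),
               tolerance = 1e-4)
})

test_that("RMSD agrees with the bio3d reference implementation", {
  ref <- random_coords(10, 3)
  mob <- ref + matrix(rnorm(30, 0, 0.1), 10, 3)
  ens <- conformation_ensemble(list(ref, apply_rigid_transform(mob)))
  ours <- rmsd_series(ens, 1)[2]
  theirs <- bio3d::rmsd(as.vector(t(ref)), as.vector(t(apply_rigid_transform(mob))),
                        fit = TRUE)
  # bio3d reports RMSD rounded to 3 decimals
  expect_equal(round(ours, 3), theirs)
})

test_that("a static ensemble has zero fluctuation everywhere", {
  frame <- random_coords(6, 5)
  ens <- conformation_ensemble(list(frame, frame, frame))
  rmsf <- rmsf_per_atom(ens)
  expect_equal(max(rmsf), 0, tolerance = 1e-12)
  expect_equal(attr(rmsf, "average"), 0, tolerance = 1e-12)
})

test_that("a two-state oscillating atom has RMSF equal to its half-amplitude", {
  core <- random_coords(6, 9)
  d <- 0.15
  up <- rbind(core, c(2, 2, 2 + d))
  down <- rbind(core, c(2, 2, 2 - d))
  ens <- conformation_ensemble(list(up, down, up, down))
  rmsf <- rmsf_per_atom(ens, fit_atoms = 1:6)   # the core defines the frame
  expect_equal(rmsf[7], d, tolerance = 1e-9)
  expect_equal(max(rmsf[1:6]), 0, tolerance = 1e-9)
  expect_type(attr(rmsf, "average"), "double")
})

test_that("radius of gyration closed forms hold", {
  expect_equal(radius_of_gyration(matrix(c(3, -1, 2), 1, 3)), 0)
  dimer <- rbind(c(0, 0, 0), c(0.8, 0, 0))
  expect_equal(radius_of_gyration(dimer), 0.4)
  # uniform ball of radius R: Rg -> sqrt(3/5) R
  set.seed(100)
  n <- 60000
  pts <- matrix(rnorm(n * 3), n, 3)
  pts <- pts / sqrt(rowSums(pts^2)) * runif(n)^(1 / 3)
  expect_equal(radius_of_gyration(pts), sqrt(3 / 5), tolerance = 0.02)
})

test_that("single-sphere SASA approaches the closed form", {
  val <- sasa(matrix(0, 1, 3), radii = 0.2, probe_radius = 0.14,
              n_sphere_points = 960)
  expect_equal(as.numeric(val), 4 * pi * 0.34^2, tolerance = 0.01)
})

test_that("coincident atoms expose one sphere and distant atoms expose two", {
  two_same <- matrix(0, 2, 3)
  val <- sasa(two_same, radii = c(0.2, 0.2))
  expect_equal(as.numeric(val), 4 * pi * 0.34^2, tolerance = 0.01)

  apart <- rbind(c(0, 0, 0), c(1, 0, 0))   # separation > 2 * 0.34
  val2 <- sasa(apart, radii = c(0.2, 0.2))
  expect_equal(as.numeric(val2), 2 * 4 * pi * 0.34^2, tolerance = 1e-9)
})

test_that("SASA is non-increasing as a third atom approaches a pair", {
  pair <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  vals <- vapply(seq(2, 0.1, by = -0.1), function(d)
    as.numeric(sasa(rbind(pair, c(0.25, d, 0)), radii = rep(0.2, 3),
                    n_sphere_points = 480)),
    numeric(1))
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("doubling the lattice changes SASA by less than half a percent", {
  frame <- random_coords(8, 13) * 0.3
  a <- as.numeric(sasa(frame, radii = rep(0.17, 8), n_sphere_points = 960))
  b <- as.numeric(sasa(frame, radii = rep(0.17, 8), n_sphere_points = 1920))
  expect_lt(abs(a / b - 1), 0.005)
})

test_that("all four observables are invariant under a global rigid transform", {
  frames <- list(random_coords(9, 21), random_coords(9, 22) * 0.8 +
                   random_coords(9, 21) * 0.2)
  masses <- runif(9, 1, 16)
  radii <- runif(9, 0.12, 0.2)
  ens <- conformation_ensemble(frames, masses = masses, radii = radii)
  moved <- conformation_ensemble(lapply(frames, apply_rigid_transform),
                                 masses = masses, radii = radii)
  expect_equal(rmsd_series(moved, 1), rmsd_series(ens, 1), tolerance = 1e-9)
  expect_equal(as.numeric(rmsf_per_atom(moved)),
               as.numeric(rmsf_per_atom(ens)), tolerance = 1e-9)
  expect_equal(radius_of_gyration(apply_rigid_transform(frames[[1]]), masses),
               radius_of_gyration(frames[[1]], masses), tolerance = 1e-12)
  expect_equal(as.numeric(sasa(apply_rigid_transform(frames[[1]]), radii)),
               as.numeric(sasa(frames[[1]], radii)), tolerance = 1e-6)
})

test_that("multi-MODEL PDB and XYZ trajectories load with element-based masses", {
  pdb_path <- withr::local_tempfile(fileext = ".pdb")
  coords <- list(rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0)),
                 rbind(c(0.1, 0, 0), c(1.6, 0, 0), c(0, 1.4, 0)))
  lines <- character()
  for (m in seq_along(coords)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    for (a in 1:3) {
      el <- c("C", "N", "O")[a]
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        a, el, "DA", 1, coords[[m]][a, 1], coords[[m]][a, 2],
        coords[[m]][a, 3], el))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), pdb_path)
  ens <- read_ensemble_pdb(pdb_path)
  expect_equal(dim(ens$frames), c(2, 3, 3))
  expect_equal(ens$frames[1, 2, 1], 0.15)            # angstrom -> nm
  expect_equal(ens$masses, c(12.011, 14.007, 15.999))

  xyz_path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "frame 1",
               "C 0.0 0.0 0.0", "N 1.5 0.0 0.0", "O 0.0 1.5 0.0",
               "3", "frame 2",
               "C 0.1 0.0 0.0", "N 1.6 0.0 0.0", "O 0.0 1.4 0.0"), xyz_path)
  ens2 <- read_ensemble_xyz(xyz_path)
  expect_equal(ens2$frames, ens$frames, tolerance = 1e-9)
  expect_equal(ens2$masses, ens$masses)
})
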