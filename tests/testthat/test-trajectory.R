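rigid_apply <- function(traj, rot, trans) {
  for (f in seq_len(traj$n_frames)) {
    traj$coords[f, , ] <- sweep(traj$coords[f, , , drop = TRUE] %*% t(rot),
                                2, trans, "+")
  }
  traj
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

test_that("XYZ files round-trip exactly at format precision", {
  traj <- generate_toy_trajectory("harmonic-network",
                                  list(n_atoms = 7, n_frames = 4), seed = 1)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(traj, path)
  back <- read_trajectory(path, "xyz")
  expect_equal(back$coords, traj$coords, tolerance = 1e-5)
  expect_equal(back$n_frames, 4L)
})

test_that("small XYZ fixtures parse to exact values", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "frame 1",
               "C 0.0 0.0 0.0", "O 1.5 0.0 0.0", "N 0.0 2.0 0.0",
               "3", "frame 2",
               "C 0.1 0.0 0.0", "O 1.6 0.0 0.0", "N 0.1 2.0 0.0"), path)
  traj <- read_trajectory(path)
  expect_equal(traj$n_frames, 2L)
  expect_equal(traj$atom_names, c("C", "O", "N"))
  expect_equal(traj$coords[2, 2, ], c(1.6, 0, 0))
  # truncated file errors with location
  writeLines(c("3", "frame 1", "C 0.0 0.0 0.0"), path)
  expect_error(read_trajectory(path), "truncated")
  # atom-count mismatch names the model
  writeLines(c("2", "f", "C 0 0 0", "O 1 0 0",
               "3", "f", "C 0 0 0", "O 1 0 0", "N 2 0 0"), path)
  expect_error(read_trajectory(path), "model 2")
})

test_that("multi-model PDB files load with residue labels", {
  path <- withr::local_tempfile(fileext = ".pdb")
  at <- function(i, nm, res, resno, x, y, z) {
    sprintf("ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            i, nm, res, resno, x, y, z)
  }
  writeLines(c(
    "MODEL        1",
    at(1, "CA", "ALA", 1, 0, 0, 0), at(2, "CA", "GLY", 2, 3.8, 0, 0),
    "ENDMDL", "MODEL        2",
    at(1, "CA", "ALA", 1, 0.5, 0, 0), at(2, "CA", "GLY", 2, 4.3, 0, 0),
    "ENDMDL", "END"), path)
  traj <- read_trajectory(path)
  expect_equal(traj$n_frames, 2L)
  expect_equal(traj$n_atoms, 2L)
  expect_equal(traj$res_ids, c(1L, 2L))
  expect_equal(traj$coords[2, 1, 1], 0.5)
})

test_that("Kabsch superposition undoes rigid motion exactly", {
  set.seed(1)
  ref <- matrix(rnorm(30, sd = 5), ncol = 3)
  expect_equal(superpose(ref, ref)$rmsd, 0, tolerance = 1e-12)
  mob <- sweep(ref %*% t(rot_z(37)), 2, c(5, -3, 11), "+")
  sp <- superpose(mob, ref)
  expect_equal(sp$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_equal(crossprod(sp$rotation), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("superposed RMSD matches the direct formula and bio3d", {
  set.seed(2)
  ref <- matrix(rnorm(60, sd = 5), ncol = 3)
  mob <- ref + matrix(rnorm(60, sd = 0.4), ncol = 3)
  sp <- superpose(mob, ref)
  fitted <- attr(sp, "coords")
  expect_equal(sp$rmsd, naive_rmsd(fitted, ref), tolerance = 1e-10)
  # independent route: bio3d's fitted rmsd on the same pair
  b <- bio3d::rmsd(as.vector(t(ref)), as.vector(t(mob)), fit = TRUE)
  expect_equal(sp$rmsd, b, tolerance = 1e-3)  # bio3d rounds internally
  # one displaced atom, rest identical
  mob2 <- ref; mob2[1, ] <- mob2[1, ] + c(2, 0, 0)
  sp2 <- superpose(mob2, ref)
  expect_equal(sp2$rmsd, naive_rmsd(attr(sp2, "coords"), ref),
               tolerance = 1e-10)
  expect_error(superpose(ref[1:2, ], ref[1:2, ]), "3 selected")
})

test_that("the rotation stays proper for near-reflective inputs", {
  set.seed(3)
  ref <- matrix(rnorm(45, sd = 3), ncol = 3)
  mob <- ref
  mob[, 3] <- -mob[, 3]            # reflection: not reachable by rotation
  sp <- superpose(mob, ref)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_gt(sp$rmsd, 0)
})

test_that("RMSD series vanishes for static and rigid-motion trajectories", {
  base <- matrix(rnorm(36, sd = 4), ncol = 3)
  static <- coordinate_trajectory(
    aperm(array(rep(base, 5), c(nrow(base), 3, 5)), c(3, 1, 2)))
  rs <- rmsd_series(static)
  expect_equal(rs$rmsd, rep(0, 5), tolerance = 1e-12)
  rigid <- generate_toy_trajectory("rigid-motion",
                                   list(n_atoms = 20, n_frames = 30),
                                   seed = 4)
  expect_equal(rmsd_series(rigid)$rmsd, rep(0, 30), tolerance = 1e-8)
})

test_that("RMSD of isotropic jitter matches the analytic expectation", {
  set.seed(5)
  n_at <- 40; sig <- 0.3
  base <- matrix(rnorm(n_at * 3, sd = 8), ncol = 3)
  coords <- array(NA_real_, c(200, n_at, 3))
  for (f in 1:200) coords[f, , ] <- base + matrix(rnorm(n_at * 3, sd = sig),
                                                  ncol = 3)
  traj <- coordinate_trajectory(coords)
  rs <- rmsd_series(traj, reference = base)
  # superposition removes ~6 of the 3N fluctuation degrees of freedom
  expected <- sig * sqrt(3) * sqrt((n_at - 2) / n_at)
  expect_equal(rs$mean, expected, tolerance = 0.1)
})

test_that("DCCM has unit diagonal and detects common motion", {
  traj <- generate_toy_trajectory("harmonic-network",
                                  list(n_atoms = 12, n_frames = 300),
                                  seed = 6)
  cm <- dccm(traj)
  expect_equal(diag(cm$values), rep(1, 12), tolerance = 1e-9)
  expect_true(isSymmetric(cm$values, tol = 1e-12))
  expect_true(all(abs(cm$values) <= 1 + 1e-12))
  # all atoms translated by one common random walk: full correlation
  set.seed(7)
  base <- matrix(rnorm(36, sd = 5), ncol = 3)
  walk <- apply(matrix(rnorm(200 * 3), 200, 3), 2, cumsum)
  coords <- array(NA_real_, c(200, 12, 3))
  for (f in 1:200) coords[f, , ] <- sweep(base, 2, walk[f, ], "+")
  cm2 <- dccm(coordinate_trajectory(coords))
  expect_equal(cm2$values, matrix(1, 12, 12), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("independent fluctuations decorrelate", {
  traj <- generate_toy_trajectory("harmonic-network",
                                  list(n_atoms = 15, n_frames = 2000,
                                       sd = 0.5),
                                  seed = 8)
  cm <- dccm(traj)
  off <- cm$values[upper.tri(cm$values)]
  expect_lt(mean(abs(off)), 0.05)
})

test_that("difference correlation isolates a programmed coupling", {
  pair <- generate_toy_trajectory(
    "paired-coupling",
    list(n_atoms = 10, n_frames = 1500, sd = 0.5, latent_sd = 1.0,
         focus = 3L, partner = 7L), seed = 9)
  ca <- dccm(pair$b)           # coupled system
  cb <- dccm(pair$a)           # decoupled
  dc <- difference_correlation(ca, cb, focus = 3L)
  expect_equal(dc$values[3], 0)                 # both diagonals are 1
  expect_gt(dc$values[7], 0.3)                  # programmed coupling
  others <- dc$values[-c(3, 7)]
  expect_lt(max(abs(others)), 0.25)
  expect_true(all(dc$clamped >= -0.5 & dc$clamped <= 0.5))
  # identical inputs give identically zero
  dc0 <- difference_correlation(ca, ca, focus = 3L)
  expect_equal(dc0$values, rep(0, 10), ignore_attr = TRUE)
  # mismatched indices are reported
  cb_bad <- cb; cb_bad$res_ids <- cb$res_ids + 100L
  expect_error(difference_correlation(ca, cb_bad, 3L), "mismatch")
})

test_that("RDF concentrates at a fixed pair distance and integrates counts", {
  coords <- array(0, c(10, 2, 3))
  coords[, 2, 1] <- 5.0
  traj <- coordinate_trajectory(coords)
  r1 <- rdf(traj, 1L, 2L, r_max = 8, dr = 0.2)
  expect_equal(sum(r1$counts), 10)
  expect_equal(r1$r[which.max(r1$counts)], 5.1, tolerance = 0.11)
  r2 <- rdf(traj, 1L, 2L, r_max = 8, dr = 0.4)
  expect_equal(sum(r2$counts), sum(r1$counts))   # dr does not change mass
  expect_error(rdf(traj, 1L, 2L, r_max = 8, dr = 0), "dr > 0")
  expect_error(rdf(traj, 1L, 1L, r_max = 8, dr = 0.2), "disjoint")
})

test_that("an ideal gas has g(r) = 1 under periodic boundaries", {
  traj <- generate_toy_trajectory("ideal-gas",
                                  list(n_atoms = 200, box = 30,
                                       n_frames = 500), seed = 10)
  r <- rdf(traj, 1:50, 51:200, r_max = 14, dr = 0.5, pbc = TRUE)
  sel <- r$r > 3
  expect_lt(mean(abs(r$g[sel] - 1)), 0.05)
  expect_error(rdf(traj, 1:50, 51:200, r_max = 16, dr = 0.5, pbc = TRUE),
               "half the smallest box")
})

test_that("site distances match the per-frame norm oracle", {
  coords <- array(0, c(5, 2, 3))
  coords[, 2, 2] <- 10
  traj <- coordinate_trajectory(coords)
  d <- site_distance(traj, 1L, 2L)
  expect_equal(d$mean, 10)
  expect_equal(d$sd, 0)
  set.seed(11)
  coords2 <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  traj2 <- coordinate_trajectory(coords2)
  d2 <- site_distance(traj2, 2L, 4L)
  oracle <- vapply(1:5, function(f) {
    sqrt(sum((coords2[f, 2, ] - coords2[f, 4, ])^2))
  }, numeric(1))
  expect_equal(d2$distance, oracle, tolerance = 1e-12)
  # tagged atom shifted +2 A along the separation axis
  trajB <- traj
  trajB$coords[, 2, 2] <- trajB$coords[, 2, 2] + 2
  cmp <- compare_site_distance(traj, trajB, 1L, 2L)
  expect_equal(cmp$mean_difference, 2.0, tolerance = 1e-9)
})

test_that("PCA eigenvalues satisfy the trace identity and mode capture", {
  base <- matrix(rnorm(30, sd = 5), ncol = 3)
  static <- coordinate_trajectory(
    aperm(array(rep(base, 6), c(10, 3, 6)), c(3, 1, 2)))
  p0 <- pca_modes(static)
  expect_equal(p0$eigenvalues, rep(0, 30), tolerance = 1e-12)
  # single-coordinate sinusoidal motion
  coords <- array(rep(base, each = 100), c(100, 10, 3))
  coords[, 1, 1] <- coords[, 1, 1] + 3 * sin(seq(0, 6 * pi, length.out = 100))
  traj <- coordinate_trajectory(coords)
  p1 <- pca_modes(traj)
  expect_gte(p1$variance_fraction[1], 0.999)
  jit <- generate_toy_trajectory("harmonic-network",
                                 list(n_atoms = 8, n_frames = 120), seed = 12)
  p2 <- pca_modes(jit)
  expect_equal(sum(p2$eigenvalues), p2$total_variance, tolerance = 1e-8)
  expect_true(all(diff(p2$eigenvalues) <= 1e-12))
  expect_equal(colMeans(p2$projections), rep(0, ncol(p2$projections)),
               tolerance = 1e-10)
})

test_that("observables are invariant under a global rigid motion", {
  traj <- generate_toy_trajectory("harmonic-network",
                                  list(n_atoms = 10, n_frames = 150),
                                  seed = 13)
  moved <- rigid_apply(traj, rot_z(63), c(7, -2, 4))
  expect_equal(dccm(moved)$values, dccm(traj)$values, tolerance = 1e-6)
  expect_equal(site_distance(moved, 1L, 5L)$distance,
               site_distance(traj, 1L, 5L)$distance, tolerance = 1e-9)
  expect_equal(sort(pca_modes(moved)$eigenvalues, decreasing = TRUE),
               sort(pca_modes(traj)$eigenvalues, decreasing = TRUE),
               tolerance = 1e-6)
  expect_equal(rdf(moved, 1:3, 4:10, r_max = 10, dr = 0.5)$counts,
               rdf(traj, 1:3, 4:10, r_max = 10, dr = 0.5)$counts)
})

test_that("DCCM is invariant under atom reordering", {
  traj <- generate_toy_trajectory("harmonic-network",
                                  list(n_atoms = 8, n_frames = 200),
                                  seed = 14)
  perm <- sample(8)
  permuted <- coordinate_trajectory(traj$coords[, perm, , drop = FALSE],
                                    atom_names = traj$atom_names[perm],
                                    res_ids = traj$res_ids[perm],
                                    res_names = traj$res_names[perm])
  c1 <- dccm(traj)
  c2 <- dccm(permuted)
  m1 <- c1$values[match(c2$res_ids, c1$res_ids), match(c2$res_ids, c1$res_ids)]
  expect_equal(m1, c2$values, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("toy generators enforce their contracts", {
  expect_error(generate_toy_trajectory("no-such-kind"), "unknown")
  g1 <- generate_toy_trajectory("ideal-gas", list(n_atoms = 10, box = 20,
                                                  n_frames = 3), seed = 1)
  expect_equal(dim(g1$coords), c(3, 10, 3))
  expect_true(all(g1$coords >= 0 & g1$coords <= 20))
  g2 <- generate_toy_trajectory("ideal-gas", list(n_atoms = 10, box = 20,
                                                  n_frames = 3), seed = 1)
  expect_identical(g1$coords, g2$coords)
})

test_that("per-residue maps export through the B-factor column", {
  traj <- generate_toy_trajectory("harmonic-network",
                                  list(n_atoms = 5, n_frames = 2), seed = 15)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_bfactor_pdb(traj, c(-0.5, -0.2, 0, 0.2, 0.5), path)
  lines <- readLines(path)
  expect_length(grep("^ATOM", lines), 5L)
  expect_match(lines[1], "-0.50")
  back <- read_trajectory(path)
  expect_equal(back$coords[1, , ], traj$coords[1, , ], tolerance = 1e-3)
})
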