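# Kabsch superposition, mean structures, RMSD and helicity detection.

test_that("superposition recovers exact rigid motions", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)
  sp0 <- superpose(P, P)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-9)
  m <- random_rigid_motion()
  Q <- sweep(P %*% t(m$R), 2, m$t, "+")
  expect_lt(superpose(P, Q)$rmsd, 1e-9)
  # symmetry and optimality against the identity alignment
  for (rep in 1:10) {
    A <- matrix(rnorm(24), 8, 3)
    B <- matrix(rnorm(24), 8, 3)
    sp <- superpose(A, B)
    expect_lt(abs(sp$rmsd - superpose(B, A)$rmsd), 1e-9)
    raw <- sqrt(mean(rowSums((sweep(A, 2, colMeans(A) - colMeans(B)) -
                                B)^2)))
    expect_lte(sp$rmsd, raw + 1e-12)
  }
})

test_that("superposition matches the brute-force rotation-grid oracle", {
  set.seed(7)
  for (rep in 1:10) {
    P <- matrix(rnorm(30), 10, 3)
    Q <- matrix(rnorm(30), 10, 3)
    expect_lt(abs(superpose(P, Q)$rmsd - grid_search_rmsd(P, Q)), 1e-3)
  }
})

test_that("reflections are never used even when they would score better", {
  set.seed(3)
  P <- matrix(rnorm(21), 7, 3)
  Q <- P %*% diag(c(-1, 1, 1))    # mirror image
  sp <- superpose(P, Q)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_gt(sp$rmsd, 0.1)
})

test_that("mean structure of trivial trajectories is exact", {
  d <- make_duplex(20, seed = 1)
  traj1 <- oxdna_trajectory(d$topology, list(d$frame))
  ms1 <- mean_structure(traj1)
  expect_equal(ms1$frame$pos, d$frame$pos, tolerance = 1e-12)
  # rigid-motion copies collapse back to the template (up to global pose)
  set.seed(5)
  frames <- lapply(1:30, function(k) {
    m <- random_rigid_motion()
    move_frame(d$frame, m$R, m$t)
  })
  ms <- mean_structure(oxdna_trajectory(d$topology, frames))
  expect_lt(max(ms$spread), 1e-6)
  sp <- superpose(ms$frame$pos, d$frame$pos)
  expect_lt(sp$rmsd, 1e-6)
  expect_error(mean_structure(oxdna_trajectory(d$topology, list())),
               "empty")
})

test_that("mean structure averages away nucleotide-level noise", {
  d <- make_duplex(20, seed = 2)
  n <- 40L
  sigma <- 0.3
  set.seed(11)
  frames <- lapply(seq_len(200), function(k) {
    m <- random_rigid_motion()
    noisy <- d$frame$pos + matrix(rnorm(3 * n, sd = sigma), n, 3)
    move_frame(oxdna_frame(noisy, d$frame$a1, d$frame$a3,
                           box = d$frame$box), m$R, m$t)
  })
  ms <- mean_structure(oxdna_trajectory(d$topology, frames))
  sp <- superpose(ms$frame$pos, d$frame$pos)
  expect_lt(max(abs(sp$aligned - d$frame$pos)), 3 * sigma / sqrt(200))
  # versors survive re-orthonormalization as a valid frame
  expect_lt(max(abs(rowSums(ms$frame$a1 * ms$frame$a3))), 1e-9)
})

test_that("mean structure is equivariant under rigid motion of all frames", {
  d <- make_duplex(12, seed = 3)
  set.seed(17)
  frames <- lapply(1:20, function(k)
    oxdna_frame(d$frame$pos + matrix(rnorm(72, sd = 0.1), 24, 3),
                d$frame$a1, d$frame$a3, box = d$frame$box))
  traj <- oxdna_trajectory(d$topology, frames)
  ms <- mean_structure(traj)
  m <- random_rigid_motion()
  ms2 <- mean_structure(move_trajectory(traj, m$R, m$t))
  moved <- sweep(ms$frame$pos %*% t(m$R), 2, m$t, "+")
  expect_lt(max(abs(ms2$frame$pos - moved)), 1e-6)
})

test_that("rmsd against references behaves like a metric of displacement", {
  d <- make_duplex(30, seed = 4)
  # collinear axis points: the degenerate case is flagged but still solved
  pts <- d$ground_truth$centerline
  expect_warning(r0 <- rmsd_to_reference(pts, pts), "collinear")
  expect_equal(r0$rmsd, 0, tolerance = 1e-12)
  # rigidly moved reference changes nothing
  m <- random_rigid_motion()
  ref2 <- sweep(pts %*% t(m$R), 2, m$t, "+")
  expect_lt(suppressWarnings(rmsd_to_reference(pts, ref2)$rmsd), 1e-9)
  # isotropic noise: rmsd approximates the noise RMS
  set.seed(23)
  noise <- matrix(rnorm(500 * 3, sd = 0.5), 500, 3)
  big <- matrix(rnorm(500 * 3, sd = 4), 500, 3)
  res <- rmsd_to_reference(big, big + noise)
  expect_lt(abs(res$rmsd - 0.5 * sqrt(3)) / (0.5 * sqrt(3)), 0.1)
  expect_equal(dim(res$displacement), c(500L, 3L))
  expect_error(rmsd_to_reference(pts, pts[1:10, ]), "mapping")
})

test_that("helicity detection reads handedness and period from the path", {
  j <- 0:191
  helix <- cbind(j * 0.34, 0.3 * cos(2 * pi * j / 32),
                 -0.3 * sin(2 * pi * j / 32))   # left-handed about +x
  h <- helix_path_helicity(helix)
  expect_identical(h$handedness, "left")
  expect_lt(abs(h$period - 32), 2)
  mir <- helix %*% diag(c(1, 1, -1))
  hm <- helix_path_helicity(mir)
  expect_identical(hm$handedness, "right")
  expect_lt(abs(hm$period - 32), 2)
  # straight line plus sub-floor noise: no helicity
  set.seed(2)
  straight <- cbind(j * 0.34, rnorm(192, sd = 0.01), rnorm(192, sd = 0.01))
  expect_identical(helix_path_helicity(straight)$handedness, "none")
  expect_error(helix_path_helicity(helix[1:10, ]), "too short")
})

test_that("bundle helices carry the designed helicity", {
  b <- make_bundle(rows = 2, cols = 2, bp_per_helix = 128,
                   junction_spacing = 32, weave_amplitude = 0.6,
                   stagger = 1, seed = 2)
  ax <- helix_axes(b$trajectory, b$helices)
  for (h in seq_along(ax$points)) {
    r <- helix_path_helicity(ax$points[[h]][, , 1])
    expect_identical(r$handedness, "left")
    expect_lt(abs(r$period - 32), 2)
  }
  bm <- make_bundle(rows = 2, cols = 2, bp_per_helix = 128,
                    junction_spacing = 32, weave_amplitude = 0.6,
                    stagger = -1, seed = 2)
  axm <- helix_axes(bm$trajectory, bm$helices)
  rm1 <- helix_path_helicity(axm$points[[1]][, , 1])
  expect_identical(rm1$handedness, "right")
  b0 <- make_bundle(rows = 2, cols = 2, bp_per_helix = 128,
                    weave_amplitude = 0, seed = 2)
  ax0 <- helix_axes(b0$trajectory, b0$helices)
  expect_identical(helix_path_helicity(ax0$points[[1]][, , 1])$handedness,
                   "none")
})
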