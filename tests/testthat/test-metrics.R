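# Helix axes, weave profiles, triangular-wave analysis and corrugation.

test_that("axis points of an ideal duplex reproduce its centerline", {
  d <- make_duplex(24, seed = 2)
  traj <- oxdna_trajectory(d$topology, list(d$frame))
  helices <- list(cbind(1:24, 48:25))
  ax <- helix_axes(traj, helices)
  expect_lt(max(abs(ax$points[[1]][, , 1] - d$ground_truth$centerline)),
            1e-9)
  # masked (frayed) positions propagate as gaps
  mask <- list(c(FALSE, FALSE, rep(TRUE, 22)))
  ax2 <- helix_axes(traj, helices, mask = mask)
  expect_true(all(is.na(ax2$points[[1]][1:2, , 1])))
  expect_false(anyNA(ax2$points[[1]][3:24, , 1]))
  # a pair map missing the terminal pairs produces the same mask
  bp <- base_pair_map(3:24, 48 - (3:24) + 1)
  expect_identical(mask_from_pairs(helices, bp)[[1]],
                   c(FALSE, FALSE, rep(TRUE, 22)))
  # helices with too few valid positions are excluded with a warning
  expect_warning(helix_axes(traj, helices,
                            mask = list(rep(c(TRUE, FALSE), c(3, 21)))),
                 "excluded")
})

test_that("two straight parallel helices give a flat noiseless profile", {
  spec <- generator_spec(helix_spacing = 2.6)
  tile <- make_tile(n_helices = 2, bp_per_helix = 64, weave_amplitude = 0,
                    n_frames = 3, seed = 4, spec = spec)
  ax <- helix_axes(tile$trajectory, tile$helices)
  wp <- weave_profile(ax)
  expect_true(all(abs(wp$mean - 2.6) < 1e-9))
  expect_true(all(wp$sd < 1e-9))
})

test_that("weave profiles are symmetric in pair order and rigid motion", {
  tile <- make_tile(n_helices = 3, bp_per_helix = 64, junction_spacing = 32,
                    weave_amplitude = 1.2, n_frames = 2, noise = 0.1,
                    seed = 6)
  ax <- helix_axes(tile$trajectory, tile$helices)
  ab <- weave_profile(ax, pair_list = cbind(1, 2))
  ba <- weave_profile(ax, pair_list = cbind(2, 1))
  expect_equal(ab$mean, ba$mean)
  expect_equal(ab$sd, ba$sd)
  m <- random_rigid_motion()
  axm <- helix_axes(move_trajectory(tile$trajectory, m$R, m$t),
                    tile$helices)
  wpm <- weave_profile(axm, pair_list = cbind(1, 2))
  expect_lt(max(abs(wpm$mean - ab$mean) / ab$mean), 1e-6)
})

test_that("the triangular tile reproduces its designed weave", {
  tile <- make_tile(n_helices = 6, bp_per_helix = 96, junction_spacing = 32,
                    weave_amplitude = 1.5, seed = 3)
  ax <- helix_axes(tile$trajectory, tile$helices)
  wp <- weave_profile(ax)
  for (J in 2:4) {
    st <- weave_waveform_stats(wp[wp$a == J, ])
    expect_lt(abs(st$amplitude - 1.5), 0.02)
    expect_equal(st$period, 32)
    xov <- tile$crossovers$position[tile$crossovers$pair == J]
    expect_true(all(st$minima %in% xov))
  }
})

test_that("per-index noise statistics match the propagation oracle", {
  tile <- make_tile(n_helices = 3, bp_per_helix = 64, junction_spacing = 32,
                    weave_amplitude = 1.0, noise = 0.2, n_frames = 300,
                    seed = 8)
  ax <- helix_axes(tile$trajectory, tile$helices)
  wp <- weave_profile(ax, pair_list = cbind(1, 2))
  # noise sigma per axis point -> distance sd of sqrt(2) * sigma
  oracle <- sqrt(2) * 0.2
  expect_lt(abs(mean(wp$sd) - oracle) / oracle, 0.1)
  expect_true(all(abs(wp$sd - oracle) / oracle < 0.35))
})

test_that("triangular_theta matches its closed form and inverse", {
  expect_lt(abs(triangular_theta(1.5, 16, 0.34) - 7.85), 0.05)
  expect_equal(triangular_theta(0, 16, 0.34), 0)
  amp <- 2 * (16 * 0.34) * tan(5 * pi / 180)
  expect_equal(triangular_theta(amp, 16, 0.34), 5, tolerance = 1e-9)
  expect_error(triangular_theta(1.5, -2, 0.34), "must be")
})

test_that("waveform statistics detect periods and flag aperiodic input", {
  x <- sin(2 * pi * (0:83) / 21)
  st <- weave_waveform_stats(2.5 + 0.4 * x)
  expect_lt(abs(st$period - 21), 1.5)
  st2 <- weave_waveform_stats(rep(2.5, 64))
  expect_true(st2$aperiodic)
  expect_true(is.na(st2$period))
})

test_that("splay angle round-trips through the weave analysis", {
  # generator splay -> tile amplitude -> measured amplitude -> theta
  for (theta_in in c(2, 7.85, 12)) {
    amp <- 2 * (16 * 0.34) * tan(theta_in * pi / 180)
    tile <- make_tile(n_helices = 4, bp_per_helix = 96,
                      junction_spacing = 32, weave_amplitude = amp,
                      seed = 5)
    ax <- helix_axes(tile$trajectory, tile$helices)
    wp <- weave_profile(ax, pair_list = cbind(2, 3))
    st <- weave_waveform_stats(wp)
    theta_out <- triangular_theta(st$amplitude, st$period / 2, 0.34)
    expect_lt(abs(theta_out - theta_in), 0.3)
  }
})

test_that("a planar tile has zero corrugation everywhere", {
  tile <- make_tile(n_helices = 6, bp_per_helix = 128,
                    junction_spacing = 32, weave_amplitude = 1.5,
                    corrugation_twist = 0, seed = 2)
  ax <- helix_axes(tile$trajectory, tile$helices)
  cp <- corrugation_profile(ax, tile$crossovers, max_offset = 8)
  expect_true(all(abs(cp$mean$angle) < 0.2))
})

test_that("junction twist produces the antisymmetric corrugation profile", {
  for (delta in c(1, 3, 5)) {
    tile <- make_tile(n_helices = 6, bp_per_helix = 128,
                      junction_spacing = 32, weave_amplitude = 1.5,
                      corrugation_twist = 2 * delta, seed = 2)
    ax <- helix_axes(tile$trajectory, tile$helices)
    cp <- corrugation_profile(ax, tile$crossovers, max_offset = 8)
    m <- cp$mean
    # antisymmetric about the junction
    for (o in 1:8) {
      ap <- m$angle[m$offset == o]; am <- m$angle[m$offset == -o]
      expect_lt(abs(ap + am), 0.1)
    }
    # reaching +/- delta at the far offsets
    expect_lt(abs(abs(m$angle[m$offset == 8]) - delta), 0.5)
    expect_lt(abs(abs(m$angle[m$offset == -8]) - delta), 0.5)
    expect_lt(abs(m$angle[m$offset == 0]), 0.1)
  }
})

test_that("corrugation is mirror-antisymmetric and rigid-motion invariant", {
  tile <- make_tile(n_helices = 5, bp_per_helix = 128,
                    junction_spacing = 32, weave_amplitude = 1.5,
                    corrugation_twist = 6, seed = 7)
  ax <- helix_axes(tile$trajectory, tile$helices)
  cp <- corrugation_profile(ax, tile$crossovers, max_offset = 8)
  # mirror image (negate z, the out-of-plane axis): profile negated
  fr <- tile$trajectory$frames[[1]]
  M <- diag(c(1, 1, -1))
  mir <- oxdna_trajectory(tile$topology,
                          list(oxdna_frame(fr$pos %*% M, fr$a1 %*% M,
                                           fr$a3 %*% M, box = fr$box)))
  cpm <- corrugation_profile(helix_axes(mir, tile$helices),
                             tile$crossovers, max_offset = 8)
  expect_lt(max(abs(cpm$mean$angle + cp$mean$angle)), 1e-6)
  # rigid motion: unchanged
  m <- random_rigid_motion()
  cpr <- corrugation_profile(
    helix_axes(move_trajectory(tile$trajectory, m$R, m$t), tile$helices),
    tile$crossovers, max_offset = 8)
  expect_lt(max(abs(cpr$mean$angle - cp$mean$angle)), 1e-6)
})

test_that("the canonical-junction filter drops edge and seam junctions", {
  tile <- make_tile(n_helices = 6, bp_per_helix = 160,
                    junction_spacing = 32, weave_amplitude = 1.5,
                    seam_at = 80, seed = 4)
  expect_true(any(tile$crossovers$seam))
  expect_true(any(tile$crossovers$edge))
  ax <- helix_axes(tile$trajectory, tile$helices)
  cp <- corrugation_profile(ax, tile$crossovers, max_offset = 8)
  used <- unique(cp$curves$junction)
  excluded <- with(tile$crossovers, paste0(pair, "@", position)[!canonical])
  expect_false(any(used %in% excluded))
})
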