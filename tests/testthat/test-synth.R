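# Synthetic generators: determinism, validity of outputs, and
# forward-inverse consistency with the analysis modules.

test_that("identical seeds give byte-identical generator output", {
  a <- make_tile(n_helices = 3, bp_per_helix = 64, noise = 0.2,
                 n_frames = 3, seed = 42)
  b <- make_tile(n_helices = 3, bp_per_helix = 64, noise = 0.2,
                 n_frames = 3, seed = 42)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- make_tile(n_helices = 3, bp_per_helix = 64, noise = 0.2,
                 n_frames = 3, seed = 43)
  expect_false(identical(a$trajectory$frames[[1]]$pos,
                         c$trajectory$frames[[1]]$pos))
  e1 <- make_junction_ensemble(density = list(kind = "gaussian",
                                              phi_mean = 120, phi_sd = 10,
                                              theta_sd = 4),
                               n_samples = 50, seed = 7)
  e2 <- make_junction_ensemble(density = list(kind = "gaussian",
                                              phi_mean = 120, phi_sd = 10,
                                              theta_sd = 4),
                               n_samples = 50, seed = 7)
  expect_identical(serialize(e1, NULL), serialize(e2, NULL))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(make_duplex(8, seed = 3))
  expect_identical(runif(1), before)
})

test_that("every generated topology validates and pairs as designed", {
  gens <- list(
    make_duplex(16, seed = 1),
    make_junction_frame(150, 3, seed = 1),
    make_tile(n_helices = 3, bp_per_helix = 48, junction_spacing = 16,
              seed = 1),
    make_bundle(rows = 2, cols = 2, bp_per_helix = 48,
                junction_spacing = 16, weave_amplitude = 0.4, seed = 1))
  for (g in gens) {
    expect_silent(validate_topology(g$topology))
    fr <- if (!is.null(g$frame)) g$frame else g$trajectory$frames[[1]]
    bp <- detect_base_pairs(fr, g$topology)
    expect_identical(as.data.frame(bp)[c("i", "j")],
                     as.data.frame(g$pairs)[c("i", "j")])
  }
})

test_that("duplex geometry follows rise, pitch and versor conventions", {
  spec <- generator_spec(rise = 0.34, pitch = 10.5)
  d <- make_duplex(22, spec = spec, seed = 5)
  ctr <- d$ground_truth$centerline
  expect_equal(origametry:::vnorm(ctr[22, ] - ctr[1, ]), 21 * 0.34,
               tolerance = 1e-9)
  # a1 rotates by 360/10.5 degrees per bp about the axis
  a1 <- d$frame$a1
  ax <- d$ground_truth$axis
  ang <- sapply(1:21, function(t)
    origametry:::signed_angle_about(a1[t, ], a1[t + 1, ], ax))
  expect_true(all(abs(ang - 360 / 10.5) < 1e-6))
  # versors are unit and orthogonal
  expect_lt(max(abs(rowSums(d$frame$a1^2) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(d$frame$a1 * d$frame$a3))), 1e-9)
})

test_that("junction ensembles hit their target densities", {
  # delta density: every frame measures back the requested angles
  ens <- make_junction_ensemble(density = list(kind = "delta", phi = 180,
                                               theta = 0),
                                n_samples = 5, seed = 3)
  tab <- junction_angle_table(ens$trajectory, ens$junction, isomer = FALSE)
  expect_true(all(abs(tab$phi - 180) < 1))
  expect_true(all(abs(tab$theta) < 0.5))
  # gaussian density: sample means converge as 3 sigma / sqrt(n)
  n <- 4000
  g <- make_junction_ensemble(density = list(kind = "gaussian",
                                             phi_mean = 120, phi_sd = 15,
                                             theta_mean = 0, theta_sd = 5),
                              n_samples = n, seed = 13,
                              build_frames = FALSE)
  expect_lt(abs(mean(g$samples$phi) - 120), 3 * 15 / sqrt(n))
  expect_lt(abs(mean(g$samples$theta)), 3 * 5 / sqrt(n))
})

test_that("windowed draws land between window centre and density mode", {
  wins <- lapply(c(60, 80, 100), function(cc)
    bias_window(cc, 0.05, window_id = cc))
  g <- make_junction_ensemble(density = list(kind = "gaussian",
                                             phi_mean = 120, phi_sd = 15,
                                             theta_sd = 5),
                              windows = wins, n_samples = 3000, seed = 19,
                              build_frames = FALSE)
  for (cc in c(60, 80, 100)) {
    m <- mean(g$samples$phi[g$samples$window_id == cc])
    expect_gt(m, cc - 1)
    expect_lt(m, 120 + 1)
    # exact biased mean: precision-weighted combination
    tau <- 1 / 15^2 + 0.05
    mu <- (120 / 15^2 + 0.05 * cc) / tau
    expect_lt(abs(m - mu), 3 * sqrt(1 / tau) / sqrt(1000))
  }
})

test_that("function densities are sampled by grid inverse transform", {
  dens <- function(phi, theta)
    exp(-((phi - 200)^2 / (2 * 8^2) + (theta - 10)^2 / (2 * 3^2)))
  g <- make_junction_ensemble(density = dens, n_samples = 4000, seed = 23,
                              build_frames = FALSE)
  expect_lt(abs(mean(g$samples$phi) - 200), 1)
  expect_lt(abs(mean(g$samples$theta) - 10), 0.5)
  expect_lt(abs(sd(g$samples$phi) - 8), 0.5)
  bad <- function(phi, theta) rep(-1, length(phi))
  expect_error(make_junction_ensemble(density = bad, n_samples = 10,
                                      build_frames = FALSE),
               "normalizable")
})

test_that("analysis recovers generator parameters across the grid", {
  # weave amplitude and spacing
  for (case in list(c(0.5, 16), c(1.5, 32), c(2.5, 48))) {
    amp <- case[1]; sp <- case[2]
    tile <- make_tile(n_helices = 4, bp_per_helix = 3 * sp,
                      junction_spacing = sp, weave_amplitude = amp,
                      seed = 31)
    ax <- helix_axes(tile$trajectory, tile$helices)
    st <- weave_waveform_stats(weave_profile(ax, pair_list = cbind(2, 3)))
    expect_lt(abs(st$amplitude - amp), 0.02 + 0.02 * amp)
    expect_lt(abs(st$period - sp), 1)
  }
  # corrugation twist
  for (twist in c(2, 10)) {
    tile <- make_tile(n_helices = 5, bp_per_helix = 128,
                      junction_spacing = 32, weave_amplitude = 1,
                      corrugation_twist = twist, seed = 37)
    ax <- helix_axes(tile$trajectory, tile$helices)
    cp <- corrugation_profile(ax, tile$crossovers, max_offset = 8)
    reach <- max(abs(cp$mean$angle))
    expect_lt(abs(reach - twist / 2), 0.3)
  }
  # bundle period
  for (sp in c(16, 32)) {
    b <- make_bundle(rows = 2, cols = 2, bp_per_helix = 4 * sp,
                     junction_spacing = sp, weave_amplitude = 0.6,
                     stagger = 1, seed = 41)
    ax <- helix_axes(b$trajectory, b$helices)
    r <- helix_path_helicity(ax$points[[1]][, , 1],
                             window = max(7, sp %/% 2))
    expect_identical(r$handedness, "left")
    expect_lt(abs(r$period - sp), 2)
  }
})

test_that("tile crossovers alternate groups half a period apart", {
  tile <- make_tile(n_helices = 4, bp_per_helix = 96,
                    junction_spacing = 32, seed = 1)
  xov <- tile$crossovers
  g1 <- sort(xov$position[xov$pair == 1])
  g2 <- sort(xov$position[xov$pair == 2])
  expect_true(all(diff(g1) == 32))
  expect_true(all(diff(g2) == 32))
  expect_true(all(outer(g1, g2, "-") %% 32 == 16))
})
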