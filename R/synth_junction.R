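# Synthetic stacked four-way (Holliday) junction construction. A junction is
# built from a target (phi, theta): two coaxially stacked duplexes, each made
# of two arms that bend away from the junction plane by theta, with duplex 2
# rotated by phi about the inter-duplex axis. Strand routing follows the
# stacked-junction convention: two continuing strands run straight along
# their duplex, two exchanging strands cross between duplexes at the centre.

# Geometry of one junction realizing exactly (phi, theta), both in degrees.
# Returns per-duplex state blocks in the index layout described in
# make_junction_frame().
junction_geometry <- function(phi, theta, arm_bp, spec, phase = 0) {
  n <- arm_bp
  chat <- c(1, 0, 0)                      # duplex 1 -> duplex 2
  u1 <- c(0, 1, 0)                        # duplex 1 axis (continuing strand 1)
  u2 <- as.numeric(rotation_about(chat, phi) %*% u1)
  if (abs(abs(theta) - 90) < 1e-6)
    stop("theta = +/-90 degrees is degenerate (arms along the stack axis)")
  ct <- cos(deg2rad(theta)); st <- sin(deg2rad(theta))
  arms <- list(
    list(duplex = 1, w = ct * (-u1) + st * (-chat)),   # arm 1: duplex 1, "in"
    list(duplex = 1, w = ct * u1 + st * (-chat)),      # arm 2: duplex 1, "out"
    list(duplex = 2, w = ct * (-u2) + st * chat),      # arm 3: duplex 2, "in"
    list(duplex = 2, w = ct * u2 + st * chat))         # arm 4: duplex 2, "out"
  p <- list(-(spec$junction_gap / 2) * chat, (spec$junction_gap / 2) * chat)
  blocks <- vector("list", 2)
  for (d in 1:2) {
    wL <- arms[[2 * d - 1]]$w; wR <- arms[[2 * d]]$w
    tt <- seq_len(2 * n)
    along <- ifelse(tt <= n, n - tt + 0.5, tt - n - 0.5) * spec$rise
    wmat <- matrix(0, 2 * n, 3)
    wmat[tt <= n, ] <- matrix(wL, sum(tt <= n), 3, byrow = TRUE)
    wmat[tt > n, ] <- matrix(wR, sum(tt > n), 3, byrow = TRUE)
    centers <- outer(rep(1, 2 * n), p[[d]]) + along * wmat
    tangents <- matrix(0, 2 * n, 3)
    tangents[tt <= n, ] <- matrix(-wL, sum(tt <= n), 3, byrow = TRUE)
    tangents[tt > n, ] <- matrix(wR, sum(tt > n), 3, byrow = TRUE)
    e1L <- unitv(cross3(wL, chat)); e1R <- unitv(cross3(wR, chat))
    e1 <- matrix(0, 2 * n, 3)
    e1[tt <= n, ] <- matrix(e1L, sum(tt <= n), 3, byrow = TRUE)
    e1[tt > n, ] <- matrix(e1R, sum(tt > n), 3, byrow = TRUE)
    e2 <- t(vapply(seq_len(2 * n),
                   function(k) cross3(tangents[k, ], e1[k, ]),
                   numeric(3)))
    alpha <- phase + 2 * pi * (tt - 1) / spec$pitch
    blocks[[d]] <- duplex_states(centers, tangents, e1, e2, alpha,
                                 spec$position_radius)
  }
  blocks
}

# Topology for the four-strand stacked junction given the two continuing
# strands' sequences (each 2 * arm_bp long). Index layout: duplex 1 strand A
# = 1..2n, duplex 1 strand B = 2n+1..4n (in base-pair order), duplex 2
# strand A = 4n+1..6n, duplex 2 strand B = 6n+1..8n.
junction_topology <- function(seq1A, seq2A) {
  n <- length(seq1A) / 2
  stopifnot(n == floor(n), length(seq2A) == 2 * n)
  base <- c(seq1A, dna_complement(seq1A), seq2A, dna_complement(seq2A))
  N <- 8 * n
  strand <- integer(N)
  strand[1:(2 * n)] <- 1L
  strand[(4 * n + 1):(6 * n)] <- 2L
  strand[2 * n + c((n + 1):(2 * n))] <- 3L   # d1B outer half (R arm)
  strand[6 * n + c(1:n)] <- 3L               # d2B inner half (L arm)
  strand[6 * n + c((n + 1):(2 * n))] <- 4L   # d2B outer half (R arm)
  strand[2 * n + c(1:n)] <- 4L               # d1B inner half (L arm)
  paths <- list(
    1:(2 * n),
    (4 * n + 1):(6 * n),
    c(2 * n + ((2 * n):(n + 1)), 6 * n + (n:1)),
    c(6 * n + ((2 * n):(n + 1)), 2 * n + (n:1)))
  n3 <- rep(NA_integer_, N); n5 <- rep(NA_integer_, N)
  for (p in paths) {
    k <- seq_len(length(p) - 1)
    n3[p[k]] <- p[k + 1]
    n5[p[k + 1]] <- p[k]
  }
  oxdna_topology(strand, base, n3, n5)
}

#' Construct a single ideal stacked-junction configuration
#'
#' Builds a four-way junction that realizes exactly the requested twist
#' `phi` and splay `theta`: four `arm_bp`-long ideal arms, arms 1-2 stacked
#' into duplex 1 and arms 3-4 into duplex 2, duplex 2 rotated by `phi`
#' about the inter-duplex axis (so `phi = 0` is a parallel and
#' `phi = 180` an anti-parallel junction), and every arm tilted `theta`
#' degrees away from the junction plane (positive = duplexes splaying
#' apart).
#'
#' @param phi junction twist in degrees, taken modulo 360.
#' @param theta junction splay in degrees, in (-90, 90).
#' @param arm_bp base pairs per arm.
#' @param spec a [generator_spec()].
#' @param seed RNG seed for the (non-repetitive) sequences.
#' @param phase twist phase of the first base pair, radians.
#' @return A list with `topology`, `frame`, `junction` (a
#'   [junction_spec()]), `pairs` and `ground_truth`.
#' @export
make_junction_frame <- function(phi, theta, arm_bp = 16,
                                spec = generator_spec(), seed = 1,
                                phase = 0) {
  n <- arm_bp
  seqs <- with_seed(seed, list(random_sequence(2 * n), random_sequence(2 * n)))
  topo <- junction_topology(seqs[[1]], seqs[[2]])
  blocks <- junction_geometry(phi, theta, n, spec, phase)
  frame <- junction_frame_from_blocks(blocks, n, spec)
  jspec <- junction_spec_for_generator(n)
  tt <- seq_len(2 * n)
  pairs <- base_pair_map(c(tt, 4 * n + tt), c(2 * n + tt, 6 * n + tt),
                         "design-derived")
  list(topology = topo, frame = frame, junction = jspec, pairs = pairs,
       ground_truth = list(kind = "junction", phi = phi %% 360,
                           theta = theta, arm_bp = n, seed = seed,
                           spec = spec))
}

junction_frame_from_blocks <- function(blocks, n, spec) {
  pos <- rbind(blocks[[1]]$posA, blocks[[1]]$posB,
               blocks[[2]]$posA, blocks[[2]]$posB)
  a1 <- rbind(blocks[[1]]$a1A, blocks[[1]]$a1B,
              blocks[[2]]$a1A, blocks[[2]]$a1B)
  a3 <- rbind(blocks[[1]]$a3A, blocks[[1]]$a3B,
              blocks[[2]]$a3A, blocks[[2]]$a3B)
  box <- rep(2 * (2 * n * spec$rise + spec$junction_gap) + 20, 3)
  oxdna_frame(pos, a1, a3, box = box)
}

# The junction_spec matching the generator's fixed index layout.
junction_spec_for_generator <- function(n) {
  arm_pairs <- function(offA, offB, tset)
    cbind(offA + tset, offB + tset)
  junction_spec(
    arms = list(
      list(duplex = 1, pairs = arm_pairs(0, 2 * n, n:1)),
      list(duplex = 1, pairs = arm_pairs(0, 2 * n, (n + 1):(2 * n))),
      list(duplex = 2, pairs = arm_pairs(4 * n, 6 * n, n:1)),
      list(duplex = 2, pairs = arm_pairs(4 * n, 6 * n, (n + 1):(2 * n)))),
    continuing = c(1L, 2L),
    exchanging = c(3L, 4L),
    midpoints = c(3 * n, 3 * n + 1, 7 * n, 7 * n + 1))
}

# Draw (phi, theta) samples from a density specification, optionally
# reweighted by a harmonic phi window. Gaussian densities with harmonic
# biases are sampled exactly (product of Gaussians); function densities are
# sampled by inverse transform on a fine grid.
sample_junction_angles <- function(density, n, window = NULL) {
  if (is.function(density)) {
    dphi <- seq(0.25, 359.75, by = 0.5)
    dtheta <- seq(-89.75, 89.75, by = 0.5)
    grid <- expand.grid(phi = dphi, theta = dtheta)
    w <- density(grid$phi, grid$theta)
    if (any(!is.finite(w)) || any(w < 0) || sum(w) <= 0)
      stop("density is not normalizable on the angle domain")
    if (!is.null(window))
      w <- w * exp(-bias_energy(grid$phi, window))
    k <- sample.int(nrow(grid), n, replace = TRUE, prob = w)
    return(data.frame(phi = (grid$phi[k] + stats::runif(n, -0.25, 0.25)) %% 360,
                      theta = grid$theta[k] + stats::runif(n, -0.25, 0.25)))
  }
  kind <- density$kind
  if (kind == "delta") {
    return(data.frame(phi = rep(density$phi %% 360, n),
                      theta = rep(density$theta, n)))
  }
  if (kind == "gaussian") {
    pm <- density$phi_mean; ps <- density$phi_sd
    tm <- if (is.null(density$theta_mean)) 0 else density$theta_mean
    ts <- density$theta_sd
    if (!is.null(window) && window$stiffness > 0) {
      tau <- 1 / ps^2 + window$stiffness
      # nearest circular image of the window centre to the density mean
      cc <- pm + circ_diff(window$center, pm)
      mu <- (pm / ps^2 + window$stiffness * cc) / tau
      pm <- mu; ps <- sqrt(1 / tau)
    }
    return(data.frame(phi = stats::rnorm(n, pm, ps) %% 360,
                      theta = stats::rnorm(n, tm, ts)))
  }
  stop("unknown density kind: ", kind)
}

#' Generate a stacked-junction ensemble from a stated angle density
#'
#' Draws `(phi, theta)` samples from `density` (reweighted by each harmonic
#' window's bias when `windows` are given, with samples split evenly across
#' windows) and constructs, for each sample, a stacked-junction
#' configuration realizing exactly those angles. The drawn angles are the
#' ground truth against which the angle analyses can be validated.
#'
#' @param arm_bp base pairs per arm (the reference junction has 16).
#' @param density either `list(kind = "delta", phi=, theta=)`,
#'   `list(kind = "gaussian", phi_mean=, phi_sd=, theta_mean=, theta_sd=)`,
#'   or a vectorized `function(phi, theta)` returning an unnormalized
#'   density on `[0, 360) x [-90, 90]`.
#' @param windows optional list of [bias_window()]s.
#' @param n_samples total number of samples (split across windows).
#' @param seed RNG seed; identical seeds give identical output.
#' @param spec a [generator_spec()].
#' @param build_frames if `FALSE`, skip the (possibly large) geometric
#'   construction and return only the sampled angles.
#' @return A list with `topology`, `trajectory` (`NULL` when
#'   `build_frames = FALSE`), `samples` (data frame of phi, theta,
#'   window_id, frame_index), `junction`, `pairs`, `windows` and
#'   `ground_truth`.
#' @export
make_junction_ensemble <- function(arm_bp = 16, density, windows = NULL,
                                   n_samples = 100, seed = 1,
                                   spec = generator_spec(),
                                   build_frames = TRUE) {
  stopifnot(n_samples >= 1)
  samples <- with_seed(seed, {
    if (is.null(windows)) {
      s <- sample_junction_angles(density, n_samples)
      s$window_id <- NA_integer_
      s
    } else {
      nw <- length(windows)
      per <- diff(floor(seq(0, n_samples, length.out = nw + 1)))
      do.call(rbind, lapply(seq_len(nw), function(w) {
        s <- sample_junction_angles(density, per[w], windows[[w]])
        s$window_id <- if (is.null(windows[[w]]$window_id)) w
                       else windows[[w]]$window_id
        s
      }))
    }
  })
  samples$frame_index <- seq_len(nrow(samples))
  n <- arm_bp
  seqs <- with_seed(seed + 1L,
                    list(random_sequence(2 * n), random_sequence(2 * n)))
  topo <- junction_topology(seqs[[1]], seqs[[2]])
  jspec <- junction_spec_for_generator(n)
  tt <- seq_len(2 * n)
  pairs <- base_pair_map(c(tt, 4 * n + tt), c(2 * n + tt, 6 * n + tt),
                         "design-derived")
  traj <- NULL
  if (build_frames) {
    frames <- lapply(seq_len(nrow(samples)), function(k) {
      blocks <- junction_geometry(samples$phi[k], samples$theta[k], n, spec)
      fr <- junction_frame_from_blocks(blocks, n, spec)
      fr$time <- k
      fr
    })
    traj <- oxdna_trajectory(topo, frames)
  }
  list(topology = topo, trajectory = traj, samples = samples,
       junction = jspec, pairs = pairs, windows = windows,
       ground_truth = list(kind = "junction_ensemble", angles = samples,
                           arm_bp = n, seed = seed, spec = spec))
}
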