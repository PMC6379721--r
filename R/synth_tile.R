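# Synthetic origami sheets and square-lattice bundles. A tile is a set of
# parallel helices whose centerlines carry the triangular "weave" (in-plane
# splay between crossovers), an optional out-of-plane corrugation (junction
# twist), and optional iid Gaussian thermal noise applied at the base-pair
# level. Crossover positions alternate between the two symmetry groups of
# helix pairs, offset by half a junction spacing.

# Periodic helpers, period 1: tri01 is 0 at 0 and 1 at 1/2 (weave tent);
# triz is 0 at 0 and 1/2 with extrema +/-1 at 1/4 and 3/4 (corrugation).
tri01 <- function(x) 1 - 2 * abs(x - floor(x) - 0.5)
triz <- function(x) {
  s <- x - 0.25
  s <- s - round(s)
  1 - 4 * abs(s)
}

# Strand layout shared by the multi-helix generators: helix h occupies
# indices (h-1)*2*bp + (1..2*bp); strand A is 1..bp (5'->3' along +x),
# strand B is bp+1..2*bp, so bp j of helix h pairs (off + j, off + 2*bp + 1 - j).
multi_helix_topology <- function(n_helices, bp) {
  seqs <- lapply(seq_len(n_helices), function(h) random_sequence(bp))
  base <- strand <- c()
  n3 <- n5 <- c()
  for (h in seq_len(n_helices)) {
    off <- (h - 1L) * 2L * bp
    base <- c(base, seqs[[h]], rev(dna_complement(seqs[[h]])))
    strand <- c(strand, rep(c(2L * h - 1L, 2L * h), each = bp))
    n3 <- c(n3, off + c(2:bp, NA), off + c((bp + 2):(2 * bp), NA))
    n5 <- c(n5, off + c(NA, 1:(bp - 1)), off + c(NA, (bp + 1):(2 * bp - 1)))
  }
  oxdna_topology(strand, base, n3, n5)
}

multi_helix_pairs <- function(n_helices, bp) {
  i <- j <- integer(0)
  for (h in seq_len(n_helices)) {
    off <- (h - 1L) * 2L * bp
    i <- c(i, off + seq_len(bp))
    j <- c(j, off + 2L * bp + 1L - seq_len(bp))
  }
  base_pair_map(i, j, "design-derived")
}

# Frames from per-helix centerlines (list of bp x 3 matrices) plus optional
# per-base-pair Gaussian noise (same displacement for both nucleotides of a
# pair, so the noise acts on the helix-axis points).
multi_helix_frames <- function(centerlines, spec, noise, n_frames, time0 = 1) {
  n_helices <- length(centerlines)
  bp <- nrow(centerlines[[1]])
  alpha <- 2 * pi * (seq_len(bp) - 1) / spec$pitch
  e1 <- matrix(rep(c(0, 1, 0), each = bp), bp, 3)
  e2 <- matrix(rep(c(0, 0, 1), each = bp), bp, 3)
  tangent <- matrix(rep(c(1, 0, 0), each = bp), bp, 3)
  span <- range(unlist(lapply(centerlines, function(m) m)))
  box <- rep(diff(span) + 2 * bp * spec$rise + 20, 3)
  lapply(seq_len(n_frames), function(f) {
    pos <- a1 <- a3 <- matrix(0, n_helices * 2 * bp, 3)
    for (h in seq_len(n_helices)) {
      ctr <- centerlines[[h]]
      if (noise > 0)
        ctr <- ctr + matrix(stats::rnorm(bp * 3, sd = noise), bp, 3)
      st <- duplex_states(ctr, tangent, e1, e2, alpha, spec$position_radius)
      off <- (h - 1L) * 2L * bp
      pos[off + 1:bp, ] <- st$posA
      pos[off + bp + 1:bp, ] <- st$posB[bp:1, , drop = FALSE]
      a1[off + 1:bp, ] <- st$a1A
      a1[off + bp + 1:bp, ] <- st$a1B[bp:1, , drop = FALSE]
      a3[off + 1:bp, ] <- st$a3A
      a3[off + bp + 1:bp, ] <- st$a3B[bp:1, , drop = FALSE]
    }
    oxdna_frame(pos, a1, a3, box = box, time = time0 + f - 1)
  })
}

# Per-helix base-pair index matrices (the registration between helices).
multi_helix_assignment <- function(n_helices, bp) {
  lapply(seq_len(n_helices), function(h) {
    off <- (h - 1L) * 2L * bp
    cbind(off + seq_len(bp), off + 2L * bp + 1L - seq_len(bp))
  })
}

#' Generate a 2D origami tile with weave and corrugation
#'
#' Parallel helices along x, spaced `helix_spacing` apart in y. Adjacent
#' helix pairs fall into two alternating symmetry groups whose crossovers
#' are offset by half a `junction_spacing`; between crossovers the
#' inter-helix distance follows a triangular wave of peak-to-peak
#' `weave_amplitude` with minima exactly at the crossovers. A nonzero
#' `corrugation_twist` (the full twist 2*delta across a junction) rotates
#' the inter-helix vectors out of plane by +/- `corrugation_twist / 2`,
#' antisymmetrically about every junction and passing through zero at the
#' midpoints between same-pair junctions. Optional `seam_at` removes, for
#' one group, the crossover nearest that index, doubling the junction-free
#' span there. Gaussian noise of sd `noise` nm is applied per base pair
#' (both nucleotides of a pair move together) independently per frame.
#'
#' @param n_helices number of helices (>= 2).
#' @param bp_per_helix base pairs per helix (ideally a multiple of
#'   `junction_spacing`).
#' @param junction_spacing base pairs between consecutive junctions of one
#'   helix pair (the weave period); must be even and >= 4.
#' @param weave_amplitude max - min inter-helix distance, nm.
#' @param corrugation_twist full junction twist 2*delta, degrees.
#' @param seam_at optional bp index around which one group's crossover is
#'   removed (a scaffold-seam-like opening).
#' @param noise per-base-pair Gaussian positional noise sd, nm.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param spec a [generator_spec()].
#' @return A list with `topology`, `trajectory`, `pairs`, `helices`
#'   (per-helix bp-index matrices, the registration), `crossovers` (data
#'   frame with pair, position, group, seam, edge, canonical) and
#'   `ground_truth`.
#' @export
make_tile <- function(n_helices = 6, bp_per_helix = 96, junction_spacing = 32,
                      weave_amplitude = 1.5, corrugation_twist = 0,
                      seam_at = NULL, noise = 0, n_frames = 1, seed = 1,
                      spec = generator_spec()) {
  stopifnot(n_helices >= 2, junction_spacing >= 4,
            junction_spacing %% 2 == 0, bp_per_helix >= junction_spacing)
  P <- junction_spacing
  bp <- bp_per_helix
  s <- spec$helix_spacing
  j0 <- seq_len(bp) - 1
  npair <- n_helices - 1L
  # crossover table: group 1 (odd pairs) at phase P/2, group 2 at phase 0
  xov <- do.call(rbind, lapply(seq_len(npair), function(J) {
    phase <- if (J %% 2 == 1) P / 2 else P
    pos <- seq(phase, bp - 1, by = P)
    pos <- pos[pos >= 1 & pos <= bp - 2]
    data.frame(pair = J, position = pos + 1L,   # 1-based bp index
               group = if (J %% 2 == 1) 1L else 2L)
  }))
  xov$seam <- FALSE
  seam_group <- 1L
  if (!is.null(seam_at)) {
    for (J in which(seq_len(npair) %% 2 == (seam_group %% 2))) {
      rows <- which(xov$pair == J)
      drop <- rows[which.min(abs(xov$position[rows] - seam_at))]
      xov$seam[xov$pair == J &
                 abs(xov$position - xov$position[drop]) <= P] <- TRUE
      xov <- xov[-drop, ]
    }
  }
  xov$edge <- xov$pair == 1L | xov$pair == npair |
    xov$position <= P / 2 | xov$position >= bp - P / 2
  xov$canonical <- !xov$edge & !xov$seam
  # per-pair gap profiles
  gap_dev <- function(J) {
    pos0 <- xov$position[xov$pair == J] - 1L
    if (is.null(seam_at) || length(pos0) == 0 ||
        all(diff(sort(c(-P / 2, pos0, bp - 1 + P / 2))) <= P + 0.5)) {
      sgn <- if (J %% 2 == 1) -1 else 1
      return(sgn * (weave_amplitude / 2) * (2 * tri01(j0 / P) - 1))
    }
    # tent over the surviving crossovers (seam region opens wider)
    d <- vapply(j0, function(x) min(abs(x - pos0)), numeric(1))
    -weave_amplitude / 2 + d * (2 * weave_amplitude / (2 * P)) * 2
  }
  delta_h <- deg2rad(corrugation_twist) / 2
  gamma <- function(J) ((-1)^J) * delta_h * triz(j0 / P)
  centerlines <- vector("list", n_helices)
  y <- rep(0, bp); z <- rep(0, bp)
  centerlines[[1]] <- cbind(j0 * spec$rise, y, z)
  for (J in seq_len(npair)) {
    y <- y + s + gap_dev(J)
    z <- z + s * gamma(J)
    centerlines[[J + 1]] <- cbind(j0 * spec$rise, y, z)
  }
  centerlines <- lapply(centerlines, unname)
  out <- with_seed(seed, {
    topo <- multi_helix_topology(n_helices, bp)
    frames <- multi_helix_frames(centerlines, spec, noise, n_frames)
    list(topo = topo, frames = frames)
  })
  list(topology = out$topo,
       trajectory = oxdna_trajectory(out$topo, out$frames),
       pairs = multi_helix_pairs(n_helices, bp),
       helices = multi_helix_assignment(n_helices, bp),
       crossovers = xov,
       ground_truth = list(kind = "tile", centerlines = centerlines,
                           weave_amplitude = weave_amplitude,
                           junction_spacing = P,
                           corrugation_twist = corrugation_twist,
                           seam_at = seam_at, noise = noise, seed = seed,
                           spec = spec))
}

#' Generate a square-lattice 3D bundle with helical centerline residuals
#'
#' Helices on a `rows` x `cols` square lattice, each drawn toward its four
#' neighbours in turn at junction positions staggered by a quarter of
#' `junction_spacing`, so the centerline residual winds once around the
#' lattice axis every `junction_spacing` base pairs. `stagger = +1` gives a
#' left-handed path, `-1` right-handed; `weave_amplitude` is the
#' peak-to-peak residual (the winding radius is half of it).
#'
#' @param rows,cols lattice dimensions (>= 2 for interior-like behaviour).
#' @param bp_per_helix base pairs per helix.
#' @param junction_spacing base pairs per full turn of the residual.
#' @param weave_amplitude peak-to-peak centerline residual, nm.
#' @param stagger `+1` (left-handed) or `-1` (right-handed).
#' @param noise per-base-pair Gaussian noise sd, nm.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param spec a [generator_spec()].
#' @return As [make_tile()], without a crossover table; `ground_truth`
#'   records the centerlines, handedness and period.
#' @export
make_bundle <- function(rows = 3, cols = 3, bp_per_helix = 96,
                        junction_spacing = 32, weave_amplitude = 0.6,
                        stagger = 1, noise = 0, n_frames = 1, seed = 1,
                        spec = generator_spec()) {
  stopifnot(rows >= 1, cols >= 1, stagger %in% c(-1, 1))
  P <- junction_spacing
  bp <- bp_per_helix
  j0 <- seq_len(bp) - 1
  rho <- weave_amplitude / 2
  th <- 2 * pi * j0 / P
  centerlines <- list()
  for (r in seq_len(rows)) for (cc in seq_len(cols)) {
    centerlines[[length(centerlines) + 1]] <-
      cbind(j0 * spec$rise,
            (cc - 1) * spec$helix_spacing + rho * cos(th),
            (r - 1) * spec$helix_spacing - stagger * rho * sin(th))
  }
  centerlines <- lapply(centerlines, unname)
  n_helices <- rows * cols
  out <- with_seed(seed, {
    topo <- multi_helix_topology(n_helices, bp)
    frames <- multi_helix_frames(centerlines, spec, noise, n_frames)
    list(topo = topo, frames = frames)
  })
  list(topology = out$topo,
       trajectory = oxdna_trajectory(out$topo, out$frames),
       pairs = multi_helix_pairs(n_helices, bp),
       helices = multi_helix_assignment(n_helices, bp),
       ground_truth = list(kind = "bundle", centerlines = centerlines,
                           rows = rows, cols = cols,
                           handedness = if (weave_amplitude == 0) "none"
                                        else if (stagger > 0) "left"
                                        else "right",
                           period = P, radius = rho, noise = noise,
                           seed = seed, spec = spec))
}
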