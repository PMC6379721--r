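# Synthetic configuration/trajectory generators. These replace a
# molecular-dynamics engine for testing: every generator constructs geometry
# from known parameters and returns that ground truth alongside the
# configurations, so analyses can be validated by round trip.

#' Geometry parameters for the synthetic generators
#'
#' Defaults follow the untwisted-origami B-DNA convention: rise 0.34 nm/bp,
#' pitch 10.5 bp/turn, backbone sites on a 0.6 nm radius. The nucleotide
#' position sits between backbone and base sites, so its radius is
#' `backbone_radius - base_site_offset`.
#'
#' @param rise helical rise, nm per base pair.
#' @param pitch helical pitch, base pairs per turn.
#' @param backbone_radius radius of the backbone sites, nm.
#' @param base_site_offset distance from nucleotide position to the base
#'   interaction site along a1, nm.
#' @param helix_spacing centre-to-centre inter-helix lattice spacing, nm.
#' @param junction_gap centre-to-centre distance between the two stacked
#'   duplexes of a four-way junction, nm.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(rise = 0.34, pitch = 10.5, backbone_radius = 0.6,
                           base_site_offset = 0.4 * oxdna_length_unit,
                           helix_spacing = 2.5, junction_gap = 2.0) {
  stopifnot(rise > 0, pitch > 0, backbone_radius > base_site_offset,
            helix_spacing > 0, junction_gap > 0)
  structure(list(rise = rise, pitch = pitch,
                 backbone_radius = backbone_radius,
                 base_site_offset = base_site_offset,
                 position_radius = backbone_radius - base_site_offset,
                 helix_spacing = helix_spacing,
                 junction_gap = junction_gap),
            class = "generator_spec")
}

# Run code with a private, seeded RNG stream, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

dna_complement <- function(bases) {
  unname(c(A = "T", T = "A", C = "G", G = "C")[bases])
}

# A non-repetitive random sequence (no immediate repeats of the previous
# base), mimicking sequence choices that prevent branch migration.
random_sequence <- function(n) {
  bases <- c("A", "C", "G", "T")
  out <- character(n)
  out[1] <- sample(bases, 1)
  for (k in seq_len(n)[-1]) out[k] <- sample(setdiff(bases, out[k - 1]), 1)
  out
}

# Build nucleotide states for both strands of a duplex given per-base-pair
# axis centres, tangents (strand-A 5'->3' direction), an orthonormal frame
# (e1, e2) perpendicular to the tangent, and twist angles alpha (radians).
# Strand A sits at +radius along u(alpha), strand B diametrically opposite;
# a1 points across the axis toward the partner, a3 along +/- tangent.
duplex_states <- function(centers, tangents, e1, e2, alpha, radius) {
  u <- cos(alpha) * e1 + sin(alpha) * e2
  list(posA = centers + radius * u,
       posB = centers - radius * u,
       a1A = -u, a1B = u,
       a3A = tangents, a3B = -tangents)
}

# Assemble a two-strand duplex topology: strand A listed 5'->3' as indices
# 1..n, strand B 5'->3' as n+1..2n, so base pair t is (t, 2n + 1 - t).
duplex_topology <- function(seqA, strand_ids = c(1L, 2L)) {
  n <- length(seqA)
  base <- c(seqA, rev(dna_complement(seqA)))
  n3 <- c(2:n, NA, (n + 2):(2 * n), NA)
  n5 <- c(NA, 1:(n - 1), NA, (n + 1):(2 * n - 1))
  oxdna_topology(rep(strand_ids, each = n), base, n3, n5)
}

#' Generate an ideal B-form duplex
#'
#' Two complementary antiparallel strands on helical backbones. Strand A
#' occupies indices 1..n_bp (5' to 3' along the +axis direction), strand B
#' indices n_bp+1..2*n_bp, so base pair `t` is `(t, 2*n_bp + 1 - t)`.
#'
#' @param n_bp number of base pairs (>= 2).
#' @param spec a [generator_spec()].
#' @param origin 3-vector start of the helix axis (centre of bp 1).
#' @param axis helix axis direction (unit-normalized internally).
#' @param seed RNG seed for the random (non-repetitive) sequence.
#' @param phase twist phase of base pair 1, radians.
#' @return A list with `topology`, `frame`, `pairs` (design-derived
#'   [base_pair_map()]) and `ground_truth` (centerline, axis, parameters).
#' @export
make_duplex <- function(n_bp, spec = generator_spec(), origin = c(0, 0, 0),
                        axis = c(1, 0, 0), seed = 1, phase = 0) {
  stopifnot(n_bp >= 2)
  w <- unitv(axis)
  ref <- if (abs(w[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e1 <- unitv(cross3(ref, w))
  e2 <- cross3(w, e1)
  t <- seq_len(n_bp)
  centers <- outer(rep(1, n_bp), origin) + outer((t - 1) * spec$rise, w)
  alpha <- phase + 2 * pi * (t - 1) / spec$pitch
  st <- duplex_states(centers, outer(rep(1, n_bp), w),
                      outer(rep(1, n_bp), e1), outer(rep(1, n_bp), e2),
                      alpha, spec$position_radius)
  seqA <- with_seed(seed, random_sequence(n_bp))
  topo <- duplex_topology(seqA)
  pos <- rbind(st$posA, st$posB[n_bp:1, , drop = FALSE])
  a1 <- rbind(st$a1A, st$a1B[n_bp:1, , drop = FALSE])
  a3 <- rbind(st$a3A, st$a3B[n_bp:1, , drop = FALSE])
  ctr <- colMeans(centers)
  half <- max(vnorm(centers[1, ] - ctr), vnorm(centers[n_bp, ] - ctr))
  frame <- oxdna_frame(pos, a1, a3, box = rep(2 * half + 20, 3))
  pairs <- base_pair_map(t, 2 * n_bp + 1 - t, "design-derived")
  list(topology = topo, frame = frame, pairs = pairs,
       ground_truth = list(kind = "duplex", centerline = centers,
                           axis = w, seed = seed,
                           spec = spec))
}
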