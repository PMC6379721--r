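# Weave and corrugation metrics for origami sheets: helix-axis extraction
# (base-pair midpoints), inter-helix distance profiles and their
# fluctuations, triangular-wave analysis, and signed corrugation angles
# around junctions.

#' Extract helix axes from a trajectory
#'
#' The helix axis point at a base-pair index is the midpoint between the
#' two paired bases. Unpaired (frayed/melted) positions can be masked;
#' masked positions propagate as gaps through every downstream profile.
#'
#' @param trajectory an `oxdna_trajectory` (or a single `oxdna_frame`
#'   wrapped in a one-frame trajectory).
#' @param helices list of per-helix m x 2 matrices of paired nucleotide
#'   indices, ordered along the helix (the design registration); as
#'   returned by the synthetic generators.
#' @param mask optional list of logical vectors (one per helix) marking
#'   valid base-pair positions; defaults to all valid.
#' @param min_points helices with fewer valid positions are dropped with a
#'   warning.
#' @return An object of class `helix_axes`: list with `points` (per helix,
#'   an m x 3 x n_frames array, `NA` where masked), `mask`, `n_frames`.
#' @export
helix_axes <- function(trajectory, helices, mask = NULL, min_points = 4) {
  nf <- length(trajectory$frames)
  if (is.null(mask)) mask <- lapply(helices, function(h) rep(TRUE, nrow(h)))
  stopifnot(length(mask) == length(helices))
  keep <- vapply(mask, sum, 0) >= min_points
  if (!all(keep)) {
    warning(sum(!keep), " helix/helices with fewer than ", min_points,
            " valid positions excluded")
    helices <- helices[keep]; mask <- mask[keep]
  }
  points <- lapply(seq_along(helices), function(h) {
    hm <- helices[[h]]
    arr <- array(NA_real_, c(nrow(hm), 3, nf))
    for (f in seq_len(nf)) {
      p <- trajectory$frames[[f]]$pos
      arr[, , f] <- (p[hm[, 1], , drop = FALSE] +
                     p[hm[, 2], , drop = FALSE]) / 2
      arr[!mask[[h]], , f] <- NA_real_
    }
    arr
  })
  names(points) <- names(helices)
  structure(list(points = points, mask = mask, n_frames = nf),
            class = "helix_axes")
}

#' Mask helix positions missing from a detected base-pair map
#'
#' Compares the design registration with a (typically geometry-derived)
#' [base_pair_map()]: positions whose design pair is absent from the map
#' are masked, mimicking fraying or staple melting.
#'
#' @param helices as in [helix_axes()].
#' @param pairs a `base_pair_map`.
#' @return List of logical vectors usable as the `mask` of [helix_axes()].
#' @export
mask_from_pairs <- function(helices, pairs) {
  key <- paste(pairs$i, pairs$j)
  lapply(helices, function(hm) {
    paste(pmin(hm[, 1], hm[, 2]), pmax(hm[, 1], hm[, 2])) %in% key
  })
}

#' Inter-helix distance (weave) profiles
#'
#' For each pair of adjacent helices, the mean over frames of the distance
#' between corresponding axis points, and its standard deviation, per
#' base-pair index. Positions masked in either helix are skipped.
#'
#' @param axes a [helix_axes()] object.
#' @param pair_list 2-column matrix of helix index pairs; defaults to
#'   consecutive pairs (1-2, 2-3, ...).
#' @param groups optional vector assigning each pair to a symmetry group,
#'   carried into the output.
#' @return A data frame of class `weave_profile`: `pair`, `a`, `b`,
#'   `index`, `mean`, `sd`, `n` (frames) and optionally `group`.
#' @export
weave_profile <- function(axes, pair_list = NULL, groups = NULL) {
  H <- length(axes$points)
  if (is.null(pair_list)) {
    if (H < 2) stop("need at least two helices")
    pair_list <- cbind(seq_len(H - 1), 2:H)
  }
  pair_list <- matrix(as.integer(pair_list), ncol = 2)
  out <- lapply(seq_len(nrow(pair_list)), function(r) {
    a <- pair_list[r, 1]; b <- pair_list[r, 2]
    pa <- axes$points[[a]]; pb <- axes$points[[b]]
    m <- min(dim(pa)[1], dim(pb)[1])
    ok <- axes$mask[[a]][1:m] & axes$mask[[b]][1:m]
    d <- sqrt(apply((pa[1:m, , , drop = FALSE] -
                     pb[1:m, , , drop = FALSE])^2, c(1, 3), sum))
    d <- matrix(d, nrow = m)
    df <- data.frame(pair = paste0(a, "-", b), a = a, b = b,
                     index = (1:m)[ok],
                     mean = rowMeans(d)[ok],
                     sd = apply(d, 1, stats::sd)[ok],
                     n = axes$n_frames)
    if (!is.null(groups)) df$group <- groups[r]
    df
  })
  skipped <- sum(vapply(seq_len(nrow(pair_list)), function(r) {
    a <- pair_list[r, 1]; b <- pair_list[r, 2]
    m <- min(dim(axes$points[[a]])[1], dim(axes$points[[b]])[1])
    sum(!(axes$mask[[a]][1:m] & axes$mask[[b]][1:m]))
  }, 0))
  if (skipped > 0)
    message(skipped, " masked/unregistered position(s) skipped")
  structure(do.call(rbind, out), class = c("weave_profile", "data.frame"))
}

#' Junction splay angle implied by a triangular weave waveform
#'
#' For a perfectly triangular weave, each helix leaves a junction at a
#' fixed angle and runs straight to the next extremum, so the splay angle
#' is `atan((amplitude / 2) / (half_period * rise))`.
#'
#' @param amplitude peak-to-peak inter-helix distance variation, nm.
#' @param half_period base pairs between a weave minimum and the adjacent
#'   maximum.
#' @param rise helical rise, nm per bp.
#' @return Splay angle theta in degrees.
#' @examples
#' triangular_theta(1.5, 16, 0.34)  # 7.85 degrees
#' @export
triangular_theta <- function(amplitude, half_period, rise = 0.34) {
  if (amplitude < 0 || half_period <= 0 || rise <= 0)
    stop("amplitude must be >= 0; half_period and rise must be > 0")
  rad2deg(atan((amplitude / 2) / (half_period * rise)))
}

#' Amplitude, period and extrema of a weave waveform
#'
#' Smooths the profile with a 3-point moving average, locates local
#' extrema, and reports `amplitude = mean(maxima) - mean(minima)` and the
#' dominant period from the peak of the circular autocorrelation.
#'
#' @param profile numeric vector of mean inter-helix distances by index, or
#'   a [weave_profile()] subset for a single pair.
#' @return A list with `amplitude` (nm), `period` (bp, `NA` if aperiodic),
#'   `maxima`, `minima` (indices into the profile) and `aperiodic`.
#' @export
weave_waveform_stats <- function(profile) {
  x <- if (is.data.frame(profile)) {
    if (length(unique(profile$pair)) > 1)
      stop("profile contains several pairs; subset to one")
    profile$mean[order(profile$index)]
  } else as.numeric(profile)
  n <- length(x)
  if (n < 8) stop("profile too short")
  sm <- stats::filter(x, rep(1 / 3, 3), sides = 2)
  sm[1] <- mean(x[1:2]); sm[n] <- mean(x[(n - 1):n])
  sm <- as.numeric(sm)
  interior <- 2:(n - 1)
  maxima <- interior[sm[interior] > sm[interior - 1] &
                     sm[interior] > sm[interior + 1]]
  minima <- interior[sm[interior] < sm[interior - 1] &
                     sm[interior] < sm[interior + 1]]
  if (!length(maxima) || !length(minima))
    return(list(amplitude = 0, period = NA_real_, maxima = maxima,
                minima = minima, aperiodic = TRUE))
  amplitude <- mean(x[maxima]) - mean(x[minima])
  # dominant period: peak of the circular autocorrelation
  xc <- x - mean(x)
  r <- Re(stats::fft(Mod(stats::fft(xc))^2, inverse = TRUE)) / n
  lags <- 2:floor(n / 2)
  period <- lags[which.max(r[lags + 1])]
  list(amplitude = amplitude, period = period, maxima = maxima,
       minima = minima, aperiodic = FALSE)
}

#' Corrugation (out-of-plane junction twist) profiles
#'
#' For every junction, follows the inter-helix vector of its helix pair as
#' one moves away from the junction: at each offset, the local inter-helix
#' vector and the frame-averaged inter-helix vector at the junction are
#' projected onto the plane perpendicular to the junction's average helix
#' axis, and the angle between the projections is signed by the scalar
#' triple product (local, junction, axis). Positive angles are
#' anticlockwise about the axis (which points along increasing base-pair
#' index).
#'
#' @param axes a [helix_axes()] object.
#' @param crossovers data frame with columns `pair` (index into
#'   consecutive helix pairs) and `position` (bp index), as from
#'   [make_tile()]; when a logical `canonical` column is present and
#'   `canonical_only = TRUE`, edge/seam junctions are excluded.
#' @param max_offset maximum |offset| in bp from the junction midpoint.
#' @param canonical_only apply the canonical-junction filter.
#' @param tangent_halfwidth half-width (bp) of the central difference used
#'   for the junction's average helix axis.
#' @return A list of class `corrugation_profile`: `curves` (data frame
#'   `junction`, `pair`, `position`, `offset`, `angle`) and `mean` (data
#'   frame `offset`, `angle`, `n` averaged over junctions).
#' @export
corrugation_profile <- function(axes, crossovers, max_offset = 8,
                                canonical_only = TRUE,
                                tangent_halfwidth = 2) {
  if (canonical_only && !is.null(crossovers$canonical))
    crossovers <- crossovers[crossovers$canonical, , drop = FALSE]
  if (!nrow(crossovers)) stop("no junctions to analyse")
  nf <- axes$n_frames
  curves <- list()
  for (r in seq_len(nrow(crossovers))) {
    J <- crossovers$pair[r]; c0 <- crossovers$position[r]
    pa <- axes$points[[J]]; pb <- axes$points[[J + 1]]
    m <- min(dim(pa)[1], dim(pb)[1])
    w <- tangent_halfwidth
    if (c0 - w < 1 || c0 + w > m) next
    # average helix axis at the junction (both helices, all frames)
    tang <- apply(pa[c0 + w, , , drop = FALSE] - pa[c0 - w, , , drop = FALSE],
                  2, mean) +
            apply(pb[c0 + w, , , drop = FALSE] - pb[c0 - w, , , drop = FALSE],
                  2, mean)
    ahat <- unitv(tang)
    # frame-averaged inter-helix vector at the junction
    vj <- apply(pb[c0, , , drop = FALSE] - pa[c0, , , drop = FALSE], 2, mean)
    vjp <- vj - sum(vj * ahat) * ahat
    if (vnorm(vjp) < 1e-9) next
    offsets <- (-max_offset):max_offset
    offsets <- offsets[c0 + offsets >= 1 & c0 + offsets <= m]
    ang <- vapply(offsets, function(o) {
      idx <- c0 + o
      if (!(axes$mask[[J]][idx] && axes$mask[[J + 1]][idx]))
        return(NA_real_)
      a_of <- vapply(seq_len(nf), function(f) {
        g <- pb[idx, , f] - pa[idx, , f]
        gp <- g - sum(g * ahat) * ahat
        if (vnorm(gp) < 1e-9) return(NA_real_)
        rad2deg(atan2(sum(cross3(vjp, gp) * ahat), sum(vjp * gp)))
      }, numeric(1))
      mean(a_of, na.rm = TRUE)
    }, numeric(1))
    curves[[length(curves) + 1]] <-
      data.frame(junction = paste0(J, "@", c0), pair = J, position = c0,
                 offset = offsets, angle = ang)
  }
  if (!length(curves)) stop("no junction had enough registered indices")
  curves <- do.call(rbind, curves)
  agg <- stats::aggregate(angle ~ offset, curves, mean, na.action = stats::na.omit)
  nag <- stats::aggregate(angle ~ offset, curves, function(a) sum(!is.na(a)))
  mean_curve <- data.frame(offset = agg$offset, angle = agg$angle,
                           n = nag$angle)
  structure(list(curves = curves, mean = mean_curve),
            class = "corrugation_profile")
}

#' @export
print.corrugation_profile <- function(x, ...) {
  cat("corrugation profile:", length(unique(x$curves$junction)),
      "junction(s), offsets", min(x$mean$offset), "..", max(x$mean$offset),
      "bp\n")
  invisible(x)
}

#' Write a profile table as delimited text
#'
#' @param profile a `weave_profile` or `corrugation_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  tab <- if (inherits(profile, "corrugation_profile")) profile$curves
         else as.data.frame(profile)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
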