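# Mean structures, optimal rigid superposition (Kabsch), RMSD and
# helix-path helicity detection.

#' Optimal rigid superposition of corresponding point sets
#'
#' Kabsch algorithm: the proper rotation R and translation t minimizing
#' `sum |R p_i + t - q_i|^2`. Reflections are never returned — molecular
#' chirality is preserved even when an improper alignment would score
#' better.
#'
#' @param P,Q n x 3 matrices of corresponding points (n >= 3).
#' @return An object of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation`, `rmsd` (nm) and `aligned` (P after the motion).
#' @export
superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3, ncol(Q) == 3, nrow(P) == nrow(Q), nrow(P) >= 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    warning("(near-)collinear point set: rotation about the line is ",
            "undetermined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cq - as.numeric(R %*% cp)
  aligned <- apply_rigid(P, R, t)
  rmsd <- sqrt(mean(rowSums((aligned - Q)^2)))
  structure(list(rotation = R, translation = t, rmsd = rmsd,
                 aligned = aligned), class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("superposition: rmsd =", signif(x$rmsd, 6), "nm\n")
  invisible(x)
}

#' Iterative mean structure of a trajectory
#'
#' Initializes the mean from the first frame, then repeatedly superposes
#' every frame onto the current mean (over all nucleotide positions, or an
#' optional core subset), averages positions and versors, and
#' re-orthonormalizes the versors (a3 first, then a1 projected
#' perpendicular), until the mean moves less than `tol` or `max_iter`
#' passes.
#'
#' @param trajectory an `oxdna_trajectory`.
#' @param core optional integer vector of nucleotide indices used for the
#'   alignment (all by default); averaging always covers all nucleotides.
#' @param tol convergence threshold on the RMS shift of the mean, nm.
#' @param max_iter maximum alignment passes.
#' @return An object of class `mean_structure`: `frame` (an `oxdna_frame`),
#'   `spread` (per-nucleotide positional RMS about the mean, nm),
#'   `n_frames`, `iterations`.
#' @export
mean_structure <- function(trajectory, core = NULL, tol = 1e-4,
                           max_iter = 20) {
  frames <- trajectory$frames
  if (!length(frames)) stop("empty trajectory")
  n <- nrow(frames[[1]]$pos)
  if (is.null(core)) core <- seq_len(n)
  mean_pos <- frames[[1]]$pos
  iter <- 0L
  repeat {
    iter <- iter + 1L
    acc_pos <- matrix(0, n, 3)
    acc_a1 <- matrix(0, n, 3)
    acc_a3 <- matrix(0, n, 3)
    acc_sq <- numeric(n)
    for (fr in frames) {
      sp <- superpose(fr$pos[core, , drop = FALSE],
                      mean_pos[core, , drop = FALSE])
      p <- apply_rigid(fr$pos, sp$rotation, sp$translation)
      acc_pos <- acc_pos + p
      acc_a1 <- acc_a1 + fr$a1 %*% t(sp$rotation)
      acc_a3 <- acc_a3 + fr$a3 %*% t(sp$rotation)
      acc_sq <- acc_sq + rowSums((p - mean_pos)^2)
    }
    new_mean <- acc_pos / length(frames)
    shift <- sqrt(mean(rowSums((new_mean - mean_pos)^2)))
    mean_pos <- new_mean
    if (shift < tol || iter >= max_iter) break
  }
  a3 <- acc_a3 / sqrt(rowSums(acc_a3^2))
  a1 <- acc_a1 - rowSums(acc_a1 * a3) * a3
  a1 <- a1 / sqrt(rowSums(a1^2))
  spread <- sqrt(acc_sq / length(frames))
  fr1 <- frames[[1]]
  structure(list(frame = oxdna_frame(mean_pos, a1, a3, box = fr1$box,
                                     time = fr1$time),
                 spread = spread, n_frames = length(frames),
                 iterations = iter),
            class = "mean_structure")
}

#' @export
print.mean_structure <- function(x, ...) {
  cat("mean structure over", x$n_frames, "frame(s), converged in",
      x$iterations, "pass(es); median spread",
      signif(stats::median(x$spread), 4), "nm\n")
  invisible(x)
}

#' RMSD of a structure against a reference point set
#'
#' Superposes the model points (helix-axis points, typically) onto the
#' reference and reports the RMSD together with the per-point displacement
#' vectors (reference minus aligned model).
#'
#' @param x a `mean_structure`, an `oxdna_frame`, or an n x 3 matrix of
#'   model points.
#' @param reference m x 3 matrix of reference points.
#' @param mapping optional 2-column matrix pairing model row i with
#'   reference row j; identity by default (sizes must then match).
#' @return A list with `rmsd` (nm), `displacement` (k x 3) and the
#'   `superposition`.
#' @export
rmsd_to_reference <- function(x, reference, mapping = NULL) {
  pts <- if (inherits(x, "mean_structure")) x$frame$pos
         else if (inherits(x, "oxdna_frame")) x$pos
         else as.matrix(x)
  reference <- as.matrix(reference)
  if (is.null(mapping)) {
    if (nrow(pts) != nrow(reference))
      stop("model has ", nrow(pts), " points but reference has ",
           nrow(reference), "; supply a mapping")
    mapping <- cbind(seq_len(nrow(pts)), seq_len(nrow(pts)))
  }
  mapping <- matrix(as.integer(mapping), ncol = 2)
  sp <- superpose(pts[mapping[, 1], , drop = FALSE],
                  reference[mapping[, 2], , drop = FALSE])
  disp <- reference[mapping[, 2], , drop = FALSE] - sp$aligned
  list(rmsd = sp$rmsd, displacement = disp, superposition = sp)
}

#' Detect helicity of a helix-axis path
#'
#' Smooths the polyline with a running mean of `window` points (the local
#' straight axis), computes the residual, and accumulates the winding of
#' the residual about the path direction. The handedness follows the net
#' winding sign (right-handed = anticlockwise about the direction of
#' increasing index); the period is the number of base-pair steps per 360
#' degrees of winding. Residuals below `noise_floor` give `"none"`.
#'
#' @param points n x 3 polyline of helix-axis points (bp order).
#' @param window running-mean window (odd, in bp) for the local axis.
#' @param noise_floor residual amplitude (nm) below which no helicity is
#'   reported.
#' @return A list with `handedness` (`"left"`, `"right"` or `"none"`),
#'   `period` (bp per turn, `NA` for `"none"`), `winding` (total degrees)
#'   and `amplitude` (median residual, nm).
#' @export
helix_path_helicity <- function(points, window = 15, noise_floor = 0.05) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (window %% 2 == 0) window <- window + 1L
  if (n < 2 * window) stop("polyline too short: ", n, " points for window ",
                           window)
  half <- (window - 1L) / 2L
  sm <- apply(points, 2, function(v)
    as.numeric(stats::filter(v, rep(1 / window, window), sides = 2)))
  keep <- (half + 1):(n - half)
  res <- points[keep, , drop = FALSE] - sm[keep, , drop = FALSE]
  amp <- stats::median(sqrt(rowSums(res^2)))
  if (amp < noise_floor)
    return(list(handedness = "none", period = NA_real_, winding = 0,
                amplitude = amp))
  axis <- principal_axis(points)
  if (sum(axis * (points[n, ] - points[1, ])) < 0) axis <- -axis
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  b1 <- unitv(cross3(ref, axis))
  b2 <- cross3(axis, b1)
  ang <- rad2deg(atan2(res %*% b2, res %*% b1))
  steps <- circ_diff(ang[-1], ang[-length(ang)])
  unwrapped <- cumsum(c(ang[1], steps))
  idx <- seq_along(unwrapped)
  slope <- stats::coef(stats::lm(unwrapped ~ idx))[2]   # deg per bp
  if (abs(slope) < 1e-6)
    return(list(handedness = "none", period = NA_real_,
                winding = sum(steps), amplitude = amp))
  list(handedness = if (slope > 0) "right" else "left",
       period = 360 / abs(slope),
       winding = sum(steps), amplitude = amp)
}
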