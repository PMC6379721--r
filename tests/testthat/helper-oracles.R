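# Shared helpers: random rigid motions, mirror images, and the brute-force
# rotation-grid RMSD oracle used to cross-check the closed-form
# superposition.

random_rigid_motion <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, sd = 5))
}

move_frame <- function(frame, R, t) {
  oxdna_frame(sweep(frame$pos %*% t(R), 2, t, "+"),
              frame$a1 %*% t(R), frame$a3 %*% t(R),
              box = frame$box, time = frame$time,
              vel = frame$vel %*% t(R), angvel = frame$angvel %*% t(R))
}

move_trajectory <- function(traj, R, t) {
  oxdna_trajectory(traj$topology,
                   lapply(traj$frames, move_frame, R = R, t = t))
}

# Mirror image through the yz plane (negates x of positions and versors).
mirror_frame <- function(frame) {
  M <- diag(c(-1, 1, 1))
  oxdna_frame(frame$pos %*% M, frame$a1 %*% M, frame$a3 %*% M,
              box = frame$box, time = frame$time)
}

euler_rotation <- function(a, b, c) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cc <- cos(c); sc <- sin(c)
  Rz1 <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  Rz2 <- matrix(c(cc, sc, 0, -sc, cc, 0, 0, 0, 1), 3, 3)
  Rz1 %*% Ry %*% Rz2
}

# Brute-force minimum RMSD over rotations: nested grid search on Euler
# angles (optimal translation is the centroid match), independent of the
# SVD route it cross-checks.
grid_search_rmsd <- function(P, Q, levels = 4) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  score <- function(R) sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  best <- list(a = 0, b = pi / 2, c = 0, val = Inf)
  spans <- c(pi, pi / 2, pi)          # half-widths around the current best
  step_n <- 9
  for (lev in seq_len(levels)) {
    aa <- seq(best$a - spans[1], best$a + spans[1], length.out = 2 * step_n + 1)
    bb <- seq(max(0, best$b - spans[2]), min(pi, best$b + spans[2]),
              length.out = step_n + 1)
    cc <- seq(best$c - spans[3], best$c + spans[3], length.out = 2 * step_n + 1)
    for (a in aa) for (b in bb) for (c in cc) {
      v <- score(euler_rotation(a, b, c))
      if (v < best$val) best <- list(a = a, b = b, c = c, val = v)
    }
    spans <- spans / step_n
  }
  best$val
}

expect_angle_equal <- function(x, y, tol) {
  d <- abs(((x - y + 180) %% 360) - 180)
  expect_lt(d, tol)
}
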