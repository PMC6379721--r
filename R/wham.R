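# Weighted-histogram analysis over (phi, theta) bins: combines harmonically
# phi-windowed angle samples into one free-energy landscape F(phi, theta)
# in kT units.

#' Build a free-energy landscape from windowed angle samples by WHAM
#'
#' Standard self-consistent reweighting on a fixed 2D grid. Each sample
#' carries the `window_id` of the bias window it was collected under; the
#' per-window free-energy offsets are iterated to convergence, after which
#' `F = -ln P` over occupied bins, shifted so the minimum is 0 (`log_norm`
#' records the shift, so `exp(-(F + log_norm))` sums to one over occupied
#' bins). Unoccupied bins are `NA`, never 0.
#'
#' @param samples data frame with columns `phi` (degrees, `[0, 360)`),
#'   `theta` (degrees) and, when `windows` are given, `window_id`.
#' @param windows list of [bias_window()]s, or `NULL` for unbiased samples.
#' @param phi_edges,theta_edges bin edges in degrees; defaults give the
#'   2 x 1 degree bins used throughout.
#' @param temperature temperature in K; labels the kT unit only.
#' @param tol convergence tolerance on the window offsets.
#' @param max_iters maximum self-consistency iterations.
#' @return An object of class `free_energy_landscape`: `phi_edges`,
#'   `theta_edges`, matrices `F` and `counts` (phi x theta), `phi_centers`,
#'   `theta_centers`, `log_norm`, `temperature`, `offsets`, `iterations`,
#'   `converged`, `disconnected`.
#' @export
wham <- function(samples, windows = NULL,
                 phi_edges = seq(0, 360, by = 2),
                 theta_edges = seq(-90, 90, by = 1),
                 temperature = 296.15, tol = 1e-7, max_iters = 1e5) {
  if (is.null(samples) || nrow(samples) == 0) stop("no samples")
  if (is.null(windows)) {
    windows <- list(bias_window(0, 0, window_id = 1L))
    samples$window_id <- 1L
  }
  wid <- vapply(seq_along(windows), function(w)
    if (is.null(windows[[w]]$window_id)) w else windows[[w]]$window_id,
    numeric(1))
  if (!all(samples$window_id %in% wid))
    stop("samples reference window ids not in `windows`")
  npb <- length(phi_edges) - 1L
  ntb <- length(theta_edges) - 1L
  pc <- (phi_edges[-1] + phi_edges[-length(phi_edges)]) / 2
  tc <- (theta_edges[-1] + theta_edges[-length(theta_edges)]) / 2
  ip <- findInterval(samples$phi, phi_edges, rightmost.closed = TRUE)
  it <- findInterval(samples$theta, theta_edges, rightmost.closed = TRUE)
  inb <- ip >= 1 & ip <= npb & it >= 1 & it <= ntb
  if (!all(inb)) {
    warning(sum(!inb), " sample(s) outside the bin range were dropped")
    samples <- samples[inb, ]; ip <- ip[inb]; it <- it[inb]
  }
  if (!nrow(samples)) stop("no samples inside the bin range")
  W <- length(windows)
  bin <- (it - 1L) * npb + ip                      # flat bin index
  M <- tabulate(bin, nbins = npb * ntb)            # total counts per bin
  Nw <- vapply(wid, function(w) sum(samples$window_id == w), numeric(1))
  # bias energy of every window at every phi-bin centre (theta unbiased)
  U <- vapply(windows, function(w) bias_energy(pc, w), numeric(npb))
  U <- matrix(U, nrow = npb)                       # npb x W
  occ_flat <- which(M > 0)
  occ_phi <- ((occ_flat - 1L) %% npb) + 1L
  f <- rep(0, W)
  iter <- 0L
  converged <- FALSE
  logNw <- log(Nw[Nw > 0])
  active <- which(Nw > 0)
  while (iter < max_iters) {
    iter <- iter + 1L
    # log denominator per occupied bin: log sum_w N_w exp(f_w - U_w(bin))
    A <- sweep(-U[occ_phi, active, drop = FALSE], 2,
               f[active] + logNw, "+")
    amax <- apply(A, 1, max)
    logden <- amax + log(rowSums(exp(A - amax)))
    logP <- log(M[occ_flat]) - logden
    logP <- logP - max(logP)
    # new offsets: f_w = -ln sum_b P_b exp(-U_w(b))
    B <- sweep(-U[occ_phi, active, drop = FALSE], 1, logP, "+")
    bmax <- apply(B, 2, max)
    fnew <- -(bmax + log(colSums(exp(sweep(B, 2, bmax)))))
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f[active]))
    f[active] <- fnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("WHAM did not converge within ", max_iters, " iterations")
  logP <- logP - log(sum(exp(logP)))               # normalize over occupied
  Fv <- rep(NA_real_, npb * ntb)
  Fv[occ_flat] <- -logP
  shift <- min(Fv, na.rm = TRUE)
  Fv <- Fv - shift
  Fmat <- matrix(Fv, npb, ntb)
  Cmat <- matrix(M, npb, ntb)
  # connectivity: each window's sampled phi range must chain with the next
  ranges <- lapply(wid[active], function(w)
    range(ip[samples$window_id == w]))
  ranges <- ranges[order(vapply(ranges, `[`, 1, 1))]
  disconnected <- FALSE
  if (length(ranges) > 1) {
    hi <- ranges[[1]][2]
    for (r in ranges[-1]) {
      if (r[1] > hi + 1L) { disconnected <- TRUE; break }
      hi <- max(hi, r[2])
    }
  }
  if (disconnected)
    warning("sampled phi ranges do not overlap; landscape is disconnected")
  structure(list(phi_edges = phi_edges, theta_edges = theta_edges,
                 phi_centers = pc, theta_centers = tc,
                 F = Fmat, counts = Cmat, log_norm = shift,
                 temperature = temperature, offsets = f,
                 iterations = iter, converged = converged,
                 disconnected = disconnected),
            class = "free_energy_landscape")
}

#' @export
print.free_energy_landscape <- function(x, ...) {
  cat("free-energy landscape:", length(x$phi_centers), "x",
      length(x$theta_centers), "bins (phi x theta),",
      sum(x$counts > 0), "occupied;",
      "T =", x$temperature, "K;",
      if (x$converged) paste0("converged in ", x$iterations, " iteration(s)")
      else "NOT converged", "\n")
  invisible(x)
}

#' One-dimensional free-energy marginal of a landscape
#'
#' `F_axis(x) = -ln sum_other exp(-F)`, summed over the other axis
#' (optionally restricted to a sub-range, as for a profile restricted to
#' near-anti-parallel junctions), shifted to minimum 0.
#'
#' @param landscape a [wham()] result.
#' @param axis `"phi"` or `"theta"`: the axis to keep.
#' @param restrict optional length-2 range (degrees) on the *other* axis.
#' @return Data frame with `center`, `F` (NA where unoccupied) and `counts`.
#' @export
marginal_profile <- function(landscape, axis = c("phi", "theta"),
                             restrict = NULL) {
  axis <- match.arg(axis)
  Fm <- landscape$F; Cm <- landscape$counts
  other_centers <- if (axis == "phi") landscape$theta_centers
                   else landscape$phi_centers
  keep <- rep(TRUE, length(other_centers))
  if (!is.null(restrict)) {
    stopifnot(length(restrict) == 2)
    keep <- other_centers >= restrict[1] & other_centers <= restrict[2]
    if (!any(keep)) stop("restriction covers no bins")
  }
  if (axis == "phi") {
    Fm <- Fm[, keep, drop = FALSE]; Cm <- Cm[, keep, drop = FALSE]
    centers <- landscape$phi_centers
    collapse <- function(f) apply(f, 1, function(r)
      if (all(is.na(r))) NA_real_ else -log(sum(exp(-r), na.rm = TRUE)))
    Fx <- collapse(Fm); n <- rowSums(Cm)
  } else {
    Fm <- Fm[keep, , drop = FALSE]; Cm <- Cm[keep, , drop = FALSE]
    centers <- landscape$theta_centers
    Fx <- apply(Fm, 2, function(col)
      if (all(is.na(col))) NA_real_ else -log(sum(exp(-col), na.rm = TRUE)))
    n <- colSums(Cm)
  }
  if (all(is.na(Fx))) stop("restriction covers no occupied bins")
  Fx <- Fx - min(Fx, na.rm = TRUE)
  data.frame(center = centers, F = Fx, counts = n)
}

#' Locate the minimum of a free-energy landscape
#'
#' The raw argmin bin is noisy when the landscape is flat near its minimum,
#' so by default the minimum is refined by a counts-weighted quadratic fit
#' of F over the low-free-energy basin (bins with `F <= basin`), a standard
#' smoothing of binned free energies. Falls back to the argmin bin centre
#' when the fitted quadratic is not convex.
#'
#' @param landscape a [wham()] result.
#' @param refine refine by quadratic fit (default `TRUE`).
#' @param basin free-energy ceiling (kT) of the bins used in the fit.
#' @return A list with `phi`, `theta`, `bin` (argmin bin indices) and
#'   `refined`.
#' @export
landscape_minimum <- function(landscape, refine = TRUE, basin = 2) {
  idx <- which(landscape$F == min(landscape$F, na.rm = TRUE),
               arr.ind = TRUE)[1, ]
  out <- list(phi = landscape$phi_centers[idx[1]],
              theta = landscape$theta_centers[idx[2]],
              bin = unname(idx), refined = FALSE)
  if (!refine) return(out)
  sel <- which(!is.na(landscape$F) & landscape$F <= basin, arr.ind = TRUE)
  if (nrow(sel) < 12) return(out)
  x <- landscape$phi_centers[sel[, 1]]
  y <- landscape$theta_centers[sel[, 2]]
  z <- landscape$F[sel]
  w <- landscape$counts[sel]
  fit <- stats::lm(z ~ x + y + I(x^2) + I(y^2) + I(x * y), weights = w)
  b <- stats::coef(fit)
  H <- matrix(c(2 * b["I(x^2)"], b["I(x * y)"],
                b["I(x * y)"], 2 * b["I(y^2)"]), 2, 2)
  if (any(!is.finite(H)) || any(eigen(H, symmetric = TRUE,
                                      only.values = TRUE)$values <= 0))
    return(out)
  vertex <- -solve(H, c(b["x"], b["y"]))
  # accept the refinement only if it stays inside the basin
  if (vertex[1] < min(x) || vertex[1] > max(x) ||
      vertex[2] < min(y) || vertex[2] > max(y))
    return(out)
  list(phi = vertex[1], theta = vertex[2], bin = unname(idx), refined = TRUE)
}

#' Write a landscape as a delimited grid with a metadata header
#'
#' @param landscape a [wham()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# phi_bins: %d [%g, %g] deg", length(landscape$phi_centers),
            min(landscape$phi_edges), max(landscape$phi_edges)),
    sprintf("# theta_bins: %d [%g, %g] deg", length(landscape$theta_centers),
            min(landscape$theta_edges), max(landscape$theta_edges)),
    sprintf("# temperature_K: %g", landscape$temperature),
    sprintf("# log_norm: %.12g", landscape$log_norm),
    sprintf("# converged: %s after %d iterations", landscape$converged,
            landscape$iterations),
    "phi\ttheta\tF_kT\tcounts"), con)
  grid <- expand.grid(p = seq_along(landscape$phi_centers),
                      t = seq_along(landscape$theta_centers))
  lines <- sprintf("%g\t%g\t%s\t%d",
                   landscape$phi_centers[grid$p],
                   landscape$theta_centers[grid$t],
                   ifelse(is.na(landscape$F[cbind(grid$p, grid$t)]), "NA",
                          sprintf("%.6f",
                                  landscape$F[cbind(grid$p, grid$t)])),
                   landscape$counts[cbind(grid$p, grid$t)])
  writeLines(lines, con)
  invisible(path)
}
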