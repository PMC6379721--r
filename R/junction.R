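# Holliday-junction geometry: the twist angle phi (0 = parallel, 180 =
# anti-parallel, < 180 = left-handed) and the splay angle theta (positive =
# arms bending away from the junction plane), plus stacked-isomer
# classification and the harmonic phi-window bias used for umbrella
# sampling.

#' Describe one four-way junction
#'
#' @param arms list of four arms in fixed order: arms 1 and 2 are the two
#'   halves of stacked duplex 1, arms 3 and 4 of stacked duplex 2. Each arm
#'   is a list with `duplex` (1 or 2) and `pairs`, an m x 2 matrix of
#'   paired nucleotide indices ordered from the junction outward.
#' @param continuing strand ids of the two continuing (non-crossing)
#'   strands; the first one fixes the junction-plane orientation.
#' @param exchanging strand ids of the two exchanging (crossing) strands.
#' @param midpoints nucleotide indices of the exchanging strands at the
#'   junction midpoint.
#' @param label optional junction label.
#' @return An object of class `junction_spec`.
#' @export
junction_spec <- function(arms, continuing, exchanging, midpoints,
                          label = NULL) {
  stopifnot(length(arms) == 4)
  all_idx <- unlist(lapply(arms, function(a) as.vector(a$pairs)))
  if (anyDuplicated(all_idx))
    stop("junction arms are not disjoint")
  structure(list(arms = arms, continuing = continuing,
                 exchanging = exchanging, midpoints = midpoints,
                 label = label),
            class = "junction_spec")
}

#' @export
print.junction_spec <- function(x, ...) {
  cat("four-way junction", if (!is.null(x$label)) x$label else "",
      ": arms of", paste(vapply(x$arms, function(a) nrow(a$pairs), 1L),
                         collapse = "/"), "bp\n")
  invisible(x)
}

arm_midpoints <- function(frame, arm) {
  (frame$pos[arm$pairs[, 1], , drop = FALSE] +
   frame$pos[arm$pairs[, 2], , drop = FALSE]) / 2
}

#' Least-squares axis of one junction arm
#'
#' Fits a line through the base-pair midpoints of the arm, skipping the
#' `exclusion` pairs nearest the junction (where the duplex is distorted)
#' and using the next `fit_length` pairs. The direction is oriented to
#' point away from the junction.
#'
#' @param frame an `oxdna_frame`.
#' @param arm one element of a [junction_spec()]'s `arms`.
#' @param fit_length number of base pairs in the fit.
#' @param exclusion number of junction-proximal base pairs to skip.
#' @return Unit 3-vector.
#' @export
arm_axis <- function(frame, arm, fit_length = 8, exclusion = 2) {
  m <- nrow(arm$pairs)
  if (m < fit_length + exclusion)
    stop("arm has ", m, " pairs; need at least fit_length + exclusion = ",
         fit_length + exclusion)
  mid <- arm_midpoints(frame, arm)
  sel <- (exclusion + 1):(exclusion + fit_length)
  ax <- principal_axis(mid[sel, , drop = FALSE])
  outward <- mid[sel[length(sel)], ] - mid[sel[1], ]
  if (sum(ax * outward) < 0) ax <- -ax
  ax
}

# Centres of the two stacked duplexes: mean of the innermost base-pair
# midpoints of each duplex's two arms.
duplex_centers <- function(frame, junction) {
  ctr <- function(d) {
    arms <- Filter(function(a) a$duplex == d, junction$arms)
    colMeans(do.call(rbind, lapply(arms, function(a)
      arm_midpoints(frame, a)[1, , drop = FALSE])))
  }
  list(ctr(1), ctr(2))
}

#' Plane of a four-way junction
#'
#' The plane that separates the two stacked duplexes: it passes through the
#' midpoint of the exchanging strands' junction nucleotides, and its normal
#' is the inter-duplex direction, oriented toward duplex 1 (the duplex of
#' the first continuing strand, whose 5' end fixes the convention).
#'
#' @param frame an `oxdna_frame`.
#' @param junction a [junction_spec()].
#' @return A list with `point` and unit `normal`.
#' @export
junction_plane <- function(frame, junction) {
  ctrs <- duplex_centers(frame, junction)
  sep <- ctrs[[1]] - ctrs[[2]]
  if (vnorm(sep) < 1e-3)
    stop("degenerate junction: stacked duplexes are not separated ",
         "(arms collinear?)")
  list(point = colMeans(frame$pos[junction$midpoints, , drop = FALSE]),
       normal = unitv(sep))
}

#' Junction twist and splay angles
#'
#' Computes the four arm axes and from them the twist angles `phi1`, `phi2`
#' (signed dihedrals, about the inter-duplex axis, between corresponding
#' arms of the two stacked duplexes), their circular mean `phi` in
#' `[0, 360)`, and the splay angles `theta1`, `theta2` (mean angle between
#' each duplex's arms and the junction plane, positive when the arms splay
#' away from the other duplex) and their mean `theta`.
#'
#' `phi = 0` for a parallel and `180` for an anti-parallel junction
#' (referring to the relative orientation of the two continuing strands);
#' values below 180 are left-handed.
#'
#' @inheritParams arm_axis
#' @param junction a [junction_spec()].
#' @return A list with `phi`, `phi1`, `phi2`, `theta`, `theta1`, `theta2`.
#' @export
junction_angles <- function(frame, junction, fit_length = 8, exclusion = 2) {
  v <- lapply(junction$arms, arm_axis, frame = frame,
              fit_length = fit_length, exclusion = exclusion)
  ctrs <- duplex_centers(frame, junction)
  sep <- ctrs[[2]] - ctrs[[1]]
  if (vnorm(sep) < 1e-3)
    stop("degenerate junction: stacked duplexes are not separated")
  chat <- unitv(sep)              # duplex 1 -> duplex 2
  nrm <- -chat                    # plane normal, toward duplex 1
  phi1 <- signed_angle_about(-v[[1]], -v[[3]], chat)
  phi2 <- signed_angle_about(v[[2]], v[[4]], chat)
  clamp <- function(x) pmin(1, pmax(-1, x))
  th <- vapply(seq_len(4), function(k) {
    side <- if (junction$arms[[k]]$duplex == 1) 1 else -1
    rad2deg(asin(clamp(sum(v[[k]] * side * nrm))))
  }, numeric(1))
  theta1 <- (th[1] + th[2]) / 2
  theta2 <- (th[3] + th[4]) / 2
  list(phi = circ_mean(c(phi1, phi2)), phi1 = phi1, phi2 = phi2,
       theta = (theta1 + theta2) / 2, theta1 = theta1, theta2 = theta2)
}

#' @rdname junction_angles
#' @export
junction_phi <- function(frame, junction, fit_length = 8, exclusion = 2) {
  junction_angles(frame, junction, fit_length, exclusion)$phi
}

#' @rdname junction_angles
#' @export
junction_theta <- function(frame, junction, fit_length = 8, exclusion = 2) {
  junction_angles(frame, junction, fit_length, exclusion)$theta
}

#' Classify the stacked isomer of a junction
#'
#' A stacked junction has two coaxially stacked arm pairs; two alternative
#' stackings (isomers) exist. Arms are coaxially stacked when their outward
#' axes are anti-aligned beyond `stacking_threshold`. Returns `"I"` when
#' the labelled stacking (arms 1+2 and 3+4) is coaxial, `"II"` when one of
#' the two alternative pairings is, and `"open"` otherwise.
#'
#' @inheritParams junction_angles
#' @param stacking_threshold arm-axis dot product below which two arms are
#'   declared coaxially stacked.
#' @return `"I"`, `"II"` or `"open"`.
#' @export
classify_isomer <- function(frame, junction, fit_length = 8, exclusion = 2,
                            stacking_threshold = -0.8) {
  v <- lapply(junction$arms, arm_axis, frame = frame,
              fit_length = fit_length, exclusion = exclusion)
  stacked <- function(a, b) sum(v[[a]] * v[[b]]) < stacking_threshold
  if (stacked(1, 2) && stacked(3, 4)) return("I")
  if ((stacked(1, 3) && stacked(2, 4)) || (stacked(1, 4) && stacked(2, 3)))
    return("II")
  "open"
}

#' Harmonic phi bias window
#'
#' @param center window centre in degrees.
#' @param stiffness harmonic stiffness in kT per squared degree (>= 0).
#' @param window_id optional id.
#' @return An object of class `bias_window`.
#' @export
bias_window <- function(center, stiffness, window_id = NULL) {
  stopifnot(stiffness >= 0)
  structure(list(center = center %% 360, stiffness = stiffness,
                 window_id = window_id), class = "bias_window")
}

#' Bias energy of a phi value under a harmonic window
#'
#' `0.5 * stiffness * d(phi, center)^2` in kT, with `d` the minimal
#' circular difference in degrees.
#'
#' @param phi_value phi value(s) in degrees.
#' @param window a [bias_window()].
#' @return Energy (kT), vectorized over `phi_value`.
#' @export
bias_energy <- function(phi_value, window) {
  0.5 * window$stiffness * circ_diff(phi_value, window$center)^2
}

#' Tabulate junction angles over a trajectory
#'
#' @param trajectory an `oxdna_trajectory`.
#' @param junction a [junction_spec()].
#' @inheritParams junction_angles
#' @param isomer also classify the stacked isomer per frame.
#' @return A data frame with one row per frame: `frame`, `phi1`, `phi2`,
#'   `phi`, `theta1`, `theta2`, `theta` and optionally `isomer`.
#' @export
junction_angle_table <- function(trajectory, junction, fit_length = 8,
                                 exclusion = 2, isomer = TRUE) {
  rows <- lapply(seq_along(trajectory$frames), function(k) {
    a <- junction_angles(trajectory$frames[[k]], junction,
                         fit_length, exclusion)
    data.frame(frame = k, phi1 = a$phi1, phi2 = a$phi2, phi = a$phi,
               theta1 = a$theta1, theta2 = a$theta2, theta = a$theta)
  })
  out <- do.call(rbind, rows)
  if (isomer)
    out$isomer <- vapply(trajectory$frames, classify_isomer, "",
                         junction = junction, fit_length = fit_length,
                         exclusion = exclusion)
  out
}

#' Flag frames affected by branch migration
#'
#' A junction whose midpoint base pairs change identity across frames has
#' undergone branch migration and should be excluded from free-energy
#' accumulation. This check verifies, per frame, that the innermost design
#' base pair of every arm still satisfies the geometric pairing criterion
#' of [detect_base_pairs()].
#'
#' @param trajectory an `oxdna_trajectory`.
#' @param junction a [junction_spec()].
#' @param cutoff,antiparallel_threshold,base_site_offset as in
#'   [detect_base_pairs()].
#' @return Logical vector, `TRUE` for frames whose midpoint pairing is
#'   intact.
#' @export
check_branch_migration <- function(trajectory, junction, cutoff = 0.45,
                                   antiparallel_threshold = 0.7,
                                   base_site_offset = 0.4 * oxdna_length_unit) {
  inner <- do.call(rbind, lapply(junction$arms,
                                 function(a) a$pairs[1, , drop = FALSE]))
  vapply(trajectory$frames, function(fr) {
    site <- fr$pos + base_site_offset * fr$a1
    ok <- TRUE
    for (r in seq_len(nrow(inner))) {
      i <- inner[r, 1]; j <- inner[r, 2]
      dr <- fr$pos[j, ] - fr$pos[i, ]
      ok <- ok &&
        vnorm(site[i, ] - site[j, ]) < cutoff &&
        sum(fr$a3[i, ] * fr$a3[j, ]) < -antiparallel_threshold &&
        sum(fr$a1[i, ] * dr) > 0 && sum(fr$a1[j, ] * -dr) > 0
      if (!ok) break
    }
    ok
  }, logical(1))
}

#' Write an angle-sample table as delimited text
#'
#' @param samples a data frame as from [junction_angle_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_angle_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
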