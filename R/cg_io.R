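#' Length of one oxDNA simulation unit in nanometres
#'
#' All file I/O converts between oxDNA simulation units and the package's
#' internal nanometre convention with this single constant; nothing else in
#' the package ever sees simulation units.
#'
#' @export
oxdna_length_unit <- 0.8518

#' Construct a coarse-grained topology
#'
#' A topology records, for every nucleotide, its strand membership, base
#' identity and backbone connectivity. Indices are 1-based; `NA` means "no
#' neighbour" (a strand end). The oxDNA file convention (0-based, -1 for
#' none) is translated at the file boundary by [read_oxdna_topology()] and
#' [write_oxdna_topology()].
#'
#' @param strand_id integer vector, 1-based strand id per nucleotide.
#' @param base character vector of bases (A/C/G/T).
#' @param neighbor_3p,neighbor_5p integer vectors of neighbour indices in
#'   the 3' and 5' directions (`NA` = none).
#' @param circular integer vector of strand ids that form closed cycles.
#' @param validate if `TRUE` (default) run [validate_topology()].
#' @return An object of class `oxdna_topology`.
#' @export
oxdna_topology <- function(strand_id, base, neighbor_3p, neighbor_5p,
                           circular = integer(), validate = TRUE) {
  n <- length(strand_id)
  stopifnot(length(base) == n, length(neighbor_3p) == n,
            length(neighbor_5p) == n)
  topo <- structure(
    list(n_nucleotides = n,
         n_strands = length(unique(strand_id)),
         strand_id = as.integer(strand_id),
         base = toupper(as.character(base)),
         neighbor_3p = as.integer(neighbor_3p),
         neighbor_5p = as.integer(neighbor_5p),
         circular_strands = as.integer(circular)),
    class = "oxdna_topology")
  if (validate) validate_topology(topo)
  topo
}

#' Validate a topology's internal consistency
#'
#' Checks that 3'/5' neighbour links are mutually consistent (if i's 3'
#' neighbour is j, then j's 5' neighbour is i), that neighbours share a
#' strand, and that each strand is a single connected path or cycle.
#'
#' @param topology an `oxdna_topology`.
#' @return The topology, invisibly; stops with an informative error on
#'   inconsistency.
#' @export
validate_topology <- function(topology) {
  n <- topology$n_nucleotides
  n3 <- topology$neighbor_3p
  n5 <- topology$neighbor_5p
  for (nb in list(n3, n5)) {
    bad <- which(!is.na(nb) & (nb < 1 | nb > n))
    if (length(bad))
      stop("neighbor index out of range at nucleotide(s) ",
           paste(bad, collapse = ", "))
  }
  i <- which(!is.na(n3))
  if (any(is.na(n5[n3[i]]) | n5[n3[i]] != i))
    stop("inconsistent neighbor links: 3' neighbor does not point back ",
         "at nucleotide(s) ",
         paste(i[is.na(n5[n3[i]]) | n5[n3[i]] != i], collapse = ", "))
  j <- which(!is.na(n5))
  if (any(is.na(n3[n5[j]]) | n3[n5[j]] != j))
    stop("inconsistent neighbor links: 5' neighbor does not point back ",
         "at nucleotide(s) ",
         paste(j[is.na(n3[n5[j]]) | n3[n5[j]] != j], collapse = ", "))
  if (any(!is.na(n3) & topology$strand_id[ifelse(is.na(n3), 1L, n3)] !=
          topology$strand_id))
    stop("backbone link crosses strands")
  # each strand is one path or one cycle
  for (s in unique(topology$strand_id)) {
    idx <- which(topology$strand_id == s)
    ends5 <- sum(is.na(n5[idx]))
    ends3 <- sum(is.na(n3[idx]))
    if (!((ends5 == 1 && ends3 == 1) || (ends5 == 0 && ends3 == 0)))
      stop("strand ", s, " is not a single path or cycle")
    if (ends5 == 0 && !(s %in% topology$circular_strands))
      stop("strand ", s, " is a cycle but not declared circular")
  }
  invisible(topology)
}

#' @export
print.oxdna_topology <- function(x, ...) {
  cat("oxDNA topology:", x$n_nucleotides, "nucleotides in",
      x$n_strands, "strand(s)\n")
  invisible(x)
}

#' Walk a strand 5' to 3'
#'
#' @param topology an `oxdna_topology`.
#' @param strand strand id.
#' @return integer vector of nucleotide indices from the 5' end (or from an
#'   arbitrary start for circular strands) following 3' links.
#' @export
strand_path <- function(topology, strand) {
  idx <- which(topology$strand_id == strand)
  if (!length(idx)) stop("no such strand: ", strand)
  start <- idx[is.na(topology$neighbor_5p[idx])]
  circular <- length(start) == 0L
  cur <- if (circular) idx[1] else start[1]
  out <- integer(0)
  repeat {
    out <- c(out, cur)
    nxt <- topology$neighbor_3p[cur]
    if (is.na(nxt) || (circular && nxt == out[1])) break
    cur <- nxt
    if (length(out) > length(idx)) stop("strand ", strand, " walk did not terminate")
  }
  out
}

#' Construct a configuration frame
#'
#' @param pos n x 3 matrix of nucleotide positions (nm).
#' @param a1 n x 3 matrix of base versors (unit, backbone-to-base face).
#' @param a3 n x 3 matrix of helix-normal/stacking versors (unit).
#' @param box length-3 simulation box (nm).
#' @param time time label of the frame.
#' @param vel,angvel optional n x 3 velocity matrices; carried through I/O,
#'   never interpreted by any analysis.
#' @return An object of class `oxdna_frame`.
#' @export
oxdna_frame <- function(pos, a1, a3, box = c(100, 100, 100), time = 0,
                        vel = NULL, angvel = NULL) {
  pos <- as.matrix(pos); a1 <- as.matrix(a1); a3 <- as.matrix(a3)
  n <- nrow(pos)
  stopifnot(ncol(pos) == 3, nrow(a1) == n, nrow(a3) == n,
            length(box) == 3, all(box > 0))
  if (is.null(vel)) vel <- matrix(0, n, 3)
  if (is.null(angvel)) angvel <- matrix(0, n, 3)
  norm1 <- sqrt(rowSums(a1^2)); norm3 <- sqrt(rowSums(a3^2))
  if (any(abs(norm1 - 1) > 1e-6) || any(abs(norm3 - 1) > 1e-6))
    stop("versors must be unit vectors (|a1|, |a3| = 1 within 1e-6)")
  ortho <- abs(rowSums(a1 * a3))
  if (any(ortho > 1e-3))
    warning(sum(ortho > 1e-3), " nucleotide(s) with a1 . a3 > 1e-3 ",
            "(versors not orthogonal)")
  structure(list(time = time, box = as.numeric(box), pos = pos,
                 a1 = a1, a3 = a3, vel = vel, angvel = angvel),
            class = "oxdna_frame")
}

#' @export
print.oxdna_frame <- function(x, ...) {
  cat("oxDNA frame: t =", x$time, ",", nrow(x$pos), "nucleotides, box =",
      paste(signif(x$box, 4), collapse = " x "), "nm\n")
  invisible(x)
}

#' Construct a trajectory
#'
#' @param topology shared `oxdna_topology`.
#' @param frames list of `oxdna_frame`s, each with one state per nucleotide.
#' @return An object of class `oxdna_trajectory`.
#' @export
oxdna_trajectory <- function(topology, frames) {
  for (k in seq_along(frames))
    if (nrow(frames[[k]]$pos) != topology$n_nucleotides)
      stop("frame ", k, " has ", nrow(frames[[k]]$pos),
           " states but topology has ", topology$n_nucleotides)
  structure(list(topology = topology, frames = frames),
            class = "oxdna_trajectory")
}

#' @export
print.oxdna_trajectory <- function(x, ...) {
  cat("oxDNA trajectory:", length(x$frames), "frame(s) of",
      x$topology$n_nucleotides, "nucleotides\n")
  invisible(x)
}

#' @export
length.oxdna_trajectory <- function(x) length(x$frames)

#' Read an oxDNA topology file
#'
#' Line 1 holds the nucleotide and strand counts; each subsequent line holds
#' `strand base neighbor_3p neighbor_5p` with 0-based indices and -1 for
#' "no neighbour" (converted to 1-based/`NA` internally).
#'
#' @param path file path.
#' @return An `oxdna_topology`.
#' @export
read_oxdna_topology <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) < 2 || anyNA(suppressWarnings(as.integer(header[1:2]))))
    stop("malformed topology header (line 1): expected two counts")
  n <- as.integer(header[1]); ns <- as.integer(header[2])
  if (length(lines) - 1L != n)
    stop("topology header declares ", n, " nucleotides but file has ",
         length(lines) - 1L, " records")
  rec <- strsplit(trimws(lines[-1]), "\\s+")
  bad <- which(lengths(rec) != 4)
  if (length(bad))
    stop("malformed topology line ", bad[1] + 1L, ": expected 4 fields")
  m <- do.call(rbind, rec)
  strand <- suppressWarnings(as.integer(m[, 1]))
  n3 <- suppressWarnings(as.integer(m[, 3]))
  n5 <- suppressWarnings(as.integer(m[, 4]))
  if (anyNA(strand) || anyNA(n3) || anyNA(n5))
    stop("malformed topology line ",
         which(is.na(strand) | is.na(n3) | is.na(n5))[1] + 1L,
         ": non-numeric field")
  n3 <- ifelse(n3 < 0, NA_integer_, n3 + 1L)
  n5 <- ifelse(n5 < 0, NA_integer_, n5 + 1L)
  # detect circular strands (no 5' end)
  circ <- integer(0)
  for (s in unique(strand)) if (!any(is.na(n5[strand == s]))) circ <- c(circ, s)
  topo <- oxdna_topology(strand, m[, 2], n3, n5, circular = circ)
  if (topo$n_strands != ns)
    warning("header declares ", ns, " strands; found ", topo$n_strands)
  topo
}

#' Write an oxDNA topology file
#'
#' @param topology an `oxdna_topology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_oxdna_topology <- function(topology, path) {
  to_file <- function(x) ifelse(is.na(x), -1L, x - 1L)
  lines <- c(paste(topology$n_nucleotides, topology$n_strands),
             paste(topology$strand_id, topology$base,
                   to_file(topology$neighbor_3p),
                   to_file(topology$neighbor_5p)))
  writeLines(lines, path)
  invisible(path)
}

# Parse one "key = values" configuration header line; tolerates the classic
# (t, b, E) and any permuted header order.
parse_conf_header <- function(line) {
  m <- regmatches(line, regexec("^\\s*([a-zA-Z]+)\\s*=\\s*(.*)$", line))[[1]]
  if (length(m) < 3) return(NULL)
  vals <- suppressWarnings(as.numeric(strsplit(trimws(m[3]), "\\s+")[[1]]))
  list(key = tolower(m[2]), values = vals)
}

#' Read an oxDNA configuration/trajectory file
#'
#' Each frame consists of header lines (`t = ...`, `b = ...`, `E = ...`, in
#' any order) followed by one 15-number line per nucleotide: position, the
#' a1 and a3 versors, velocity and angular velocity. Lengths are converted
#' from simulation units to nm via `length_unit`.
#'
#' @param path file path.
#' @param topology the matching `oxdna_topology` (fixes the per-frame
#'   nucleotide count).
#' @param length_unit nm per file length unit; default [oxdna_length_unit].
#' @return An `oxdna_trajectory`.
#' @export
read_oxdna_trajectory <- function(path, topology,
                                  length_unit = oxdna_length_unit) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- topology$n_nucleotides
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    hdr <- list(t = 0, b = c(1, 1, 1), e = c(0, 0, 0))
    seen <- FALSE
    while (i <= length(lines)) {
      h <- parse_conf_header(lines[i])
      if (is.null(h)) break
      hdr[[h$key]] <- h$values
      seen <- TRUE
      i <- i + 1L
    }
    if (!seen) stop("expected a frame header at line ", i)
    kf <- length(frames) + 1L
    if (i + n - 1L > length(lines))
      stop("truncated frame ", kf, ": expected ", n, " nucleotide lines, got ",
           length(lines) - i + 1L)
    block <- lines[i:(i + n - 1L)]
    if (any(grepl("=", block, fixed = TRUE)))
      stop("truncated frame ", kf, ": header found inside nucleotide block")
    num <- suppressWarnings(
      matrix(as.numeric(unlist(strsplit(trimws(block), "\\s+"))),
             nrow = n, byrow = TRUE))
    if (ncol(num) != 15 || anyNA(num))
      stop("parse error in frame ", kf,
           ": expected 15 numeric fields per nucleotide line")
    frames[[kf]] <- oxdna_frame(
      pos = num[, 1:3] * length_unit,
      a1 = num[, 4:6], a3 = num[, 7:9],
      vel = num[, 10:12] * length_unit, angvel = num[, 13:15],
      box = hdr$b * length_unit, time = hdr$t[1])
    i <- i + n
  }
  if (!length(frames)) stop("no frames found in ", path)
  oxdna_trajectory(topology, frames)
}

#' Write an oxDNA configuration/trajectory file
#'
#' @param trajectory an `oxdna_trajectory` (or a single `oxdna_frame` plus
#'   `topology`).
#' @param path output file path.
#' @param length_unit nm per file length unit; default [oxdna_length_unit].
#' @return `path`, invisibly.
#' @export
write_oxdna_trajectory <- function(trajectory, path,
                                   length_unit = oxdna_length_unit) {
  fmt <- function(m) apply(m, 1, function(r) paste(sprintf("%.10g", r),
                                                   collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in trajectory$frames) {
    writeLines(c(sprintf("t = %.10g", fr$time),
                 sprintf("b = %s", paste(sprintf("%.10g", fr$box / length_unit),
                                         collapse = " ")),
                 "E = 0 0 0"), con)
    m <- cbind(fr$pos / length_unit, fr$a1, fr$a3,
               fr$vel / length_unit, fr$angvel)
    writeLines(fmt(m), con)
  }
  invisible(path)
}

#' Construct a base-pair map
#'
#' @param i,j paired nucleotide indices; stored with `i < j`.
#' @param provenance `"design-derived"` or `"geometry-derived"`.
#' @return A data frame of class `base_pair_map` with columns `i`, `j`.
#' @export
base_pair_map <- function(i, j, provenance = c("design-derived",
                                               "geometry-derived")) {
  provenance <- match.arg(provenance)
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (anyDuplicated(c(lo, hi)))
    stop("a nucleotide index appears in more than one base pair")
  out <- data.frame(i = as.integer(lo), j = as.integer(hi))
  out <- out[order(out$i), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("base_pair_map", "data.frame"),
            provenance = provenance)
}

#' Detect base pairs geometrically
#'
#' A permissive geometric proxy for hydrogen bonding: two nucleotides are
#' candidate partners when their base interaction sites (position +
#' `base_site_offset` along a1) lie within `cutoff`, their a3 versors are
#' anti-aligned (dot below `-antiparallel_threshold`), their a1 versors face
#' each other, they are on different strands or more than 3 bases apart on
#' the same strand, and their bases are Watson-Crick complementary (when
#' both identities are informative). Candidates are accepted greedily by
#' ascending site distance (ties broken by lowest index), each nucleotide
#' entering at most one pair.
#'
#' @param frame an `oxdna_frame`.
#' @param topology the matching topology.
#' @param cutoff base-site distance cutoff in nm.
#' @param antiparallel_threshold minimum anti-alignment of a3 versors.
#' @param base_site_offset nm from nucleotide position to base site along a1.
#' @return A `base_pair_map` with provenance `"geometry-derived"`.
#' @export
detect_base_pairs <- function(frame, topology, cutoff = 0.45,
                              antiparallel_threshold = 0.7,
                              base_site_offset = 0.4 * oxdna_length_unit) {
  n <- nrow(frame$pos)
  stopifnot(n == topology$n_nucleotides)
  site <- frame$pos + base_site_offset * frame$a1
  wc <- c(A = "T", T = "A", C = "G", G = "C")
  # candidate pairs within the cutoff
  d2 <- as.matrix(stats::dist(site))^2
  diag(d2) <- Inf
  cand <- which(upper.tri(d2) & d2 < cutoff^2, arr.ind = TRUE)
  if (!nrow(cand))
    return(base_pair_map(integer(0), integer(0), "geometry-derived"))
  i <- cand[, 1]; j <- cand[, 2]
  keep <- rep(TRUE, length(i))
  # strand separation rule
  same <- topology$strand_id[i] == topology$strand_id[j]
  keep <- keep & (!same | abs(i - j) > 3)
  # anti-aligned stacking versors
  keep <- keep & rowSums(frame$a3[i, , drop = FALSE] *
                         frame$a3[j, , drop = FALSE]) < -antiparallel_threshold
  # base versors facing each other (tiny tolerance so an exactly
  # perpendicular versor does not pass on floating-point noise)
  dr <- frame$pos[j, , drop = FALSE] - frame$pos[i, , drop = FALSE]
  keep <- keep & rowSums(frame$a1[i, , drop = FALSE] * dr) > 1e-9 &
    rowSums(frame$a1[j, , drop = FALSE] * -dr) > 1e-9
  # Watson-Crick complementarity when informative
  bi <- topology$base[i]; bj <- topology$base[j]
  informative <- bi %in% names(wc) & bj %in% names(wc)
  keep <- keep & (!informative | wc[bi] == bj)
  i <- i[keep]; j <- j[keep]
  if (!length(i))
    return(base_pair_map(integer(0), integer(0), "geometry-derived"))
  dd <- d2[cbind(i, j)]
  ord <- order(dd, pmin(i, j), pmax(i, j))
  used <- logical(n)
  pi <- integer(0); pj <- integer(0)
  for (k in ord) {
    if (!used[i[k]] && !used[j[k]]) {
      used[i[k]] <- used[j[k]] <- TRUE
      pi <- c(pi, i[k]); pj <- c(pj, j[k])
    }
  }
  base_pair_map(pi, pj, "geometry-derived")
}
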