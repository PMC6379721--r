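# caDNAno v2 design import: parse + validate the JSON, detect crossovers,
# build an initial configuration on the design lattice, and relax away
# pathological geometry with a capped-displacement surrogate descent.

slot_occupied <- function(slot) any(slot != -1L)

#' Parse a caDNAno v2 design file
#'
#' Reads the JSON, validates all slot cross-references, and infers the
#' lattice: honeycomb when every virtual helix satisfies the
#' `num %% 2 == (row + col) %% 2` parity convention, square otherwise (an
#' explicit `lattice` always wins, since caDNAno files do not declare it).
#'
#' @param path file path to a caDNAno v2 JSON file.
#' @param lattice `"auto"` (default), `"square"` or `"honeycomb"`.
#' @return An object of class `cadnano_design`: `lattice`, `n_positions`,
#'   and `vstrands`, a list of per-helix records with `num`, `row`, `col`,
#'   `scaf` and `stap` (n x 4 integer matrices of
#'   `(from_helix, from_pos, to_helix, to_pos)`, -1 = none), `skip` and
#'   `loop` integer vectors.
#' @export
parse_cadnano <- function(path, lattice = c("auto", "square", "honeycomb")) {
  lattice <- match.arg(lattice)
  if (!file.exists(path)) stop("no such file: ", path)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(js$format))
    stop("unsupported caDNAno format version ", js$format,
         " (only v2 'vstrands' files are supported)")
  if (is.null(js$vstrands) || !length(js$vstrands))
    stop("design has no virtual helices ('vstrands' missing or empty)")
  vh <- lapply(js$vstrands, function(v) {
    for (k in c("num", "row", "col", "scaf", "stap", "skip", "loop"))
      if (is.null(v[[k]])) stop("virtual helix missing field '", k, "'")
    tomat <- function(slots) {
      m <- do.call(rbind, lapply(slots, function(s) as.integer(unlist(s))))
      if (is.null(m) || ncol(m) != 4)
        stop("malformed slot array in helix ", v$num)
      m
    }
    list(num = as.integer(v$num), row = as.integer(v$row),
         col = as.integer(v$col), scaf = tomat(v$scaf),
         stap = tomat(v$stap), skip = as.integer(unlist(v$skip)),
         loop = as.integer(unlist(v$loop)))
  })
  npos <- unique(vapply(vh, function(v) nrow(v$scaf), 1L))
  if (length(npos) != 1)
    stop("virtual helices have differing position counts")
  nums <- vapply(vh, `[[`, 1L, "num")
  if (anyDuplicated(nums)) stop("duplicate virtual-helix num")
  # validate cross references
  dangling <- character(0)
  for (v in vh) for (type in c("scaf", "stap")) {
    m <- v[[type]]
    for (side in c(1L, 3L)) {
      h <- m[, side]; p <- m[, side + 1L]
      bad <- which(h != -1L & (!(h %in% nums) | p < 0L | p >= npos))
      if (length(bad))
        dangling <- c(dangling, sprintf("%s helix %d position %d",
                                        type, v$num, bad - 1L))
    }
  }
  if (length(dangling))
    stop("dangling slot reference(s): ", paste(dangling, collapse = "; "))
  if (lattice == "auto") {
    honey <- all(vapply(vh, function(v)
      v$num %% 2L == (v$row + v$col) %% 2L, logical(1)))
    lattice <- if (honey) "honeycomb" else "square"
  }
  structure(list(lattice = lattice, n_positions = npos, vstrands = vh),
            class = "cadnano_design")
}

#' @export
print.cadnano_design <- function(x, ...) {
  cat("caDNAno design:", length(x$vstrands), "virtual helices x",
      x$n_positions, "positions,", x$lattice, "lattice\n")
  invisible(x)
}

#' Occupied-slot bookkeeping of a design
#'
#' @param design a `cadnano_design`.
#' @return A list: `occupied` (occupied strand-slots, scaffold + staple),
#'   `skipped` (occupied slots at skip positions) and `loop_insertions`
#'   (extra nucleotides from loops at occupied slots). The nucleotide
#'   count of [build_initial()] is exactly
#'   `occupied - skipped + loop_insertions`.
#' @export
design_slot_counts <- function(design) {
  occupied <- skipped <- loops <- 0L
  for (v in design$vstrands) for (type in c("scaf", "stap")) {
    occ <- apply(v[[type]], 1, slot_occupied)
    occupied <- occupied + sum(occ)
    skipped <- skipped + sum(occ & v$skip == -1L)
    loops <- loops + sum(v$loop[occ & v$skip != -1L])
  }
  list(occupied = occupied, skipped = skipped, loop_insertions = loops)
}

#' Detect crossovers in a caDNAno design
#'
#' Every slot whose 3' link leaves its helix yields one crossover. Two
#' crossovers joining the same helix pair at adjacent positions are paired
#' as a double crossover; scaffold crossings are labelled
#' `"scaffold-seam"`.
#'
#' @param design a `cadnano_design`.
#' @return A data frame of class `crossover_set`: `helix_a`, `helix_b`
#'   (design nums, a < b), `position` (0-based design index), `kind`
#'   (`"staple"` or `"scaffold-seam"`) and `paired_with` (row index of the
#'   partner crossover or `NA`).
#' @export
detect_crossovers <- function(design) {
  rows <- list()
  for (v in design$vstrands) for (type in c("scaf", "stap")) {
    m <- v[[type]]
    xo <- which(m[, 3] != -1L & m[, 3] != v$num)
    for (p in xo)
      rows[[length(rows) + 1]] <-
        data.frame(helix_a = min(v$num, m[p, 3]),
                   helix_b = max(v$num, m[p, 3]),
                   position = p - 1L,
                   kind = if (type == "scaf") "scaffold-seam" else "staple")
  }
  if (!length(rows)) {
    out <- data.frame(helix_a = integer(0), helix_b = integer(0),
                      position = integer(0), kind = character(0),
                      paired_with = integer(0))
    return(structure(out, class = c("crossover_set", "data.frame")))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$helix_a, out$helix_b, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out$paired_with <- NA_integer_
  for (r in seq_len(nrow(out))) {
    if (!is.na(out$paired_with[r])) next
    partner <- which(is.na(out$paired_with) &
                       seq_len(nrow(out)) != r &
                       out$helix_a == out$helix_a[r] &
                       out$helix_b == out$helix_b[r] &
                       abs(out$position - out$position[r]) <= 1L)
    if (length(partner)) {
      partner <- partner[1]
      out$paired_with[r] <- partner
      out$paired_with[partner] <- r
    }
  }
  structure(out, class = c("crossover_set", "data.frame"))
}

# Lattice coordinates (y, z in nm) of a virtual helix.
lattice_yz <- function(v, lattice, s) {
  if (lattice == "square") c(v$col * s, v$row * s)
  else c(v$col * s * sqrt(3) / 2,
         s * (1.5 * v$row + 0.5 * ((v$row + v$col) %% 2)))
}

# Walk all strand paths of one type ("scaf"/"stap"); returns a list of
# paths, each a list(helix=, pos=, circular=) in 5'->3' order.
walk_paths <- function(design, type) {
  vh <- design$vstrands
  nums <- vapply(vh, `[[`, 1L, "num")
  bynum <- function(h) vh[[match(h, nums)]]
  occ <- lapply(vh, function(v) apply(v[[type]], 1, slot_occupied))
  names(occ) <- as.character(nums)
  visited <- lapply(occ, function(o) rep(FALSE, length(o)))
  paths <- list()
  walk_from <- function(h, p) {
    hs <- integer(0); ps <- integer(0)
    repeat {
      key <- as.character(h)
      if (visited[[key]][p + 1L]) break   # closed a cycle
      visited[[key]][p + 1L] <<- TRUE
      hs <- c(hs, h); ps <- c(ps, p)
      nxt <- bynum(h)[[type]][p + 1L, 3:4]
      if (nxt[1] == -1L) return(list(helix = hs, pos = ps, circular = FALSE))
      h <- nxt[1]; p <- nxt[2]
    }
    list(helix = hs, pos = ps, circular = TRUE)
  }
  # linear paths first (slots with no 5' link)
  for (v in vh) {
    starts <- which(occ[[as.character(v$num)]] & v[[type]][, 1] == -1L)
    for (p in starts)
      paths[[length(paths) + 1]] <- walk_from(v$num, p - 1L)
  }
  # remaining occupied slots belong to cycles
  for (v in vh) {
    key <- as.character(v$num)
    rem <- which(occ[[key]] & !visited[[key]])
    while (length(rem)) {
      paths[[length(paths) + 1]] <- walk_from(v$num, rem[1] - 1L)
      rem <- which(occ[[key]] & !visited[[key]])
    }
  }
  paths
}

#' Build an initial configuration from a caDNAno design
#'
#' Places every helix at its lattice coordinates and every nucleotide on an
#' ideal B-form backbone along the helix axis; the topology follows the
#' scaffold and staple routing through all crossovers, skips omit
#' nucleotides, and loops insert extra nucleotides at fractional axial
#' positions. The result is a plausible but locally strained starting
#' structure, to be passed through [relax_config()].
#'
#' @param design a `cadnano_design`.
#' @param scaffold_sequence optional character vector (or single string) of
#'   scaffold bases, applied along the scaffold path; defaults to a
#'   deterministic pseudo-random sequence from `seed`.
#' @param spec a [generator_spec()]; `helix_spacing` sets the lattice
#'   constant.
#' @param seed RNG seed for default sequences.
#' @return A list with `topology`, `frame`, `pairs` (design-derived
#'   [base_pair_map()]), `helices` (per-helix bp-index matrices for
#'   [helix_axes()]), `nucleotide_table` (helix/position/type per
#'   nucleotide) and `counts` (the [design_slot_counts()]).
#' @export
build_initial <- function(design, scaffold_sequence = NULL,
                          spec = generator_spec(), seed = 1) {
  s <- spec$helix_spacing
  scaf_paths <- walk_paths(design, "scaf")
  stap_paths <- walk_paths(design, "stap")
  if (!length(scaf_paths) && !length(stap_paths))
    stop("design has no occupied slots")
  vh <- design$vstrands
  nums <- vapply(vh, `[[`, 1L, "num")
  skipv <- lapply(vh, `[[`, "skip")
  loopv <- lapply(vh, `[[`, "loop")
  names(skipv) <- names(loopv) <- as.character(nums)
  # emit nucleotides strand by strand
  rec <- list()   # per nucleotide: helix, pos, sub (loop copy), type, strand
  strand_paths <- list()
  strand_id <- 0L
  circular <- integer(0)
  emit <- function(path, type) {
    strand_id <<- strand_id + 1L
    idxs <- integer(0)
    for (k in seq_along(path$helix)) {
      h <- path$helix[k]; p <- path$pos[k]; key <- as.character(h)
      if (skipv[[key]][p + 1L] == -1L) next
      copies <- 1L + max(0L, loopv[[key]][p + 1L])
      # 5'->3' axial sense at this slot (sign of the walk direction)
      sgn <- if (k < length(path$helix) && path$helix[k + 1L] == h)
               as.integer(sign(path$pos[k + 1L] - p))
             else if (k > 1L && path$helix[k - 1L] == h)
               as.integer(sign(p - path$pos[k - 1L]))
             else 1L
      if (sgn == 0L) sgn <- 1L
      for (m in seq_len(copies)) {
        rec[[length(rec) + 1L]] <<- list(helix = h, pos = p, sub = m - 1L,
                                         copies = copies, type = type,
                                         strand = strand_id, dir = sgn)
        idxs <- c(idxs, length(rec))
      }
    }
    if (path$circular) circular <<- c(circular, strand_id)
    strand_paths[[strand_id]] <<- idxs
  }
  for (p in scaf_paths) emit(p, "scaf")
  for (p in stap_paths) emit(p, "stap")
  n <- length(rec)
  if (!n) stop("design builds no nucleotides (everything skipped?)")
  helix <- vapply(rec, `[[`, 1L, "helix")
  pos <- vapply(rec, `[[`, 1L, "pos")
  sub <- vapply(rec, `[[`, 0L, "sub")
  copies <- vapply(rec, `[[`, 1L, "copies")
  type <- vapply(rec, `[[`, "", "type")
  strand <- vapply(rec, `[[`, 1L, "strand")
  dirs <- vapply(rec, `[[`, 1L, "dir")
  # geometry
  yz <- vapply(vh, lattice_yz, numeric(2), lattice = design$lattice, s = s)
  colnames(yz) <- as.character(nums)
  axial <- pos + sub / copies
  x <- axial * spec$rise
  alpha <- 2 * pi * axial / spec$pitch
  u <- cbind(0, cos(alpha), sin(alpha))
  center <- cbind(x, t(yz[, as.character(helix), drop = FALSE]))
  side <- ifelse(type == "scaf", 1, -1)
  posm <- center + side * spec$position_radius * u
  a1 <- -side * u
  a3 <- cbind(dirs, 0, 0)
  # sequence: scaffold from input or seeded random; staples complement the
  # scaffold nucleotide sharing their slot, random where unpaired
  base <- rep(NA_character_, n)
  scaf_idx <- which(type == "scaf")
  if (!is.null(scaffold_sequence)) {
    sq <- if (length(scaffold_sequence) == 1L)
            strsplit(scaffold_sequence, "")[[1]] else scaffold_sequence
    sq <- toupper(sq)
    if (length(sq) < length(scaf_idx))
      stop("scaffold sequence has ", length(sq), " bases; design needs ",
           length(scaf_idx))
    base[scaf_idx] <- sq[seq_along(scaf_idx)]
  } else {
    base[scaf_idx] <- with_seed(seed, random_sequence(length(scaf_idx)))
  }
  slot_key <- paste(helix, pos, sub)
  scaf_lookup <- stats::setNames(seq_along(scaf_idx), slot_key[scaf_idx])
  stap_idx <- which(type == "stap")
  partner <- scaf_lookup[slot_key[stap_idx]]
  base[stap_idx] <- ifelse(is.na(partner), "T",
                           dna_complement(base[scaf_idx[partner]]))
  # neighbour links from strand paths
  n3 <- rep(NA_integer_, n); n5 <- rep(NA_integer_, n)
  for (sid in seq_along(strand_paths)) {
    pth <- strand_paths[[sid]]
    if (length(pth) < 2) next
    k <- seq_len(length(pth) - 1L)
    n3[pth[k]] <- pth[k + 1L]
    n5[pth[k + 1L]] <- pth[k]
    if (sid %in% circular) {
      n3[pth[length(pth)]] <- pth[1]
      n5[pth[1]] <- pth[length(pth)]
    }
  }
  topo <- oxdna_topology(strand, base, n3, n5, circular = circular)
  box <- rep(max(x) - min(x) + 2 * max(abs(yz)) + 20, 3)
  frame <- oxdna_frame(posm, a1, a3, box = box)
  # base pairs + per-helix registration where both strands occupy a slot
  pi <- stap_idx[!is.na(partner)]
  pj <- scaf_idx[partner[!is.na(partner)]]
  pairs <- base_pair_map(pj, pi, "design-derived")
  helices <- lapply(nums, function(h) {
    sel <- which(helix[pj] == h)
    sel <- sel[order(pos[pj[sel]], sub[pj[sel]])]
    cbind(pj[sel], pi[sel])
  })
  names(helices) <- as.character(nums)
  list(topology = topo, frame = frame, pairs = pairs, helices = helices,
       nucleotide_table = data.frame(helix = helix, position = pos,
                                     sub = sub, type = type,
                                     strand = strand),
       counts = design_slot_counts(design))
}

#' Relax a configuration with a capped-displacement surrogate descent
#'
#' Initial structures built on the design lattice can contain stretched
#' backbones and overlapping nucleotides. This relaxation performs
#' steepest descent on a surrogate energy — harmonic backbone springs at
#' rest length `rest` plus a soft quadratic excluded-volume repulsion
#' below `rep_cutoff` — with every per-step displacement capped at
#' `cap_nm`, halving the step whenever the energy would rise, so the
#' reported energy trace is monotone non-increasing.
#'
#' @param frame an `oxdna_frame`.
#' @param topology the matching topology.
#' @param k_bond,rest backbone spring stiffness (energy/nm^2) and rest
#'   length (nm).
#' @param k_rep,rep_cutoff repulsion stiffness and onset distance (nm).
#' @param cap_nm per-step displacement cap (nm).
#' @param tol stop when the largest backbone deviation from `rest` falls
#'   below this (nm).
#' @param max_iters iteration cap.
#' @return The relaxed `oxdna_frame`, with attributes `energy_trace`
#'   (energy per accepted iteration) and `iterations`.
#' @export
relax_config <- function(frame, topology, k_bond = 10, rest = 0.64,
                         k_rep = 10, rep_cutoff = 0.6, cap_nm = 0.05,
                         tol = 0.1, max_iters = 5000) {
  n <- nrow(frame$pos)
  bi <- which(!is.na(topology$neighbor_3p))
  bj <- topology$neighbor_3p[bi]
  bonded_key <- c(paste(pmin(bi, bj), pmax(bi, bj)))
  energy_of <- function(p) {
    d <- sqrt(rowSums((p[bi, , drop = FALSE] - p[bj, , drop = FALSE])^2))
    # bi enumerates each physical bond exactly once (i -> its 3' neighbour)
    eb <- 0.5 * k_bond * sum((d - rest)^2)
    dm <- as.matrix(stats::dist(p))
    close <- which(upper.tri(dm) & dm < rep_cutoff, arr.ind = TRUE)
    if (nrow(close)) {
      key <- paste(close[, 1], close[, 2])
      close <- close[!(key %in% bonded_key), , drop = FALSE]
    }
    er <- if (nrow(close))
      0.5 * k_rep * sum((rep_cutoff - dm[close])^2) else 0
    if (!is.finite(eb + er)) {
      bad <- bi[!is.finite(d)]
      stop("non-finite surrogate energy (nucleotide indices ",
           paste(utils::head(bad, 5), collapse = ", "), ")")
    }
    list(total = eb + er, bonds = d, close = close, dm = dm)
  }
  gradient <- function(p, ev) {
    dvec <- p[bi, , drop = FALSE] - p[bj, , drop = FALSE]
    coef <- k_bond * (ev$bonds - rest) / pmax(ev$bonds, 1e-9)
    g <- matrix(0, n, 3)
    for (k in seq_along(bi)) {
      g[bi[k], ] <- g[bi[k], ] + coef[k] * dvec[k, ]
      g[bj[k], ] <- g[bj[k], ] - coef[k] * dvec[k, ]
    }
    cl <- ev$close
    if (nrow(cl)) for (k in seq_len(nrow(cl))) {
      i <- cl[k, 1]; j <- cl[k, 2]
      dij <- ev$dm[i, j]
      dir <- (p[i, ] - p[j, ]) / max(dij, 1e-9)
      f <- -k_rep * (rep_cutoff - dij)
      g[i, ] <- g[i, ] + f * dir
      g[j, ] <- g[j, ] - f * dir
    }
    g
  }
  p <- frame$pos
  ev <- energy_of(p)
  trace <- ev$total
  step <- cap_nm
  iter <- 0L
  while (iter < max_iters) {
    iter <- iter + 1L
    if (max(abs(ev$bonds - rest)) < tol && nrow(ev$close) == 0) break
    g <- gradient(p, ev)
    gmax <- max(sqrt(rowSums(g^2)))
    if (gmax < 1e-12) break
    accepted <- FALSE
    sc <- step
    for (half in 1:20) {
      disp <- -g * (sc / gmax)
      mags <- sqrt(rowSums(disp^2))
      over <- mags > cap_nm
      if (any(over)) disp[over, ] <- disp[over, ] * (cap_nm / mags[over])
      cand <- p + disp
      evc <- energy_of(cand)
      if (evc$total <= ev$total) {
        p <- cand; ev <- evc; accepted <- TRUE
        break
      }
      sc <- sc / 2
    }
    trace <- c(trace, ev$total)
    if (!accepted) break
  }
  out <- frame
  out$pos <- p
  attr(out, "energy_trace") <- trace
  attr(out, "iterations") <- iter
  out
}
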