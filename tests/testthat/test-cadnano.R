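# caDNAno design import, crossover detection, initial build and relaxation.

fixture_path <- function() {
  system.file("extdata", "two_helix_fixture.json", package = "origametry")
}

write_design_json <- function(vstrands, path = tempfile(fileext = ".json")) {
  jsonlite::write_json(list(name = "inline", vstrands = vstrands), path,
                       auto_unbox = TRUE)
  path
}

# a minimal single-helix design: scaffold only, positions 0..(n-1)
single_helix_vstrand <- function(n = 32, num = 0L, row = 0L, col = 0L) {
  scaf <- lapply(0:(n - 1), function(p)
    c(if (p == 0) c(-1L, -1L) else c(num, p - 1L),
      if (p == n - 1) c(-1L, -1L) else c(num, p + 1L)))
  list(num = num, row = row, col = col, scaf = scaf,
       stap = lapply(1:n, function(p) c(-1L, -1L, -1L, -1L)),
       skip = as.list(rep(0L, n)), loop = as.list(rep(0L, n)))
}

test_that("the bundled two-helix fixture parses with the expected content", {
  d <- parse_cadnano(fixture_path(), lattice = "square")
  expect_s3_class(d, "cadnano_design")
  expect_length(d$vstrands, 2)
  expect_equal(d$n_positions, 32)
  counts <- design_slot_counts(d)
  expect_equal(counts$occupied, 80)       # 64 scaffold + 16 staple slots
  expect_equal(counts$skipped, 3)
  expect_equal(counts$loop_insertions, 2)
})

test_that("crossovers are detected, paired and seam-labelled", {
  d <- parse_cadnano(fixture_path(), lattice = "square")
  xo <- detect_crossovers(d)
  expect_equal(nrow(xo), 3)               # hand count: 2 staple + 1 seam
  staple <- xo[xo$kind == "staple", ]
  expect_equal(sort(staple$position), c(15, 16))
  # the two staple crossovers form one double crossover
  expect_equal(staple$paired_with[1], which(xo$position == 16))
  expect_equal(staple$paired_with[2], which(xo$position == 15))
  seam <- xo[xo$kind == "scaffold-seam", ]
  expect_equal(seam$position, 31)
  expect_true(is.na(seam$paired_with))
  # a crossover-free design yields an empty set
  d1 <- parse_cadnano(write_design_json(list(single_helix_vstrand())))
  expect_equal(nrow(detect_crossovers(d1)), 0)
})

test_that("skip and loop semantics fix the built nucleotide count exactly", {
  d <- parse_cadnano(fixture_path(), lattice = "square")
  built <- build_initial(d, seed = 2)
  counts <- built$counts
  expect_equal(built$topology$n_nucleotides,
               counts$occupied - counts$skipped + counts$loop_insertions)
  expect_equal(built$topology$n_nucleotides, 79)
  expect_equal(built$topology$n_strands, 3)   # scaffold + 2 staples
  expect_silent(validate_topology(built$topology))
})

test_that("a single helix builds straight with ideal spacing", {
  d <- parse_cadnano(write_design_json(list(single_helix_vstrand(32))))
  built <- build_initial(d, seed = 1)
  expect_equal(built$topology$n_nucleotides, 32)
  expect_equal(built$topology$n_strands, 1)
  x <- built$frame$pos[, 1]
  expect_equal(max(x) - min(x), 31 * 0.34, tolerance = 1e-9)
  # backbone neighbour distances inside loose pre-relaxation bounds
  i <- which(!is.na(built$topology$neighbor_3p))
  j <- built$topology$neighbor_3p[i]
  dd <- sqrt(rowSums((built$frame$pos[i, ] - built$frame$pos[j, ])^2))
  expect_true(all(dd > 0.3 & dd < 1.2))
})

test_that("a provided scaffold sequence is applied and complemented", {
  d <- parse_cadnano(fixture_path(), lattice = "square")
  seq <- paste(rep(c("A", "C", "G", "T"), length.out = 70), collapse = "")
  built <- build_initial(d, scaffold_sequence = seq)
  scaf <- built$nucleotide_table$type == "scaf"
  expect_equal(built$topology$base[which(scaf)[1:4]], c("A", "C", "G", "T"))
  # paired staples carry the complement
  bp <- built$pairs
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_true(all(built$topology$base[bp$j] ==
                    comp[built$topology$base[bp$i]]))
  expect_error(build_initial(d, scaffold_sequence = "ACGT"),
               "scaffold sequence")
})

test_that("malformed designs are rejected with specific errors", {
  expect_error(parse_cadnano(write_design_json(list())), "no virtual")
  # caDNAno v3 style file
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "3.0", parts = list()), f,
                       auto_unbox = TRUE)
  expect_error(parse_cadnano(f), "unsupported")
  # dangling reference
  vs <- single_helix_vstrand(8)
  vs$scaf[[4]] <- c(0L, 2L, 5L, 4L)     # helix 5 does not exist
  expect_error(parse_cadnano(write_design_json(list(vs))),
               "dangling")
})

test_that("lattice inference follows the parity heuristic with override", {
  honey <- list(single_helix_vstrand(8, num = 0L, row = 0L, col = 0L),
                single_helix_vstrand(8, num = 1L, row = 0L, col = 1L))
  expect_identical(parse_cadnano(write_design_json(honey))$lattice,
                   "honeycomb")
  square <- list(single_helix_vstrand(8, num = 0L, row = 0L, col = 0L),
                 single_helix_vstrand(8, num = 1L, row = 0L, col = 2L))
  expect_identical(parse_cadnano(write_design_json(square))$lattice,
                   "square")
  expect_identical(parse_cadnano(write_design_json(honey),
                                 lattice = "square")$lattice, "square")
})

test_that("relaxation fixes stretched bonds and overlaps monotonically", {
  d <- make_duplex(10, seed = 6)
  fr <- d$frame
  # stretch one backbone link to ~5 nm
  fr$pos[5, ] <- fr$pos[5, ] + c(0, 0, 4.5)
  rel <- relax_config(fr, d$topology, max_iters = 3000)
  i <- 4; j <- 5
  expect_lt(sqrt(sum((rel$pos[5, ] - rel$pos[4, ])^2)), 1.0)
  trace <- attr(rel, "energy_trace")
  expect_true(all(diff(trace) <= 1e-12))
  # an already-relaxed configuration barely moves
  ideal <- relax_config(rel, d$topology, max_iters = 500)
  expect_lt(max(abs(ideal$pos - rel$pos)), 0.05)
  # overlapping nucleotides are pushed apart
  fr2 <- d$frame
  fr2$pos[15, ] <- fr2$pos[3, ] + c(0.01, 0, 0)
  rel2 <- relax_config(fr2, d$topology, max_iters = 3000)
  expect_gt(sqrt(sum((rel2$pos[15, ] - rel2$pos[3, ])^2)), 0.4)
})

test_that("relaxation is covariant with rigid motion of the input", {
  d <- parse_cadnano(fixture_path(), lattice = "square")
  built <- build_initial(d, seed = 2)
  rel <- relax_config(built$frame, built$topology, max_iters = 200)
  m <- random_rigid_motion()
  moved <- move_frame(built$frame, m$R, m$t)
  rel2 <- relax_config(moved, built$topology, max_iters = 200)
  back <- sweep((rel2$pos - matrix(m$t, nrow(rel2$pos), 3,
                                   byrow = TRUE)) %*% m$R, 2, 0, "+")
  expect_lt(max(abs(back - rel$pos)), 1e-6)
})
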