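# DCCM, radius of gyration, contact-probability maps, node degrees.

test_that("DCCM diagonal is 1 and constructed anticorrelation gives -1", {
  withr::with_seed(10, {
    disp <- rnorm(20)
  })
  coords <- lapply(disp, function(d) rbind(c(d, 0, 0), c(10 - d, 0, 0),
                                           c(20 + d, 1, 0)))
  tr <- make_bead_traj(coords)
  cc <- dccm(tr, "all")
  expect_equal(unname(diag(cc)), rep(1, 3))
  expect_equal(unname(cc[1, 2]), -1)
  expect_equal(unname(cc[1, 3]), 1)
  expect_true(isSymmetric(unclass(cc)))
  expect_true(all(abs(cc) <= 1 + 1e-12))
})

test_that("independent displacements give near-zero off-diagonals", {
  nfr <- 10000
  withr::with_seed(11, {
    co <- array(rnorm(nfr * 4 * 3), c(nfr, 4, 3))
  })
  co <- sweep(co, 2L, (1:4) * 20, `+`)   # separate the beads
  tr <- trajectory(taildyn:::.bead_atoms(4), co, 1)
  cc <- dccm(tr, "all")
  off <- cc[upper.tri(cc)]
  expect_true(all(abs(off) < 3 / sqrt(nfr) + 0.01))
})

test_that("DCCM matches the reference implementation and flags zero variance", {
  nfr <- 200
  withr::with_seed(12, {
    co <- array(rnorm(nfr * 5 * 3), c(nfr, 5, 3))
  })
  tr <- trajectory(taildyn:::.bead_atoms(5), co, 1)
  cc <- dccm(tr, "all")
  xyz <- t(vapply(seq_len(nfr), function(f) as.vector(t(co[f, , ])),
                  numeric(15)))
  ref <- bio3d::dccm.xyz(xyz)
  expect_equal(unclass(cc), unclass(ref), tolerance = 1e-6,
               ignore_attr = TRUE)
  co[, 2, ] <- 0
  expect_warning(cz <- dccm(trajectory(taildyn:::.bead_atoms(5), co, 1), "all"),
                 "zero")
  expect_true(all(is.na(cz[2, ])))
  expect_error(dccm(make_bead_traj(list(diag(3), diag(3))), "all"), "10 frames")
})

test_that("radius of gyration matches hand values and rigid-body invariance", {
  one <- make_bead_traj(list(matrix(c(3, 4, 5), 1)))
  expect_equal(radius_of_gyration(one), 0)
  two <- make_bead_traj(list(rbind(c(0, 0, 0), c(1, 0, 0))))
  expect_equal(radius_of_gyration(two, mass_weighted = FALSE), 0.5)
  expect_equal(radius_of_gyration(two, mass_weighted = TRUE), 0.5)  # equal masses
  # rigid motion leaves Rg constant
  base <- rbind(c(0, 0, 0), c(2, 1, 0), c(-1, 3, 2), c(4, -2, 1))
  th <- 0.6
  rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- make_bead_traj(list(base, base %*% t(rz) + 7))
  rg <- radius_of_gyration(tr)
  expect_equal(rg[1], rg[2])
})

test_that("contact-probability maps count frames and mask neighbours", {
  # residues 1,2,3 on a line; 1-3 touch in 1 of 4 frames, 1-2 always adjacent
  mkframe <- function(d13) rbind(c(0, 0, 0), c(3, 0, 0), c(d13, 0, 0))
  tr <- make_bead_traj(lapply(c(3.5, 10, 10, 10), mkframe))
  p <- contact_probability_map(tr, "all", criterion = "distance", cutoff = 4)
  expect_true(is.na(p["1", "2"]))          # adjacent pair masked
  expect_equal(unname(p["1", "3"]), 0.25)
  expect_equal(unname(p["3", "1"]), 0.25)
  # permanently touching non-adjacent pair has probability 1
  tr2 <- make_bead_traj(lapply(1:5, function(i) mkframe(3.0)))
  p2 <- contact_probability_map(tr2, "all", criterion = "distance")
  expect_equal(unname(p2["1", "3"]), 1)
  # monotone in the cutoff
  p5 <- contact_probability_map(tr, "all", criterion = "distance", cutoff = 5)
  ok <- !is.na(p) & !is.na(p5)
  expect_true(all(p5[ok] >= p[ok]))
})

test_that("the H-bond proxy needs hydrogens and honours its geometry", {
  # donor N-H ... acceptor O, ideal linear geometry, residues 1 and 3
  at <- data.frame(atom_id = 1:3, name = c("N", "H", "O"),
                   element = c("N", "H", "O"), residue_id = c(1L, 1L, 3L),
                   residue_name = "ALA", chain_id = "A")
  good <- rbind(c(0, 0, 0), c(1.0, 0, 0), c(2.9, 0, 0))
  bent <- rbind(c(0, 0, 0), c(1.0, 0, 0), c(1.0, 2.7, 0))  # 90 degrees at H
  co <- array(NA_real_, c(2, 3, 3)); co[1, , ] <- good; co[2, , ] <- bent
  tr <- trajectory(at, co, 1)
  p <- contact_probability_map(tr, "all", criterion = "hbond")
  expect_equal(unname(p["1", "3"]), 0.5)   # only the linear frame qualifies
  heavy <- at[at$element != "H", ]
  trh <- trajectory(heavy, co[, c(1, 3), , drop = FALSE], 1)
  expect_error(contact_probability_map(trh, "all", criterion = "hbond"),
               "distance")
})

test_that("node degrees sum incident edge probabilities", {
  ed <- data.frame(residue_a = c("a", "a"), residue_b = c("b", "c"),
                   probability = c(0.5, 0.7), class = "hbond")
  deg <- node_degree(ed)
  expect_equal(deg[["a"]], 1.2)
  expect_equal(deg[["b"]], 0.5)
  # empty table: all degrees zero
  expect_length(node_degree(ed[0, ]), 0L)
  # duplicated edges are rejected, never double-counted
  expect_error(node_degree(rbind(ed, ed[1, ])), "duplicated")
  expect_error(node_degree(data.frame(residue_a = "a", residue_b = "a",
                                      probability = 0.1, class = "x")),
               "self-edges")
})

test_that("degrees are additive over an interaction-class partition", {
  ed <- data.frame(residue_a = c(1, 1, 2, 3), residue_b = c(2, 3, 3, 4),
                   probability = c(0.2, 0.4, 0.6, 0.8),
                   class = c("hbond", "vdw", "hbond", "vdw"))
  total <- node_degree(ed)
  parts <- node_degree(ed, "hbond") + node_degree(ed, "vdw")
  expect_equal(total, parts)
})

test_that("edge tables round-trip through TSV and thresholded maps", {
  ed <- data.frame(residue_a = c(1L, 2L), residue_b = c(3L, 4L),
                   probability = c(0.25, 0.75), class = "contact")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_table(ed, f)
  back <- read_edge_table(f)
  expect_equal(back$probability, ed$probability)
  # probability-map -> edge table keeps only unmasked, above-threshold pairs
  mk <- function(d13) rbind(c(0, 0, 0), c(3, 0, 0), c(d13, 0, 0))
  tr <- make_bead_traj(lapply(c(3.5, 3.5, 10, 10), mk))
  p <- contact_probability_map(tr, "all", criterion = "distance")
  e2 <- edges_from_probability_map(p, min_probability = 0.1)
  expect_equal(nrow(e2), 1L)
  expect_equal(e2$probability, 0.5)
  expect_equal(node_degree(e2)[["1"]], 0.5)
})
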