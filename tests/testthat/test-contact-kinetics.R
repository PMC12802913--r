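# Contact timelines, bound-state classification, events, thermodynamics, maps.

# two-bead system: one "tail" bead orbiting / approaching one "DNA" bead at
# scripted distances
dist_traj <- function(dists) {
  at <- rbind(taildyn:::.bead_atoms(1, chain = "A"),
              within(taildyn:::.bead_atoms(1, chain = "B", element = "P",
                                           name = "P"), atom_id <- atom_id + 1L))
  co <- array(0, c(length(dists), 2, 3))
  co[, 1, 1] <- dists
  trajectory(at, co, frame_interval = 1)
}

test_that("contacts use a strict 4 Angstrom heavy-atom cutoff", {
  tr <- dist_traj(c(3.9, 4.0, 4.1, 3.9999))
  ct <- residue_dna_contacts(tr, "chain A", "chain B", cutoff = 4,
                             stride_ns = 1, burn_in_ns = 0)
  expect_equal(as.vector(ct$in_contact), c(TRUE, FALSE, FALSE, TRUE))
  # scripted crossing distances are recovered exactly
  d <- c(5, 4.5, 3.5, 2, 3.99, 4.01, 6)
  ct2 <- residue_dna_contacts(dist_traj(d), "chain A", "chain B", cutoff = 4,
                              stride_ns = 1, burn_in_ns = 0)
  expect_equal(as.vector(ct2$in_contact), d < 4)
  # monotone in the cutoff
  ct5 <- residue_dna_contacts(dist_traj(d), "chain A", "chain B", cutoff = 5,
                              stride_ns = 1, burn_in_ns = 0)
  expect_true(all(ct5$counts >= ct2$counts))
})

test_that("hydrogens are excluded and overlapping selections rejected", {
  at <- rbind(taildyn:::.bead_atoms(2, chain = "A"),
              within(taildyn:::.bead_atoms(1, chain = "A", element = "H",
                                           name = "H"), {
                       atom_id <- atom_id + 2L; residue_id <- 1L
                     }),
              within(taildyn:::.bead_atoms(1, chain = "B", element = "P",
                                           name = "P"), atom_id <- atom_id + 3L))
  co <- array(0, c(1, 4, 3))
  co[1, 1, 1] <- 10; co[1, 2, 1] <- 10   # heavy tail atoms far away
  co[1, 3, 1] <- 1                       # tail hydrogen close to DNA
  tr <- trajectory(at, co, 1)
  ct <- residue_dna_contacts(tr, "chain A", "chain B", stride_ns = 1, burn_in_ns = 0)
  expect_false(any(ct$in_contact))       # hydrogen contact does not count
  expect_error(residue_dna_contacts(tr, "chain A", "chain A",
                                    stride_ns = 1, burn_in_ns = 0), "overlap")
  suppressWarnings(
    expect_error(residue_dna_contacts(tr, "resid 999", "chain B",
                                      stride_ns = 1, burn_in_ns = 0)))
})

test_that("burn-in and stride arithmetic matches the frame bookkeeping", {
  tl <- bound_state_series(0:999, rep("bound", 1000))
  tr <- gen_toy_nucleosome_traj(tl, 12)
  ct <- residue_dna_contacts(tr, "chain A", "chain B", stride_ns = 1,
                             burn_in_ns = 200)
  expect_equal(nrow(ct$in_contact), 800L)
  expect_equal(ct$times_ns[1], 200)
  ct2 <- residue_dna_contacts(tr, "chain A", "chain B", stride_ns = 10,
                              burn_in_ns = 200)
  expect_equal(nrow(ct2$in_contact), 80L)
  expect_error(residue_dna_contacts(tr, "chain A", "chain B", stride_ns = 0.5,
                                    burn_in_ns = 0), "stride")
})

test_that("bound fraction and the floor-rule classification behave as specified", {
  # 36-residue tail with a controllable number of contacting residues
  n <- 36
  mk <- function(k) {
    tr <- gen_toy_nucleosome_traj(bound_state_series(0, "bound"), n)
    # exactly the first k tail beads sit on the DNA lattice
    tr$coords[1, seq_len(n), 3] <- 50
    if (k > 0) tr$coords[1, seq_len(k), 3] <- 3
    tr
  }
  for (k in c(0, 3, 4, 9, 36)) {
    ct <- residue_dna_contacts(mk(k), "chain A", "chain B", stride_ns = 1,
                               burn_in_ns = 0)
    expect_equal(bound_fraction(ct), k / n)
    st <- classify_bound_state(ct, 0.10)
    # unbound iff no more than floor(0.10 * 36) = 3 residues in contact
    expect_equal(st$state, if (k <= 3) "unbound" else "bound")
  }
})

test_that("event extraction reproduces hand-counted episodes", {
  st <- bound_state_series(0:6, c("bound", "bound", "bound", "unbound",
                                  "unbound", "bound", "bound"))
  ev <- extract_events(st, min_residence_ns = 0)
  expect_equal(ev$n_unbinding, 1L)
  expect_equal(ev$n_binding, 1L)
  b <- ev$episodes[ev$episodes$state == "bound", ]
  expect_equal(b$duration_ns, c(3, 2))
  expect_equal(b$end_truncated, c(FALSE, TRUE))
  expect_equal(ev$residence_ns, 3)           # censored final episode excluded
  # episodes tile the timeline without overlap
  expect_equal(ev$episodes$start_ns[-1], utils::head(ev$episodes$end_ns, -1))
  # all-bound: no events, single censored episode
  stb <- bound_state_series(0:9, rep("bound", 10))
  evb <- expect_warning(extract_events(stb, min_residence_ns = 0), NA)
  expect_equal(evb$n_unbinding, 0L)
  expect_equal(nrow(evb$episodes), 1L)
  expect_true(evb$episodes$end_truncated)
})

test_that("the residence filter merges short touches into unbound time", {
  alt <- bound_state_series(0:9, rep(c("bound", "unbound"), 5))
  expect_warning(ev <- extract_events(alt, min_residence_ns = 50), "residence")
  expect_length(ev$residence_ns, 0L)
  expect_equal(ev$n_unbinding, 0L)           # short touches removed entirely
  expect_warning(
    ev2 <- extract_events(alt, min_residence_ns = 50, count_short_events = TRUE),
    "residence")
  expect_equal(ev2$n_unbinding, 5L)
  # a long episode flanked by blips survives with its full duration
  s <- c(rep("unbound", 5), "bound", rep("unbound", 4), rep("bound", 60),
         rep("unbound", 30))
  ev3 <- extract_events(bound_state_series(seq_along(s) - 1, s),
                        min_residence_ns = 50)
  expect_equal(ev3$residence_ns, 60)
  expect_equal(ev3$n_unbinding, 1L)
})

test_that("ensemble Kd and binding free energy follow the frame-count definition", {
  eq <- bound_state_series(1:10, rep(c("bound", "unbound"), 5))
  th <- binding_thermodynamics(eq)
  expect_equal(th$Kd, 1)
  expect_equal(th$deltaG0_kcal_mol, 0)
  # 100 unbound / 900 bound at 310 K
  s <- bound_state_series(1:1000, c(rep("unbound", 100), rep("bound", 900)))
  th2 <- binding_thermodynamics(s, temperature = 310)
  expect_equal(th2$Kd, 1 / 9)
  expect_equal(th2$deltaG0_kcal_mol, 1.98720425e-3 * 310 * log(1 / 9))
  expect_equal(th2$deltaG0_kcal_mol, -1.3536, tolerance = 1e-4)
  # degenerate: all bound -> undefined, counts reported, no infinities
  ab <- binding_thermodynamics(bound_state_series(1:5, rep("bound", 5)))
  expect_false(ab$defined)
  expect_true(is.na(ab$Kd))
  expect_equal(ab$frames_bound, 5L)
})

test_that("Markov fixtures recover their ground-truth kinetics", {
  spec <- two_state_spec(k_on = 4e6, k_off = 1e6, dt = 1e-9, n_frames = 2e5,
                         seed = 31)
  ts <- gen_two_state_timeline(spec)
  th <- binding_thermodynamics(ts)
  expect_lt(abs(th$Kd / 0.25 - 1), 0.10)
  ev <- extract_events(ts, min_residence_ns = 0)
  expect_lt(abs(mean(ev$residence_ns) / 1000 - 1), 0.15)  # 1/k_off = 1000 ns
})

test_that("per-base-pair maps aggregate paired strands and conserve totals", {
  # 4-bp duplex: DNA residues 1..8, residue i pairs with 9 - i
  n_dna <- 8
  at <- rbind(taildyn:::.bead_atoms(1, chain = "A"),
              within(taildyn:::.bead_atoms(n_dna, chain = "B", element = "P",
                                           name = "P"), atom_id <- atom_id + 1L))
  co <- array(0, c(2, 1 + n_dna, 3))
  for (f in 1:2) co[f, 2:(1 + n_dna), 1] <- (1:n_dna) * 10
  co[, 1, 1] <- 30                # tail bead permanently on DNA residue 3 (bp 3)
  tr <- trajectory(at, co, 1)
  m <- per_bp_contact_map(tr, "chain A", "chain B", stride_ns = 1, burn_in_ns = 0)
  expect_equal(m$bp$mean_contacts, c(0, 0, 1, 0))
  # contact on residue 6 (the complementary strand) lands in the same bp 3 bin
  co2 <- co; co2[, 1, 1] <- 60
  m2 <- per_bp_contact_map(trajectory(at, co2, 1), "chain A", "chain B",
                           stride_ns = 1, burn_in_ns = 0)
  expect_equal(m2$bp$mean_contacts, c(0, 0, 1, 0))
  # conservation: sum over bp equals mean total atomic contacts per frame
  tl <- gen_two_state_timeline(two_state_spec(2e7, 2e7, 1e-9, 40, seed = 17))
  toy <- gen_toy_nucleosome_traj(tl, 16)
  ct <- residue_dna_contacts(toy, "chain A", "chain B", stride_ns = 1,
                             burn_in_ns = 0)
  mp <- per_bp_contact_map(toy, "chain A", "chain B", stride_ns = 1,
                           burn_in_ns = 0)
  expect_equal(sum(mp$bp$mean_contacts), mean(rowSums(ct$counts)))
  # unknown nucleotide in the pairing map is an error
  expect_error(per_bp_contact_map(tr, "chain A", "chain B",
                                  bp_pairing = c(`1` = 1), stride_ns = 1,
                                  burn_in_ns = 0), "pairing")
  # empty contact set gives an all-zero map
  far <- co; far[, 1, 2] <- 500
  m0 <- per_bp_contact_map(trajectory(at, far, 1), "chain A", "chain B",
                           stride_ns = 1, burn_in_ns = 0)
  expect_true(all(m0$bp$mean_contacts == 0))
})

test_that("end-to-end toy pipeline reproduces scripted kinetics exactly", {
  spec <- two_state_spec(k_on = 1e7, k_off = 1e7, dt = 1e-9, n_frames = 400,
                         seed = 77)
  tl <- gen_two_state_timeline(spec)
  tr <- gen_toy_nucleosome_traj(tl, 36)
  st <- classify_bound_state(residue_dna_contacts(tr, "chain A", "chain B",
                                                  stride_ns = 1, burn_in_ns = 0))
  expect_identical(st$state, tl$state)
  ev_direct <- extract_events(tl, min_residence_ns = 0)
  ev_pipe <- extract_events(st, min_residence_ns = 0)
  expect_equal(ev_pipe$n_unbinding, ev_direct$n_unbinding)
  expect_equal(ev_pipe$residence_ns, ev_direct$residence_ns)
})
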