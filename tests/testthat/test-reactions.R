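test_that("bond perception follows the covalent-radius rule", {
  h2 <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0.70, 0, 0)))
  expect_equal(nrow(perceive_bonds(h2)$bonds), 1)
  he2 <- geometry(c("He", "He"), rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_equal(nrow(perceive_bonds(he2)$bonds), 0)
  w <- geometry(c("O", "H", "H"),
                rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
  g <- perceive_bonds(w)
  # exactly the two O-H bonds: O-H distances < 1.2*(0.66+0.31), H..H above
  # 1.2*(0.31+0.31)
  expect_equal(nrow(g$bonds), 2)
  expect_true(all(g$bonds[, 1] == 1))
  expect_length(g$fragments, 1)
})

test_that("canonical SMILES are deterministic and atom-order independent", {
  ch4 <- geometry(c("C", "H", "H", "H", "H"),
                  rbind(c(0, 0, 0), c(0.63, 0.63, 0.63),
                        c(-0.63, -0.63, 0.63), c(-0.63, 0.63, -0.63),
                        c(0.63, -0.63, -0.63)))
  expect_equal(to_canonical_smiles(ch4), "C")
  perm <- c(3, 1, 5, 2, 4)
  ch4p <- geometry(ch4$elements[perm], ch4$coords[perm, ])
  expect_identical(to_canonical_smiles(ch4p), to_canonical_smiles(ch4))
})

test_that("metal atoms are removed before SMILES conversion when requested", {
  # Pd flanked by two widely separated HF ligand stand-ins
  sys <- geometry(c("Pd", "F", "H", "F", "H"),
                  rbind(c(0, 0, 0),
                        c(2.1, 0, 0), c(3.0, 0, 0),
                        c(-2.1, 0, 0), c(-3.0, 0, 0)))
  with_metal <- to_canonical_smiles(sys)
  without <- to_canonical_smiles(sys, drop_metals = TRUE)
  expect_match(with_metal, "Pd")
  expect_false(grepl("Pd", without))
  expect_equal(without, "F.F")
})

test_that("charged species get heuristic formal charges", {
  # ethoxide-like fragment: C-C-O with a total charge of -1 on the O
  etho <- geometry(c("C", "C", "O"),
                   rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.2, 0)),
                   charge = -1L)
  smi <- to_canonical_smiles(etho)
  expect_match(smi, "O-", fixed = TRUE)
})

test_that("trajectory minima are located with the endpoint rule", {
  mk <- function(e) {
    frames <- lapply(e, function(x) tagged_diatomic(x, r = 0.9))
    trajectory(frames, seq_along(e))
  }
  expect_equal(locate_minima(mk(c(0, 1, 0))), c(1, 3))
  expect_equal(locate_minima(mk(c(0, 1, 2, 3))), 1)
  expect_equal(locate_minima(mk(c(3, 1, 2, 0, 4))), c(2, 4))
  expect_equal(locate_minima(mk(c(1, 1, 1))), c(1, 3))
})

test_that("trajectories without species change give no events", {
  fx <- diatomic_fixture()
  vals <- seq(fx$re, 1.4 * fx$re, length.out = 6)
  fwd <- relaxed_scan(fx$geom, fx$coord, vals, fx$backend)
  bwd <- relaxed_scan(fwd$frames[[6]], fx$coord, rev(vals), fx$backend)
  tr <- stitch(bwd, relaxed_scan(bwd$frames[[1]], fx$coord, rev(vals),
                                 fx$backend))
  expect_length(extract_reactions(tr, fx$backend), 0)
})

test_that("a species change yields one event with the argmax TS", {
  # constructed trajectory: reactant complex frames, a ridge, product frames
  sys <- exchange_symmetric()
  react <- constrained_minimize(sys$geometry, list(), sys$backend)
  prod_coords <- rbind(c(-3.6, 0, 0), c(0, 0, 0), c(1.8, 0, 0))
  prod <- constrained_minimize(geometry(sys$elements, prod_coords,
                                        multiplicity = 2L),
                               list(), sys$backend)
  ridge <- constrained_minimize(
    sys$geometry, list(constraint(sys$coordinate, 2.6)), sys$backend)
  bump <- function(g, e) set_coords(g, g$coords, energy = e)
  frames <- list(bump(react, -0.171), bump(react, -0.1713),
                 bump(ridge, -0.12), bump(ridge, -0.064),
                 bump(ridge, -0.09), bump(prod, -0.1713),
                 bump(prod, -0.171))
  tr <- trajectory(frames, seq_along(frames))
  ev <- extract_reactions(tr, sys$backend)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$ts_frame_index, 4)
  expect_equal(ev[[1]]$reactant_smiles, sys$reactant_smiles)
  expect_equal(ev[[1]]$product_smiles, sys$product_smiles)
  expect_equal(ev[[1]]$reactant_frame_index, 2)
  expect_equal(ev[[1]]$product_frame_index, 6)

  # tie at the maximum resolves to the earliest frame
  frames2 <- frames
  frames2[[5]] <- bump(ridge, -0.064)
  ev2 <- extract_reactions(trajectory(frames2, seq_along(frames2)),
                           sys$backend)
  expect_equal(ev2[[1]]$ts_frame_index, 4)
})

test_that("aggregation applies the min-over-trajectories barrier rule", {
  kcal <- reaxplore:::HARTREE_TO_KCAL
  ref <- conformer_ensemble(list(tagged_diatomic(-12 / kcal),
                                 tagged_diatomic(-10 / kcal, r = 1.3)))
  ts_a <- tagged_diatomic(5 / kcal - 12 / kcal)
  ts_b <- tagged_diatomic(3 / kcal - 12 / kcal)
  ev <- list(fake_event("X", "Y", ts_a$energy, -13 / kcal, ts_a),
             fake_event("X", "Y", ts_b$energy, -14 / kcal, ts_b))
  tab <- aggregate_reactions(ev, ref)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$count, 2)
  expect_equal(tab$dE_act_kcal, 3)
  expect_equal(tab$dE_rxn_kcal, -2)
  # best TS of zero Hartree against a -12 kcal/mol reference: barrier 12
  ts0 <- tagged_diatomic(0)
  tab2 <- aggregate_reactions(list(fake_event("X", "Z", 0, -13 / kcal, ts0)),
                              ref)
  expect_equal(tab2$dE_act_kcal, 12)
  # flagged TS marks the row approximate but keeps it
  tab3 <- aggregate_reactions(
    list(fake_event("X", "W", ts_b$energy, -13 / kcal, ts_b, flagged = TRUE)),
    ref)
  expect_true(tab3$approximate)
})

test_that("reaction tables write CSV/JSON plus TS structures", {
  kcal <- reaxplore:::HARTREE_TO_KCAL
  ref <- conformer_ensemble(list(tagged_diatomic(-12 / kcal)))
  ts <- tagged_diatomic(-0.005)
  tab <- aggregate_reactions(list(fake_event("X", "Y", ts$energy,
                                             -13 / kcal, ts)), ref)
  dir <- withr::local_tempdir()
  out <- write_reaction_table(tab, dir)
  expect_true(file.exists(file.path(dir, "reactions.csv")))
  expect_true(file.exists(file.path(dir, "reactions.json")))
  expect_true(file.exists(file.path(dir, out$ts_xyz_path[1])))
  back <- utils::read.csv(file.path(dir, "reactions.csv"))
  expect_equal(back$dE_act_kcal, tab$dE_act_kcal, tolerance = 1e-5)
})
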