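test_that("step 1 recovers the equilibrium coordinate value", {
  fx <- diatomic_fixture(r = 0.9)
  cfg <- run_config(fx$geom, fx$coord, fx$backend, seed = 2L,
                    md_time_per_atom = 0.02)
  s1 <- step1_initialize(cfg)
  expect_equal(s1$q0, fx$re, tolerance = 0.01)
  expect_gte(length(s1$ensemble$members), 1)
})

test_that("step 1 finds both torsional conformers of the two-well chain", {
  # activating coordinate is a bond distance; the torsion is orthogonal to it
  # and must be explored by the equilibrium metadynamics
  tc <- torsion_chain()
  cfg <- run_config(tc$geometry, int_coord("distance", c(1, 2)), tc$backend,
                    seed = 11L, temperature = 300, md_time_per_atom = 0.25,
                    k_per_atom = 0.004, snapshot_interval = 50)
  s1 <- step1_initialize(cfg)
  expect_gte(length(s1$ensemble$members), 2)
  phis <- vapply(s1$ensemble$members,
                 function(m) measure(m, tc$dihedral), numeric(1))
  expect_setequal(unique(sign(round(phis / 10))), c(-1, 1))
})

test_that("input validation happens before any backend call", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "declares five atoms", "H 0 0 0", "H 1 0 0"), path)
  tripwire <- structure(list(), class = c("tripwire_backend", "backend"))
  registerS3method("backend_evaluate", "tripwire_backend",
                   function(backend, geom) stop("backend was called"),
                   envir = asNamespace("reaxplore"))
  cfg <- run_config(path, int_coord("distance", c(1, 2)), tripwire, seed = 1L)
  expect_error(step1_initialize(cfg), "ends early")
})

test_that("configuration validation rejects empty budgets and schedules", {
  fx <- diatomic_fixture()
  expect_error(run_config(fx$geom, fx$coord, fx$backend, budget = 0L),
               "budget")
  expect_error(run_config(fx$geom, fx$coord, fx$backend,
                          stretch_factors = numeric(0)), "stretch")
  expect_error(run_config(fx$geom, fx$coord, fx$backend, scan_step = -0.1),
               "scan_step")
})

test_that("the full workflow finds the exchange reaction and keeps its ledger", {
  sys <- exchange_symmetric()
  cfg <- exchange_run_config(sys, seed = 21L, stretch = c(1.3, 1.5),
                             budget = 6L)
  rep <- run_iacta(cfg)
  expect_s3_class(rep$table, "reaction_table")
  key <- paste(rep$table$reactant_smiles, rep$table$product_smiles, sep = ">>")
  expect_true(paste(sys$reactant_smiles, sys$product_smiles, sep = ">>") %in% key)
  # ledger conservation: every launched trajectory accounted for once
  expect_identical(rep$ledger[["launched"]],
                   rep$ledger[["completed"]] + rep$ledger[["flagged"]] +
                     rep$ledger[["failed"]])
  expect_lte(rep$ledger[["launched"]], cfg$budget)
  expect_gte(min(rep$table$count), 1)
  # every barrier uses the single step-1 reference
  eref <- min(ensemble_energies(rep$equilibrium_ensemble))
  for (i in seq_len(nrow(rep$table))) {
    ts_e <- attr(rep$table, "best_ts")[[i]]$energy
    expect_equal(rep$table$dE_act_kcal[i],
                 (ts_e - eref) * reaxplore:::HARTREE_TO_KCAL,
                 tolerance = 1e-9)
  }
})

test_that("scheduled metadynamics sampling doubles with atom count", {
  # same per-atom schedule on a 2-atom and a 4-atom system: the larger system
  # must collect twice the snapshots
  per_atom <- 0.1
  fx <- diatomic_fixture()
  m2 <- constrained_minimize(fx$geom, list(), fx$backend)
  tc <- torsion_chain()
  m4 <- constrained_minimize(tc$geometry, list(), tc$backend)
  bp <- bias_params(k = 0.008, alpha = 0.8, snapshot_interval = 25)
  n_snaps <- function(geom, backend) {
    md <- md_params(timestep = 0.5, temperature = 300,
                    total_time = per_atom * n_atoms(geom), seed = 4)
    length(run_metadynamics(geom, NULL, md, bp, backend))
  }
  expect_equal(n_snaps(m4, tc$backend), 2 * n_snaps(m2, fx$backend))
})

test_that("run artifacts land in the output directory", {
  sys <- exchange_symmetric()
  dir <- withr::local_tempdir()
  cfg <- exchange_run_config(sys, seed = 3L, stretch = 1.4, budget = 3L,
                             outdir = dir)
  rep <- run_iacta(cfg)
  expect_true(file.exists(file.path(dir, "reactions.csv")))
  expect_true(file.exists(file.path(dir, "reactions.json")))
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "equilibrium_ensemble.xyz")))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$ledger$launched,
               js$ledger$completed + js$ledger$flagged + js$ledger$failed)
})
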