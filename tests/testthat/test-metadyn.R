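test_that("bias kernel identities hold exactly", {
  set.seed(31)
  g <- geometry(rep(6L, 5), matrix(rnorm(15, sd = 1.2), 5, 3))
  bp <- bias_params(k = 0.01, alpha = 0.8)
  # empty history: exactly zero
  empty <- bias_energy_gradient(g, list(), bp)
  expect_identical(empty$energy, 0)
  expect_equal(empty$gradient, matrix(0, 5, 3))
  # self snapshot: exactly k
  self <- bias_energy_gradient(g, list(g), bp)
  expect_equal(self$energy, bp$k)
  # incompatible snapshot rejected
  other <- geometry(rep(7L, 5), matrix(rnorm(15), 5, 3))
  expect_error(bias_energy_gradient(g, list(other), bp), "element sequence")
})

test_that("bias gradient matches central finite differences", {
  set.seed(32)
  g <- geometry(rep(6L, 5), matrix(rnorm(15, sd = 1.2), 5, 3))
  snaps <- list(geometry(rep(6L, 5), matrix(rnorm(15, sd = 1.2), 5, 3)),
                geometry(rep(6L, 5), matrix(rnorm(15, sd = 1.2), 5, 3)))
  bp <- bias_params(k = 0.01, alpha = 0.8)
  gr <- bias_energy_gradient(g, snaps, bp)$gradient
  h <- 1e-6
  for (i in 1:5) for (k in 1:3) {
    xp <- g$coords; xp[i, k] <- xp[i, k] + h
    xm <- g$coords; xm[i, k] <- xm[i, k] - h
    fd <- (bias_energy_gradient(set_coords(g, xp), snaps, bp)$energy -
             bias_energy_gradient(set_coords(g, xm), snaps, bp)$energy) / (2 * h)
    expect_equal(gr[i, k], fd, tolerance = 1e-5)
  }
})

test_that("zero-temperature unbiased dynamics stay at a stationary point", {
  fx <- diatomic_fixture()
  m <- constrained_minimize(fx$geom, list(), fx$backend)
  md <- md_params(timestep = 0.5, temperature = 0, total_time = 0.1, seed = 1)
  snaps <- run_metadynamics(m, NULL, md, NULL, fx$backend)
  for (s in snaps) expect_lt(superpose_rmsd(s, m)$rmsd, 1e-3)
})

test_that("bias drives a torsional chain out of its well; plain MD stays", {
  tc <- torsion_chain()
  g <- constrained_minimize(tc$geometry, list(), tc$backend)
  phi_start <- measure(g, tc$dihedral)

  md_cold <- md_params(timestep = 0.5, temperature = 120, total_time = 0.3,
                       seed = 11)
  cold <- run_metadynamics(g, NULL, md_cold, NULL, tc$backend)
  phis_cold <- vapply(cold, function(s) measure(s, tc$dihedral), numeric(1))
  expect_true(all(sign(phis_cold) == sign(phi_start)))

  md_hot <- md_params(timestep = 0.5, temperature = 300, total_time = 1.0,
                      seed = 11)
  bp <- bias_params(k = 0.012, alpha = 0.8, snapshot_interval = 25)
  hot <- run_metadynamics(g, NULL, md_hot, bp, tc$backend)
  ens <- optimize_and_prune(hot, NULL, tc$backend)
  expect_gte(length(ens$members), 2)
  phis <- vapply(ens$members, function(m) measure(m, tc$dihedral), numeric(1))
  expect_setequal(unique(sign(round(phis))), c(-1, 1))
})

test_that("the MD restraint holds the activating coordinate near target", {
  sys <- exchange_symmetric()
  target <- 1.5 * 1.8
  act <- constrained_minimize(sys$geometry,
                              list(constraint(sys$coordinate, target)),
                              sys$backend)
  md <- md_params(timestep = 0.5, temperature = 300, total_time = 0.3,
                  seed = 5)
  bp <- bias_params(k = 0.006, alpha = 0.8, snapshot_interval = 25)
  snaps <- run_metadynamics(act, constraint(sys$coordinate, target, 10),
                            md, bp, sys$backend)
  expect_gt(length(snaps), 3)
  q <- vapply(snaps, function(s) measure(s, sys$coordinate), numeric(1))
  expect_true(all(abs(q - target) <= 0.05))
})

test_that("identical seeds reproduce identical snapshot lists", {
  tc <- torsion_chain()
  g <- constrained_minimize(tc$geometry, list(), tc$backend)
  md <- md_params(timestep = 0.5, temperature = 300, total_time = 0.2,
                  seed = 77)
  bp <- bias_params(k = 0.012, alpha = 0.8, snapshot_interval = 25)
  s1 <- run_metadynamics(g, NULL, md, bp, tc$backend)
  s2 <- run_metadynamics(g, NULL, md, bp, tc$backend)
  expect_length(s2, length(s1))
  for (j in seq_along(s1)) {
    expect_identical(s1[[j]]$coords, s2[[j]]$coords)
  }
  # a different seed decorrelates the trajectories
  md2 <- md_params(timestep = 0.5, temperature = 300, total_time = 0.2,
                   seed = 78)
  s3 <- run_metadynamics(g, NULL, md2, bp, tc$backend)
  expect_gt(superpose_rmsd(s1[[length(s1)]], s3[[length(s3)]])$rmsd, 1e-6)
})

test_that("the bias surface only fills in: stored snapshots keep energy >= k", {
  tc <- torsion_chain()
  g <- constrained_minimize(tc$geometry, list(), tc$backend)
  md <- md_params(timestep = 0.5, temperature = 300, total_time = 0.5,
                  seed = 13)
  bp <- bias_params(k = 0.012, alpha = 0.8, snapshot_interval = 25)
  snaps <- run_metadynamics(g, NULL, md, bp, tc$backend)
  state <- snaps[seq_len(min(length(snaps), bp$max_snapshots))]
  for (s in state) {
    expect_gte(bias_energy_gradient(s, state, bp)$energy, bp$k - 1e-12)
  }
})
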