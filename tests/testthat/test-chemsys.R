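test_that("internal coordinates measure distances, angles and dihedrals", {
  g <- geometry(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 1.5)))
  expect_equal(measure(g, int_coord("distance", c(1, 2))), 1.5)

  lin <- geometry(c("C", "C", "C"),
                  rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_equal(measure(lin, int_coord("angle", c(1, 2, 3))), 180)

  cis <- geometry(c("C", "C", "C", "C"),
                  rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  expect_equal(measure(cis, int_coord("dihedral", c(1, 2, 3, 4))), 0)

  # degenerate definitions error rather than returning NaN
  bad <- geometry(c("C", "C", "C"),
                  rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  expect_error(measure(bad, int_coord("angle", c(1, 2, 3))), "degenerate")
  collin4 <- geometry(rep(6L, 4),
                      rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)))
  expect_error(measure(collin4, int_coord("dihedral", 1:4)), "degenerate")
})

test_that("int_coord validates kind/index combinations", {
  expect_error(int_coord("distance", c(1, 2, 3)), "2 atom")
  expect_error(int_coord("angle", c(1, 1, 2)), "distinct")
  g <- geometry("H", matrix(0, 1, 3))
  expect_error(measure(g, int_coord("distance", c(1, 2))), "beyond")
})

test_that("superposition RMSD is zero on rigid copies and minimal overall", {
  w <- geometry(c("O", "H", "H"),
                rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
  expect_equal(superpose_rmsd(w, w)$rmsd, 0)
  expect_lt(superpose_rmsd(w, rigid_copy(w, 4))$rmsd, 1e-8)
  expect_error(superpose_rmsd(w, geometry(c("O", "H"), matrix(0, 2, 3))),
               "element sequences")
})

test_that("Kabsch RMSD matches a brute-force rotation-grid search", {
  # 3-atom pair with one displaced atom: exhaustive search over rotations
  a <- geometry(rep(6L, 3), rbind(c(0, 0, 0), c(1.4, 0, 0), c(0, 1.4, 0)))
  bc <- a$coords; bc[3, 3] <- bc[3, 3] + 0.6
  b <- geometry(rep(6L, 3), bc)
  ca <- sweep(a$coords, 2, colMeans(a$coords))
  cb <- sweep(b$coords, 2, colMeans(b$coords))
  euler_rmsd <- function(t) {
    R1 <- rbind(c(cos(t[1]), -sin(t[1]), 0), c(sin(t[1]), cos(t[1]), 0),
                c(0, 0, 1))
    R2 <- rbind(c(1, 0, 0), c(0, cos(t[2]), -sin(t[2])),
                c(0, sin(t[2]), cos(t[2])))
    R3 <- rbind(c(cos(t[3]), -sin(t[3]), 0), c(sin(t[3]), cos(t[3]), 0),
                c(0, 0, 1))
    d <- ca - cb %*% t(R1 %*% R2 %*% R3)
    sqrt(sum(d^2) / 3)
  }
  # exhaustive Euler-angle grid, then local polish of the best cell
  angles <- seq(-pi, pi, length.out = 37)
  best <- c(Inf, 0, 0, 0)
  for (t1 in angles) for (t2 in seq(0, pi, length.out = 19)) for (t3 in angles) {
    v <- euler_rmsd(c(t1, t2, t3))
    if (v < best[1]) best <- c(v, t1, t2, t3)
  }
  ref <- stats::optim(best[2:4], euler_rmsd, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))$value
  expect_equal(superpose_rmsd(a, b)$rmsd, ref, tolerance = 1e-6)
  expect_lte(superpose_rmsd(a, b)$rmsd, ref + 1e-9)
})

test_that("RMSD is symmetric and never exceeds the unaligned deviation", {
  set.seed(20)
  for (rep in 1:5) {
    a <- geometry(rep(8L, 6), matrix(rnorm(18, sd = 1.5), 6, 3))
    b <- geometry(rep(8L, 6), matrix(rnorm(18, sd = 1.5), 6, 3))
    r_ab <- superpose_rmsd(a, b)$rmsd
    expect_equal(r_ab, superpose_rmsd(b, a)$rmsd, tolerance = 1e-8)
    unaligned <- sqrt(sum((a$coords - b$coords)^2) / 6)
    expect_lte(r_ab, unaligned + 1e-12)
  }
})

test_that("RMSD gradient matches central finite differences", {
  set.seed(7)
  a <- geometry(rep(6L, 5), matrix(rnorm(15), 5, 3))
  b <- geometry(rep(6L, 5), matrix(rnorm(15), 5, 3))
  gr <- rmsd_gradient(a, b)
  h <- 1e-6
  for (i in 1:5) for (k in 1:3) {
    xp <- a$coords; xp[i, k] <- xp[i, k] + h
    xm <- a$coords; xm[i, k] <- xm[i, k] - h
    fd <- (superpose_rmsd(set_coords(a, xp), b)$rmsd -
             superpose_rmsd(set_coords(a, xm), b)$rmsd) / (2 * h)
    expect_equal(gr[i, k], fd, tolerance = 1e-5)
  }
  # translation invariance: net gradient sums to zero
  expect_lt(max(abs(colSums(gr))), 1e-10)
  # gradient at zero displacement is the documented zero matrix
  expect_equal(rmsd_gradient(a, a), matrix(0, 5, 3))
})

test_that("single-atom displacement concentrates the RMSD gradient", {
  a <- geometry(rep(6L, 4),
                rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0), c(0, 0, 1.5)))
  xc <- a$coords; xc[4, 3] <- xc[4, 3] + 0.4
  cur <- set_coords(a, xc)
  gr <- rmsd_gradient(cur, a)
  # dominant component on the displaced atom, pointing away from reference
  expect_gt(gr[4, 3], 0)
  expect_gt(abs(gr[4, 3]), max(abs(gr[1:3, ])))
})

test_that("rotational constants match the rigid-rotor closed form", {
  r <- 1.1
  g <- geometry(c("N", "N"), rbind(c(0, 0, 0), c(r, 0, 0)))
  b <- rotational_constants(g)
  # independent closed form: B = h / (8 pi^2 mu r^2), SI, reported in MHz
  mu_kg <- (14.007 / 2) * 1.66053906660e-27
  b_ref <- 6.62607015e-34 / (8 * pi^2 * mu_kg * (r * 1e-10)^2) / 1e6
  expect_equal(b[1], Inf)
  expect_equal(b[2], b_ref, tolerance = 1e-8)
  expect_equal(b[3], b_ref, tolerance = 1e-8)
  # rotation invariance
  b_rot <- rotational_constants(rigid_copy(g, 9))
  expect_equal(b[2:3], b_rot[2:3], tolerance = 1e-8)
  # B proportional to 1/I: doubling I (r *= sqrt 2) halves the constants
  g2 <- geometry(c("N", "N"), rbind(c(0, 0, 0), c(r * sqrt(2), 0, 0)))
  expect_equal(rotational_constants(g2)[2], b[2] / 2, tolerance = 1e-10)
  expect_error(rotational_constants(geometry("H", matrix(0, 1, 3))),
               "at least 2")
})

test_that("multi-frame XYZ round-trips with energies on comment lines", {
  w <- geometry(c("O", "H", "H"),
                rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
                energy = -5.0)
  frames <- list(w, rigid_copy(w, 2), rigid_copy(w, 3))
  frames[[2]]$energy <- -4.5
  frames[[3]]$energy <- NULL
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(frames, path)
  back <- read_xyz(path)
  expect_length(back, 3)
  expect_equal(back[[1]]$energy, -5.0)
  expect_equal(back[[2]]$energy, -4.5)
  expect_null(back[[3]]$energy)
  for (j in 1:3) {
    expect_equal(back[[j]]$coords, frames[[j]]$coords, tolerance = 1e-8)
    expect_identical(back[[j]]$elements, frames[[j]]$elements)
  }
})

test_that("malformed XYZ input errors with the offending location", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "frame with too few atoms", "H 0 0 0", "H 1 0 0"), path)
  expect_error(read_xyz(path), "line 1")
  writeLines(c("2", "bad coordinate", "H 0 0 0", "H x 0 0"), path)
  expect_error(read_xyz(path), "non-numeric")
  writeLines(c("zebra", "not a count"), path)
  expect_error(read_xyz(path), "atom count")
})

test_that("activation schedule enforces monotone ordering", {
  co <- int_coord("distance", c(1, 2))
  s <- activation_schedule(co, 1.8, c(2.0, 2.3), 4.5, 0.1)
  expect_s3_class(s, "activation_schedule")
  expect_error(activation_schedule(co, 1.8, c(2.3, 2.0), 4.5, 0.1),
               "monotone")
  expect_error(activation_schedule(co, 1.8, c(2.0), 4.5, 0), "scan_step")
  # compression direction is permitted
  expect_s3_class(activation_schedule(co, 4.5, c(2.3), 1.8, 0.1),
                  "activation_schedule")
})
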