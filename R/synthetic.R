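# Fixture generators and brute-force oracles. The oracles use only direct
# evaluation of the closed-form pair energies plus exhaustive grid search;
# they share no code with the optimizer or the metadynamics integrator, so
# they can serve as independent references for the full pipeline.

#' Collinear exchange toy system A-B + C -> A + B-C
#'
#' Builds a 3-atom system on a pairwise-Morse surface whose collinear
#' (r_AB, r_BC) reduction has exactly two wells (reactant and product van der
#' Waals complexes) separated by one saddle. The A..C pair is given a Morse
#' term with a large equilibrium distance, which is strongly repulsive over
#' the reactive region; this is what carves the exchange barrier out of an
#' otherwise additive attractive surface. The returned spec carries
#' grid-oracle results (saddle and well energies) computed by
#' [grid_saddle_oracle()]; a parameter regime without a saddle is rejected.
#'
#' @param De well depth of the A-B Morse term, Hartree (default 0.15)
#' @param a Morse width of the A-B and B-C terms, 1/Angstrom (default 3.0)
#' @param re equilibrium A-B and B-C distance, Angstrom (default 1.8)
#' @param asymmetry fractional extra depth of the B-C well; > 0 makes the
#'   product well deeper than the reactant well (default 0)
#' @param elements three element symbols for A, B, C (default F, Cl, Br);
#'   A and C must differ so the exchange is visible in the SMILES strings
#' @param oracle_n base grid resolution for the saddle oracle (default 160)
#' @return a `toy_system` list: `label`, `elements`, `geometry` (reactant
#'   complex), `params` ([morse_params()]), `backend`, `coordinate` (the
#'   activating A-B distance), `reactant_smiles`, `product_smiles`, `oracle`
#'   (from [grid_saddle_oracle()]), `barrier_kcal` (oracle saddle above the
#'   reactant well), `reaction_kcal` (product well minus reactant well)
#' @export
make_collinear_exchange <- function(De = 0.15, a = 3.0, re = 1.8,
                                    asymmetry = 0,
                                    elements = c("F", "Cl", "Br"),
                                    oracle_n = 160) {
  if (De <= 0 || a <= 0 || re <= 0) stop("De, a, re must all be > 0")
  if (asymmetry < 0) stop("asymmetry must be >= 0")
  if (length(unique(elements)) != 3) {
    stop("A, B, C must be three distinct elements")
  }
  # The A..C Morse term has a large equilibrium distance, so it is strongly
  # repulsive wherever A and C are both near B: that repulsion is what turns
  # the otherwise additive attractive surface into two wells and a saddle.
  re_ac <- 2 * re + 1.8
  pairs <- list()
  pairs[[paste(elements[1], elements[2], sep = "-")]] <-
    list(De = De, a = a, re = re)
  pairs[[paste(elements[2], elements[3], sep = "-")]] <-
    list(De = De * (1 + asymmetry), a = a, re = re)
  pairs[[paste(elements[1], elements[3], sep = "-")]] <-
    list(De = 0.02, a = 2.5, re = re_ac)
  params <- morse_params(pairs, cutoff = 10)

  # reactant complex: A-B bonded, C at the A..C van der Waals distance
  geom <- geometry(elements,
                   rbind(c(0, 0, 0), c(re, 0, 0), c(re_ac, 0, 0)),
                   charge = 0L, multiplicity = 2L)
  oracle <- grid_saddle_oracle(params, elements, n = oracle_n)

  # expected fragment strings from idealized separated structures
  react_geom <- geometry(elements,
                         rbind(c(0, 0, 0), c(re, 0, 0), c(re + 6, 0, 0)))
  prod_geom <- geometry(elements,
                        rbind(c(-6, 0, 0), c(0, 0, 0), c(re, 0, 0)))
  structure(list(
    label = sprintf("exchange-%s", paste(elements, collapse = "")),
    elements = elements,
    geometry = geom,
    params = params,
    backend = toy_morse_backend(params),
    coordinate = int_coord("distance", c(1L, 2L)),
    reactant_smiles = to_canonical_smiles(react_geom),
    product_smiles = to_canonical_smiles(prod_geom),
    oracle = oracle,
    barrier_kcal = (oracle$saddle_energy - oracle$reactant$energy) *
      HARTREE_TO_KCAL,
    reaction_kcal = (oracle$product$energy - oracle$reactant$energy) *
      HARTREE_TO_KCAL),
    class = "toy_system")
}

# Closed-form collinear energy E(r_ab, r_bc) for a 3-atom pairwise-Morse
# system, vectorized over grids. Uses only morse_energy (direct evaluation).
collinear_energy_fn <- function(params, elements) {
  k_ab <- pair_key_symbols(elements[1:2])
  k_bc <- pair_key_symbols(elements[2:3])
  k_ac <- pair_key_symbols(elements[c(1, 3)])
  p_ab <- params$pairs[[k_ab]]
  p_bc <- params$pairs[[k_bc]]
  p_ac <- params$pairs[[k_ac]]
  if (is.null(p_ab) || is.null(p_bc) || is.null(p_ac)) {
    stop("collinear system needs parameters for all three element pairs")
  }
  function(r_ab, r_bc) {
    morse_energy(r_ab, p_ab$De, p_ab$a, p_ab$re, params) +
      morse_energy(r_bc, p_bc$De, p_bc$a, p_bc$re, params) +
      morse_energy(r_ab + r_bc, p_ac$De, p_ac$a, p_ac$re, params)
  }
}

# Watershed (max-edge-minimizing) saddle between two marked cells of a grid:
# process cells in ascending energy, union 4-neighbors already processed; the
# energy at which the two basins merge is the saddle to grid precision.
watershed_saddle <- function(E, i_react, i_prod) {
  nr <- nrow(E); nc <- ncol(E)
  idx <- order(as.vector(E))
  parent <- seq_len(nr * nc)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  seen <- logical(nr * nc)
  for (cell in idx) {
    seen[cell] <- TRUE
    r <- (cell - 1) %% nr + 1
    cc <- (cell - 1) %/% nr + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r2 <- r + d[1]; c2 <- cc + d[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      nb <- (c2 - 1) * nr + r2
      if (!seen[nb]) next
      ra <- find(cell); rb <- find(nb)
      if (ra != rb) parent[ra] <- rb
    }
    if (find(i_react) == find(i_prod)) {
      return(list(energy = E[cell], cell = cell))
    }
  }
  NULL
}

grid_local_minima <- function(E) {
  nr <- nrow(E); nc <- ncol(E)
  mins <- integer(0)
  for (r in 2:(nr - 1)) {
    for (cc in 2:(nc - 1)) {
      patch <- E[(r - 1):(r + 1), (cc - 1):(cc + 1)]
      if (E[r, cc] <= min(patch) && sum(patch == min(patch)) == 1) {
        mins <- c(mins, (cc - 1) * nr + r)
      }
    }
  }
  mins
}

#' Brute-force saddle oracle for collinear exchange systems
#'
#' Evaluates the closed-form collinear energy on a dense (r_AB, r_BC) grid,
#' locates the reactant well (smallest r_AB among grid minima) and product
#' well (smallest r_BC), and finds the saddle as the merge energy of the two
#' basins when grid cells are flooded in ascending energy order (the lowest
#' maximum over all grid paths). The saddle and both wells are then polished
#' by Newton iterations on the analytic surface; the polish must confirm a
#' first-order saddle (Hessian with one negative eigenvalue). The whole
#' computation is repeated at twice the resolution and must agree within
#' `tol_kcal`, otherwise the grid is declared too coarse.
#'
#' @param params a [morse_params()] covering all three element pairs
#' @param elements the three element symbols A, B, C
#' @param n base grid resolution (n x n; default 160)
#' @param rmax largest pair distance on the grid (default: re_AB + 3.5)
#' @param tol_kcal max allowed saddle shift under 2x refinement (default 0.1)
#' @return list with `saddle_energy` (Hartree), `saddle_point` (r_AB, r_BC),
#'   `reactant` and `product` (each: `point`, `energy`), `grid_n`
#' @export
grid_saddle_oracle <- function(params, elements, n = 160, rmax = NULL,
                               tol_kcal = 0.1) {
  if (length(elements) == 2) {
    stop("a diatomic has a 1-D profile with no saddle; nothing to locate")
  }
  f <- collinear_energy_fn(params, elements)
  re_ab <- params$pairs[[pair_key_symbols(elements[1:2])]]$re
  re_bc <- params$pairs[[pair_key_symbols(elements[2:3])]]$re
  if (is.null(rmax)) rmax <- max(re_ab, re_bc) + 3.5
  rmin <- 0.75 * min(re_ab, re_bc)

  solve_at <- function(ngrid) {
    r1 <- seq(rmin, rmax, length.out = ngrid)
    r2 <- seq(rmin, rmax, length.out = ngrid)
    E <- outer(r1, r2, f)
    mins <- grid_local_minima(E)
    if (length(mins) < 2) {
      stop("no saddle: the surface has fewer than two wells in the scanned ",
           "region; choose different parameters")
    }
    pts <- cbind(r1[(mins - 1) %% ngrid + 1], r2[(mins - 1) %/% ngrid + 1])
    i_react <- mins[which.min(pts[, 1])]
    i_prod <- mins[which.min(pts[, 2])]
    if (i_react == i_prod) {
      stop("no saddle: reactant and product wells coincide on the grid")
    }
    ws <- watershed_saddle(E, i_react, i_prod)
    if (is.null(ws)) stop("grid flooding failed to connect the two wells")
    cell_pt <- function(cell) c(r1[(cell - 1) %% ngrid + 1],
                                r2[(cell - 1) %/% ngrid + 1])
    list(saddle = list(point = cell_pt(ws$cell), energy = ws$energy),
         react = list(point = cell_pt(i_react), energy = E[i_react]),
         prod = list(point = cell_pt(i_prod), energy = E[i_prod]))
  }

  fn2 <- function(p) f(p[1], p[2])
  polish <- function(p0, want_saddle) {
    p <- p0
    for (it in 1:30) {
      g <- pracma::grad(fn2, p)
      H <- pracma::hessian(fn2, p)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) return(NULL)
      p <- p - step
      if (any(p < rmin - 0.5) || any(p > rmax + 0.5)) return(NULL)
      if (sqrt(sum(g^2)) < 1e-10) break
    }
    ev <- eigen(pracma::hessian(fn2, p), symmetric = TRUE,
                only.values = TRUE)$values
    ok <- if (want_saddle) sum(ev < 0) == 1 else all(ev > 0)
    if (!ok) return(NULL)
    list(point = p, energy = fn2(p))
  }

  refine <- function(raw) {
    sd <- polish(raw$saddle$point, want_saddle = TRUE)
    rc <- polish(raw$react$point, want_saddle = FALSE)
    pd <- polish(raw$prod$point, want_saddle = FALSE)
    list(saddle = if (is.null(sd)) raw$saddle else sd,
         react = if (is.null(rc)) raw$react else rc,
         prod = if (is.null(pd)) raw$prod else pd)
  }

  a1 <- refine(solve_at(n))
  a2 <- refine(solve_at(2L * n))
  shift <- abs(a1$saddle$energy - a2$saddle$energy) * HARTREE_TO_KCAL
  if (shift > tol_kcal) {
    stop(sprintf(
      "grid too coarse: saddle shifts %.3f kcal/mol under 2x refinement", shift))
  }
  list(saddle_energy = a2$saddle$energy, saddle_point = a2$saddle$point,
       reactant = a2$react, product = a2$prod, grid_n = 2L * n)
}

#' Butane-like 4-atom torsional chain
#'
#' A chain A-B-C-D on the pairwise-Morse surface whose 1-4 interaction has its
#' minimum at the gauche 1-4 distance, producing two mirror-image torsional
#' wells (dihedral near +/- `phi0`) separated by barriers at the syn and anti
#' conformations. Four distinct elements give every topological pair its own
#' Morse term (bonds, 1-3 angle braces, and the well-forming 1-4 term).
#' Used to check that biased sampling escapes a torsional well that plain
#' low-temperature dynamics cannot leave.
#'
#' @param phi0 dihedral (degrees) of the two wells (default 65)
#' @param bond_re bond length, Angstrom (default 1.8)
#' @param theta bond angle, degrees (default 109.5)
#' @param elements four distinct element symbols (default F, O, N, C)
#' @return list with `geometry` (started in the +phi0 well), `params`,
#'   `backend`, `dihedral` (the A-B-C-D [int_coord()]), `phi0`
#' @export
make_torsion_chain <- function(phi0 = 65, bond_re = 1.8, theta = 109.5,
                               elements = c("F", "O", "N", "C")) {
  if (length(unique(elements)) != 4) stop("need four distinct elements")
  th <- theta * pi / 180
  place <- function(phi_deg) {
    phi <- phi_deg * pi / 180
    rbind(
      c(-bond_re * cos(th), bond_re * sin(th), 0),          # A
      c(0, 0, 0),                                           # B
      c(bond_re, 0, 0),                                     # C
      c(bond_re + bond_re * cos(th), bond_re * sin(th) * cos(phi),
        bond_re * sin(th) * sin(phi)))                      # D
  }
  g0 <- geometry(elements, place(phi0))
  d13 <- bond_re * sqrt(2 - 2 * cos(pi - th))
  d14 <- sqrt(sum((g0$coords[1, ] - g0$coords[4, ])^2))
  e <- elements
  pairs <- list()
  pairs[[paste(e[1], e[2], sep = "-")]] <- list(De = 0.15, a = 2.0, re = bond_re)
  pairs[[paste(e[2], e[3], sep = "-")]] <- list(De = 0.15, a = 2.0, re = bond_re)
  pairs[[paste(e[3], e[4], sep = "-")]] <- list(De = 0.15, a = 2.0, re = bond_re)
  pairs[[paste(e[1], e[3], sep = "-")]] <- list(De = 0.05, a = 1.5, re = d13)
  pairs[[paste(e[2], e[4], sep = "-")]] <- list(De = 0.05, a = 1.5, re = d13)
  pairs[[paste(e[1], e[4], sep = "-")]] <- list(De = 0.02, a = 2.0, re = d14)
  params <- morse_params(pairs, cutoff = 10)
  list(geometry = g0, params = params, backend = toy_morse_backend(params),
       dihedral = int_coord("dihedral", 1:4), phi0 = phi0)
}

#' Mueller-Brown analytic test surface
#'
#' The standard 2-D four-Gaussian test function with three minima and two
#' first-order saddles at the literature parameter values, plus its analytic
#' gradient. Used as an optimizer and dynamics testbed.
#'
#' @return list with `f` (function(xy) -> scalar), `grad`
#'   (function(xy) -> length-2 gradient), and `minima_guess` (3 x 2 matrix of
#'   approximate minimum locations to start local searches from)
#' @export
muller_brown <- function() {
  A <- c(-200, -100, -170, 15)
  a <- c(-1, -1, -6.5, 0.7)
  b <- c(0, 0, 11, 0.6)
  cc <- c(-10, -10, -6.5, 0.7)
  x0 <- c(1, 0, -0.5, -1)
  y0 <- c(0, 0.5, 1.5, 1)
  f <- function(xy) {
    dx <- xy[1] - x0; dy <- xy[2] - y0
    sum(A * exp(a * dx^2 + b * dx * dy + cc * dy^2))
  }
  grad <- function(xy) {
    dx <- xy[1] - x0; dy <- xy[2] - y0
    e <- A * exp(a * dx^2 + b * dx * dy + cc * dy^2)
    c(sum(e * (2 * a * dx + b * dy)), sum(e * (b * dx + 2 * cc * dy)))
  }
  list(f = f, grad = grad,
       minima_guess = rbind(c(-0.56, 1.44), c(-0.05, 0.47), c(0.62, 0.03)))
}
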