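#' Harmonic constraint on an internal coordinate
#'
#' @param coordinate an [int_coord()]
#' @param target target value (Angstrom for distances, degrees otherwise)
#' @param force_constant restraint stiffness, Hartree/Angstrom^2 for distances
#'   and Hartree/rad^2 for angles/dihedrals (default 1.0)
#' @return object of class `constraint`
#' @export
constraint <- function(coordinate, target, force_constant = 1.0) {
  stopifnot(inherits(coordinate, "int_coord"))
  if (force_constant <= 0) stop("force_constant must be > 0")
  structure(list(coordinate = coordinate, target = target,
                 force_constant = force_constant),
            class = "constraint")
}

# Wrapped difference q - target in penalty units (Angstrom or radians).
coord_penalty_diff <- function(kind, q, target) {
  d <- q - target
  if (kind == "dihedral") d <- ((d + 180) %% 360) - 180
  if (kind != "distance") d <- d * pi / 180
  d
}

# Raw (coordinate-unit) wrapped difference for tolerance checks.
coord_diff <- function(kind, q, target) {
  d <- q - target
  if (kind == "dihedral") d <- ((d + 180) %% 360) - 180
  d
}

default_ctol <- function(kind) if (kind == "distance") 0.01 else 0.5

# Jacobian dq/dx of an internal coordinate by central differences, in
# penalty units per Angstrom (radians for angles). Returned as length-3N
# vector. h = 1e-5 A gives ~1e-9 accuracy on these smooth coordinates.
coord_jacobian <- function(geom, coord, h = 1e-5) {
  n <- n_atoms(geom)
  J <- numeric(3 * n)
  x0 <- geom$coords
  scale <- if (coord$kind == "distance") 1 else pi / 180
  for (atom in coord$atoms) {
    for (k in 1:3) {
      xp <- x0; xp[atom, k] <- xp[atom, k] + h
      xm <- x0; xm[atom, k] <- xm[atom, k] - h
      qp <- measure(set_coords(geom, xp), coord)
      qm <- measure(set_coords(geom, xm), coord)
      d <- qp - qm
      if (coord$kind == "dihedral") d <- ((d + 180) %% 360) - 180
      J[(atom - 1) * 3 + k] <- scale * d / (2 * h)
    }
  }
  J
}

# Newton projection of the constrained coordinates exactly onto their targets:
# x <- x + (t - q) J / |J|^2, iterated. Leaves orthogonal directions untouched
# to first order.
project_constraints <- function(geom, constraints, tol = 1e-10, maxit = 20) {
  x <- as.vector(t(geom$coords))
  g <- geom
  for (it in seq_len(maxit)) {
    worst <- 0
    for (con in constraints) {
      q <- measure(g, con$coordinate)
      d <- coord_penalty_diff(con$coordinate$kind, q, con$target)
      worst <- max(worst, abs(d))
      if (abs(d) < tol) next
      J <- coord_jacobian(g, con$coordinate)
      x <- x - d * J / sum(J * J)
      g <- set_coords(g, matrix(x, ncol = 3, byrow = TRUE))
    }
    if (worst < tol) break
  }
  g
}

#' Constrained local geometry minimization
#'
#' Minimizes the backend energy subject to internal-coordinate constraints.
#' The working objective is an augmented Lagrangian: a harmonic restraint per
#' constraint plus a multiplier term updated between L-BFGS-B descents, with
#' the restraint stiffness escalated when the constraint residual stalls.
#' After the descents the constrained coordinates are projected exactly onto
#' their targets (Newton steps along the coordinate Jacobian), so constraints
#' are satisfied to numerical precision (well inside `ctol`), and the
#' reported energy is the pure backend energy at the projected structure.
#' Convergence is judged on the gradient component orthogonal to all
#' constraint Jacobians.
#'
#' @param geom starting `geometry`
#' @param constraints list of [constraint()] objects (may be empty for a
#'   plain minimization)
#' @param backend a backend
#' @param gtol max allowed gradient component (Hartree/Angstrom) orthogonal to
#'   the constraints (default 5e-4)
#' @param ctol constraint tolerance: 0.01 Angstrom / 0.5 degrees by default
#' @param maxit total inner-iteration cap (default 500)
#' @return a `geometry` with energy set; attributes `converged` (logical) and
#'   `gmax` (final orthogonal gradient max-component)
#' @export
constrained_minimize <- function(geom, constraints = list(), backend,
                                 gtol = 5e-4, ctol = NULL, maxit = 500) {
  if (inherits(constraints, "constraint")) constraints <- list(constraints)
  for (con in constraints) check_indices(geom, con$coordinate)
  nc <- length(constraints)
  lambda <- numeric(nc)
  kwork <- vapply(constraints, function(con) con$force_constant, numeric(1))

  diffs_at <- function(g) {
    vapply(constraints, function(con) {
      coord_penalty_diff(con$coordinate$kind,
                         measure(g, con$coordinate), con$target)
    }, numeric(1))
  }
  objective <- function(x) {
    g <- set_coords(geom, matrix(x, ncol = 3, byrow = TRUE))
    eg <- backend_evaluate(backend, g)
    if (!is.finite(eg$energy)) stop("backend returned non-finite energy")
    d <- diffs_at(g)
    eg$energy + sum(lambda * d) + 0.5 * sum(kwork * d^2)
  }
  gradient <- function(x) {
    g <- set_coords(geom, matrix(x, ncol = 3, byrow = TRUE))
    eg <- backend_evaluate(backend, g)
    gr <- as.vector(t(eg$gradient))
    d <- diffs_at(g)
    for (i in seq_len(nc)) {
      gr <- gr + (lambda[i] + kwork[i] * d[i]) *
        coord_jacobian(g, constraints[[i]]$coordinate)
    }
    gr
  }

  cur <- project_constraints(geom, constraints)
  x <- as.vector(t(cur$coords))
  spent <- 0L
  converged <- FALSE
  gmax <- Inf
  prev_resid <- Inf
  while (spent < maxit) {
    chunk <- min(100L, maxit - spent)
    res <- stats::optim(x, objective, gradient, method = "L-BFGS-B",
                        control = list(maxit = chunk, factr = 10,
                                       pgtol = gtol / 20))
    spent <- spent + chunk
    raw <- set_coords(geom, matrix(res$par, ncol = 3, byrow = TRUE))
    if (nc) {
      d <- diffs_at(raw)
      lambda <- lambda + kwork * d            # multiplier update
      resid <- max(abs(d))
      if (resid > prev_resid / 4 && resid > 1e-8) {
        kwork <- pmin(kwork * 10, 1e6)        # residual stalled: stiffen
      }
      prev_resid <- resid
    }
    cur <- project_constraints(raw, constraints)
    x <- as.vector(t(cur$coords))
    eg <- backend_evaluate(backend, cur)
    gperp <- as.vector(t(eg$gradient))
    if (nc) {
      # orthogonalize the constraint Jacobians, then remove their span
      basis <- list()
      for (con in constraints) {
        J <- coord_jacobian(cur, con$coordinate)
        for (b in basis) J <- J - sum(J * b) * b
        nj <- sqrt(sum(J * J))
        if (nj > 1e-12) basis[[length(basis) + 1L]] <- J / nj
      }
      for (b in basis) gperp <- gperp - sum(gperp * b) * b
    }
    gmax <- max(abs(gperp))
    if (gmax <= gtol) { converged <- TRUE; break }
  }

  ok_constraints <- TRUE
  for (con in constraints) {
    tol <- if (is.null(ctol)) default_ctol(con$coordinate$kind) else ctol
    if (abs(coord_diff(con$coordinate$kind, measure(cur, con$coordinate),
                       con$target)) > tol) ok_constraints <- FALSE
  }
  out <- set_coords(geom, cur$coords,
                    energy = backend_evaluate(backend, cur)$energy)
  attr(out, "converged") <- converged && ok_constraints
  attr(out, "gmax") <- gmax
  out
}

#' Reaction-path trajectory
#'
#' Ordered energy-tagged frames together with the per-frame value of the
#' activating coordinate and provenance identifiers.
#'
#' @param frames list of `geometry` with energies set
#' @param q_values numeric vector, one activating-coordinate value per frame
#' @param provenance named list (seed, activation value index, conformer id)
#' @param flags logical vector, TRUE where the frame's minimization converged
#' @return object of class `trajectory`
#' @export
trajectory <- function(frames, q_values, provenance = list(), flags = NULL) {
  if (length(frames) != length(q_values)) {
    stop("q_values must have one entry per frame")
  }
  if (any(vapply(frames, function(f) is.null(f$energy), logical(1)))) {
    stop("all trajectory frames must carry an energy")
  }
  if (is.null(flags)) flags <- rep(TRUE, length(frames))
  structure(list(frames = frames, q_values = as.numeric(q_values),
                 provenance = provenance, flags = flags),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  e <- trajectory_energies(x)
  cat(sprintf("<trajectory: %d frames, q %.3f..%.3f, E %.6f..%.6f Ha>\n",
              length(x$frames), x$q_values[1],
              x$q_values[length(x$q_values)], min(e), max(e)))
  invisible(x)
}

#' Frame energies of a trajectory
#' @param traj a `trajectory`
#' @return numeric vector of frame energies (Hartree)
#' @export
trajectory_energies <- function(traj) {
  vapply(traj$frames, function(f) f$energy, numeric(1))
}

#' Relaxed scan along one internal coordinate
#'
#' Performs a sequence of constrained minimizations at the requested
#' coordinate values, each warm-started from the previous frame. Frames whose
#' minimization did not converge are kept and flagged; post-processing
#' excludes flagged transition-structure candidates rather than losing the
#' trajectory.
#'
#' @param geom starting `geometry`, pre-optimized at (or near) `values[1]`
#' @param coordinate an [int_coord()]
#' @param values monotone sequence of target values
#' @param backend a backend
#' @param force_constant restraint stiffness passed to [constraint()]
#' @param provenance provenance list stored on the trajectory
#' @param ... further arguments to [constrained_minimize()]
#' @return a `trajectory`
#' @export
relaxed_scan <- function(geom, coordinate, values, backend,
                         force_constant = 1.0, provenance = list(), ...) {
  if (length(values) < 1) stop("empty scan value list")
  dv <- diff(values)
  if (length(dv) && !(all(dv > 0) || all(dv < 0))) {
    stop("scan values must be monotone")
  }
  frames <- vector("list", length(values))
  flags <- logical(length(values))
  qv <- numeric(length(values))
  cur <- geom
  for (j in seq_along(values)) {
    cur <- constrained_minimize(
      cur, list(constraint(coordinate, values[j], force_constant)),
      backend, ...)
    frames[[j]] <- cur
    flags[j] <- isTRUE(attr(cur, "converged"))
    qv[j] <- measure(cur, coordinate)
  }
  trajectory(frames, qv, provenance, flags)
}

#' Build scan values from a schedule
#' @param from,to scan endpoints (coordinate units)
#' @param step positive increment; the sign is inferred from the direction
#' @return numeric sequence from `from` to `to` inclusive
#' @export
scan_values <- function(from, to, step) {
  if (step <= 0) stop("step must be > 0")
  if (isTRUE(all.equal(from, to))) return(from)
  s <- if (to > from) step else -step
  v <- seq(from, to, by = s)
  if (abs(v[length(v)] - to) > 1e-9) v <- c(v, to)
  v
}

#' Stitch backward and forward scans into one reactant-to-product trajectory
#'
#' The backward scan runs from the activated value down to the equilibrium
#' value; the forward scan runs from the same activated conformer up to the
#' maximal value. Both must start from the same structure. The result is the
#' reversed backward scan followed by the forward scan with the duplicate
#' junction frame removed, ordered reactant to product.
#'
#' @param backward `trajectory` scanned activated -> equilibrium
#' @param forward `trajectory` scanned activated -> maximum
#' @param junction_tol max allowed RMSD (Angstrom) between the two scans'
#'   first frames (default 1e-4)
#' @return a `trajectory` with monotone q_values
#' @export
stitch <- function(backward, forward, junction_tol = 1e-4) {
  jb <- backward$frames[[1]]
  jf <- forward$frames[[1]]
  jr <- superpose_rmsd(jb, jf)$rmsd
  if (jr > junction_tol) {
    stop(sprintf(
      "backward and forward scans do not share a junction conformer (RMSD %.3g A > %.3g)",
      jr, junction_tol))
  }
  nb <- length(backward$frames)
  ord <- rev(seq_len(nb))
  frames <- c(backward$frames[ord], forward$frames[-1])
  qv <- c(backward$q_values[ord], forward$q_values[-1])
  flags <- c(backward$flags[ord], forward$flags[-1])
  trajectory(frames, qv,
             provenance = utils::modifyList(backward$provenance,
                                            forward$provenance),
             flags = flags)
}
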