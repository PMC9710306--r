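#' Metadynamics bias parameters
#'
#' The history-dependent bias is a sum of Gaussian kernels in RMSD space,
#' `V_bias = sum_i k * exp(-alpha * Delta_i^2)`, where `Delta_i` is the
#' minimized RMSD between the current structure and the i-th stored snapshot.
#'
#' @param k kernel height in Hartree. The conventional per-atom
#'   parameterization is obtained by passing `k_per_atom * n_atoms`.
#' @param alpha kernel width in 1/Angstrom^2
#' @param snapshot_interval fs between snapshot depositions
#' @param max_snapshots cap on stored kernels; once reached, no further
#'   kernels are added but the dynamics continue
#' @return object of class `bias_params`
#' @export
bias_params <- function(k, alpha = 0.8, snapshot_interval = 50,
                        max_snapshots = 100L) {
  if (k <= 0 || alpha <= 0 || snapshot_interval <= 0) {
    stop("k, alpha and snapshot_interval must all be > 0")
  }
  structure(list(k = k, alpha = alpha,
                 snapshot_interval = snapshot_interval,
                 max_snapshots = as.integer(max_snapshots)),
            class = "bias_params")
}

#' Molecular dynamics parameters
#'
#' @param timestep integration step in fs (default 1)
#' @param temperature target temperature in K
#' @param total_time simulation length in ps
#' @param tau Berendsen thermostat time constant in fs (default 50)
#' @param seed integer RNG seed for the initial Maxwell-Boltzmann velocities
#' @return object of class `md_params`
#' @export
md_params <- function(timestep = 1, temperature = 300, total_time = 1,
                      tau = 50, seed = 1L) {
  if (timestep <= 0 || total_time <= 0 || tau <= 0) {
    stop("timestep, total_time and tau must be > 0")
  }
  if (temperature < 0) stop("temperature must be >= 0")
  structure(list(timestep = timestep, temperature = temperature,
                 total_time = total_time, tau = tau, seed = as.integer(seed)),
            class = "md_params")
}

#' RMSD-Gaussian bias energy and gradient
#'
#' Evaluates `sum_i k exp(-alpha Delta_i^2)` over the stored snapshots and its
#' Cartesian gradient assembled by the chain rule through [rmsd_gradient()].
#' An empty history gives exactly zero energy and gradient; a snapshot
#' identical to the current structure contributes exactly `k`.
#'
#' @param geom current `geometry`
#' @param state list of snapshot geometries (the bias history)
#' @param params a [bias_params()]
#' @return an [energy_gradient()]
#' @export
bias_energy_gradient <- function(geom, state, params) {
  n <- n_atoms(geom)
  energy <- 0
  grad <- matrix(0, n, 3)
  xc <- sweep(geom$coords, 2, colMeans(geom$coords))
  for (snap in state) {
    if (!identical(snap$elements, geom$elements)) {
      stop("bias snapshot element sequence does not match the simulated system")
    }
    fit <- superpose_rmsd(geom, snap)
    delta <- fit$rmsd
    kern <- params$k * exp(-params$alpha * delta^2)
    energy <- energy + kern
    # dV/dx = k exp(-a D^2) * (-2 a D) * dD/dx, with the RMSD gradient
    # (x' - R y') / (N D) from the one superposition above; the combination
    # vanishes smoothly as D -> 0
    if (delta > 1e-6) {
      yc <- sweep(snap$coords, 2, colMeans(snap$coords))
      ddelta <- (xc - yc %*% t(fit$rotation)) / (n * delta)
      grad <- grad + kern * (-2 * params$alpha * delta) * ddelta
    }
  }
  energy_gradient(energy, grad, converged = TRUE)
}

kinetic_temperature <- function(v, masses) {
  ke <- 0.5 * sum(masses * rowSums(v^2))
  2 * ke / (3 * nrow(v) * KB_MD)
}

#' Constrained metadynamics conformer sampling
#'
#' Velocity-Verlet molecular dynamics under the backend forces, the
#' history-dependent RMSD bias, and (optionally) a harmonic restraint holding
#' the activating coordinate at its target. A Berendsen thermostat with time
#' constant `md$tau` keeps the kinetic temperature near target. Snapshots are
#' deposited into the bias history every `bias$snapshot_interval` fs (up to
#' `bias$max_snapshots`) and returned as candidate conformers. Runs with
#' identical inputs and seed are deterministic.
#'
#' If the energy diverges (non-finite, or drifting more than `energy_bound`
#' Hartree above the start) the run is truncated and the snapshots collected
#' so far are returned with attribute `flag = "truncated"`.
#'
#' @param start pre-optimized starting `geometry` (under the constraint, if any)
#' @param constr a [constraint()] or NULL for unconstrained sampling
#' @param md an [md_params()]
#' @param bias a [bias_params()]; pass NULL for plain thermostatted MD
#' @param backend a backend
#' @param energy_bound sanity bound (Hartree) on potential-energy rise
#' @return list of snapshot geometries (energies set to the backend energy);
#'   attributes: `flag` (NULL or "truncated"), `bias_log` (data.frame with
#'   step, n_snapshots, bias energy)
#' @export
run_metadynamics <- function(start, constr = NULL, md, bias, backend,
                             energy_bound = 1.0) {
  if (!is.null(constr)) check_indices(start, constr$coordinate)
  n <- n_atoms(start)
  masses <- element_mass(start$elements)
  dt <- md$timestep
  nsteps <- max(1L, as.integer(round(md$total_time * 1000 / dt)))
  snap_every <- max(1L, as.integer(round(bias$snapshot_interval / dt)))

  # local RNG scope: seed the stream, restore the caller's state on exit
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(md$seed)

  v <- matrix(0, n, 3)
  if (md$temperature > 0) {
    sigma <- sqrt(KB_MD * md$temperature / masses)
    v <- matrix(stats::rnorm(3 * n), n, 3) * sigma
    v <- sweep(v, 2, colSums(v * masses) / sum(masses))  # remove COM drift
  }

  total_force <- function(g, state) {
    eg <- backend_evaluate(backend, g)
    grad <- eg$gradient
    eb <- 0
    if (!is.null(bias) && length(state)) {
      bg <- bias_energy_gradient(g, state, bias)
      grad <- grad + bg$gradient
      eb <- bg$energy
    }
    if (!is.null(constr)) {
      d <- coord_penalty_diff(constr$coordinate$kind,
                              measure(g, constr$coordinate), constr$target)
      grad <- grad + constr$force_constant * d *
        matrix(coord_jacobian(g, constr$coordinate), ncol = 3, byrow = TRUE)
    }
    list(grad = grad, epot = eg$energy, ebias = eb)
  }

  cur <- start
  state <- list()
  snapshots <- list()
  log_step <- integer(0); log_nsnap <- integer(0); log_ebias <- numeric(0)
  f <- total_force(cur, state)
  e0 <- f$epot
  flag <- NULL

  for (step in seq_len(nsteps)) {
    acc <- -FORCE_TO_ACCEL * f$grad / masses
    v <- v + 0.5 * dt * acc
    newx <- cur$coords + dt * v
    cur <- set_coords(cur, newx)
    f <- total_force(cur, state)
    if (!is.finite(f$epot) || f$epot - e0 > energy_bound) {
      flag <- "truncated"
      break
    }
    acc <- -FORCE_TO_ACCEL * f$grad / masses
    v <- v + 0.5 * dt * acc
    if (md$temperature > 0) {
      Tk <- kinetic_temperature(v, masses)
      if (Tk > 1e-12) {
        lam <- sqrt(pmax(0.64, pmin(1.5625,
                    1 + dt / md$tau * (md$temperature / Tk - 1))))
        v <- v * lam
      }
    }
    if (step %% snap_every == 0) {
      snap <- set_coords(cur, cur$coords, energy = f$epot)
      snapshots[[length(snapshots) + 1L]] <- snap
      if (!is.null(bias) && length(state) < bias$max_snapshots) {
        state[[length(state) + 1L]] <- snap
      }
      log_step <- c(log_step, step)
      log_nsnap <- c(log_nsnap, length(state))
      log_ebias <- c(log_ebias, f$ebias)
    }
  }

  structure(snapshots, flag = flag,
            bias_log = data.frame(step = log_step, n_snapshots = log_nsnap,
                                  bias_energy = log_ebias))
}
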