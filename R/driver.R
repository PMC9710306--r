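#' Run configuration for the imposed-activation workflow
#'
#' Collects every knob of the four-step workflow with validated defaults.
#' Activation values default to multiplicative factors of the equilibrium
#' value q0 (stretch grid 1.1, 1.2, 1.3, 1.5 and maximum 2.5 x q0 for
#' distances); absolute values may be given instead. Total metadynamics time
#' is scheduled proportional to the atom count via `md_time_per_atom`.
#'
#' @param input a `geometry` or path to an XYZ file (first frame used)
#' @param coordinate the activating [int_coord()]
#' @param backend a backend
#' @param charge,multiplicity applied when `input` is a file path
#' @param stretch_factors multiplicative activation grid over q0
#' @param qi_values absolute activation values (overrides `stretch_factors`)
#' @param qmax_factor q_N as a multiple of q0 (default 2.5)
#' @param qN absolute maximal scanned value (overrides `qmax_factor`)
#' @param scan_step relaxed-scan increment: 0.1 Angstrom for distances,
#'   5 degrees otherwise
#' @param timestep MD timestep, fs
#' @param temperature MD temperature, K
#' @param md_time_per_atom metadynamics length per atom, ps (default 0.05);
#'   the equilibrium (step 1) search runs twice as long, the per-activation
#'   searches are shorter by design
#' @param tau Berendsen time constant, fs
#' @param k_per_atom bias kernel height per atom, Hartree (default 0.002)
#' @param alpha bias kernel width, 1/Angstrom^2 (default 0.8)
#' @param snapshot_interval fs between bias snapshots
#' @param max_snapshots cap on bias kernels
#' @param md_restraint_k restraint stiffness holding the activating coordinate
#'   during MD, Hartree/Angstrom^2 (default 10; thermal motion demands a much
#'   stiffer spring than the optimizer's working restraint)
#' @param thresholds a [prune_thresholds()]
#' @param budget max number of reactive trajectories over the whole run
#' @param seed integer master seed; all randomness derives from it
#' @param gtol,ctol optimizer tolerances (see [constrained_minimize()])
#' @param outdir optional output directory for run artifacts
#' @return a validated `run_config`
#' @export
run_config <- function(input, coordinate, backend,
                       charge = 0L, multiplicity = 1L,
                       stretch_factors = c(1.1, 1.2, 1.3, 1.5),
                       qi_values = NULL, qmax_factor = 2.5, qN = NULL,
                       scan_step = NULL,
                       timestep = 0.5, temperature = 300,
                       md_time_per_atom = 0.05, tau = 50,
                       k_per_atom = 0.002, alpha = 0.8,
                       snapshot_interval = 25, max_snapshots = 100L,
                       md_restraint_k = 10,
                       thresholds = prune_thresholds(),
                       budget = 100L, seed = 1L,
                       gtol = 5e-4, ctol = NULL, outdir = NULL) {
  stopifnot(inherits(coordinate, "int_coord"))
  if (budget < 1) stop("trajectory budget must be >= 1")
  if (is.null(scan_step)) {
    scan_step <- if (coordinate$kind == "distance") 0.1 else 5
  }
  if (scan_step <= 0) stop("scan_step must be > 0")
  if (!is.null(qi_values) && !length(qi_values)) {
    stop("qi_values, when given, must be non-empty")
  }
  if (is.null(qi_values) && !length(stretch_factors)) {
    stop("need at least one stretch factor or absolute activation value")
  }
  structure(list(
    input = input, coordinate = coordinate, backend = backend,
    charge = as.integer(charge), multiplicity = as.integer(multiplicity),
    stretch_factors = stretch_factors, qi_values = qi_values,
    qmax_factor = qmax_factor, qN = qN, scan_step = scan_step,
    timestep = timestep, temperature = temperature,
    md_time_per_atom = md_time_per_atom, tau = tau,
    k_per_atom = k_per_atom, alpha = alpha,
    snapshot_interval = snapshot_interval,
    max_snapshots = as.integer(max_snapshots),
    md_restraint_k = md_restraint_k, thresholds = thresholds,
    budget = as.integer(budget), seed = as.integer(seed),
    gtol = gtol, ctol = ctol, outdir = outdir),
    class = "run_config")
}

# Reproducible per-trajectory seed stream: trajectories are embarrassingly
# parallel, so each (activation index, conformer index) pair gets its own
# deterministic sub-seed below 2^31.
derive_seed <- function(seed, qi_index, conf_index) {
  as.integer((as.double(seed) * 100003 + qi_index * 1009 +
                conf_index * 101 + 7) %% 2147483647) + 1L
}

load_input_geometry <- function(config) {
  if (inherits(config$input, "geometry")) return(config$input)
  frames <- read_xyz(config$input, charge = config$charge,
                     multiplicity = config$multiplicity)
  frames[[1]]
}

#' Step 1: optimize the reactants and build the equilibrium ensemble
#'
#' Validates and loads the input, probes the backend with one evaluation,
#' optimizes the structure without constraints, measures the equilibrium
#' value q0 of the activating coordinate, and runs a constrained
#' metadynamics + prune cycle at q0. The resulting ensemble is the reference
#' for every estimated activation energy of the run.
#'
#' @param config a [run_config()]
#' @return list with `geometry` (optimized input), `q0`, and `ensemble`
#'   (equilibrium `conformer_ensemble`)
#' @export
step1_initialize <- function(config) {
  geom <- load_input_geometry(config)          # validation before any backend call
  check_indices(geom, config$coordinate)
  backend_probe(config$backend, geom)
  opt <- constrained_minimize(geom, list(), config$backend,
                              gtol = config$gtol, ctol = config$ctol)
  q0 <- measure(opt, config$coordinate)
  n <- n_atoms(opt)
  md <- md_params(timestep = config$timestep,
                  temperature = config$temperature,
                  total_time = 2 * config$md_time_per_atom * n,
                  tau = config$tau,
                  seed = derive_seed(config$seed, 0L, 0L))
  bias <- bias_params(k = config$k_per_atom * n, alpha = config$alpha,
                      snapshot_interval = config$snapshot_interval,
                      max_snapshots = config$max_snapshots)
  con <- constraint(config$coordinate, q0, config$md_restraint_k)
  snaps <- run_metadynamics(opt, con, md, bias, config$backend)
  ens <- optimize_and_prune(c(list(opt), snaps),
                            constraint(config$coordinate, q0),
                            config$backend, config$thresholds,
                            gtol = config$gtol, ctol = config$ctol)
  list(geometry = opt, q0 = q0, ensemble = ens)
}

#' Run the full imposed-activation workflow
#'
#' For every activation value q_i: relaxed scan from q0 to q_i starting at the
#' best equilibrium conformer; constrained metadynamics at q_i; pruning to an
#' activated-conformer ensemble; then, from every member, a backward scan to
#' q0 and a forward scan to q_N, stitched into one reactant-to-product
#' trajectory and parsed into reaction events. Events from all trajectories
#' are aggregated into the reaction table with the step-1 ensemble as the
#' activation-energy reference. Individual trajectory failures are recorded
#' and skipped; the run fails only if no trajectory completes.
#'
#' @param config a [run_config()]
#' @return a `run_report`: list with `table` (the [aggregate_reactions()]
#'   result), `q0`, `qi_values`, `qN`, `ensemble_sizes` (per activation
#'   value), `ledger` (launched/completed/flagged/failed counts),
#'   `equilibrium_ensemble`, `events`, `elapsed_s`, `config`
#' @export
run_iacta <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  s1 <- step1_initialize(config)
  q0 <- s1$q0
  qi_values <- if (!is.null(config$qi_values)) config$qi_values
               else config$stretch_factors * q0
  qN <- if (!is.null(config$qN)) config$qN else config$qmax_factor * q0
  n <- n_atoms(s1$geometry)
  bias <- bias_params(k = config$k_per_atom * n, alpha = config$alpha,
                      snapshot_interval = config$snapshot_interval,
                      max_snapshots = config$max_snapshots)

  events <- list()
  ensemble_sizes <- integer(length(qi_values))
  launched <- completed <- flagged <- failed <- 0L
  base <- s1$ensemble$members[[1]]

  for (ii in seq_along(qi_values)) {
    qi <- qi_values[ii]
    up <- relaxed_scan(base, config$coordinate,
                       scan_values(q0, qi, config$scan_step),
                       config$backend, provenance = list(qi_index = ii),
                       gtol = config$gtol, ctol = config$ctol)
    start_i <- up$frames[[length(up$frames)]]
    md <- md_params(timestep = config$timestep,
                    temperature = config$temperature,
                    total_time = config$md_time_per_atom * n,
                    tau = config$tau,
                    seed = derive_seed(config$seed, ii, 0L))
    con_md <- constraint(config$coordinate, qi, config$md_restraint_k)
    snaps <- run_metadynamics(start_i, con_md, md, bias, config$backend)
    ens_i <- optimize_and_prune(c(list(start_i), snaps),
                                constraint(config$coordinate, qi),
                                config$backend, config$thresholds,
                                gtol = config$gtol, ctol = config$ctol)
    ensemble_sizes[ii] <- length(ens_i$members)
    for (ci in seq_along(ens_i$members)) {
      if (launched >= config$budget) break
      launched <- launched + 1L
      member <- ens_i$members[[ci]]
      prov <- list(seed = derive_seed(config$seed, ii, ci),
                   qi_index = ii, conformer = ci)
      res <- tryCatch({
        bwd <- relaxed_scan(member, config$coordinate,
                            scan_values(qi, q0, config$scan_step),
                            config$backend, provenance = prov,
                            gtol = config$gtol, ctol = config$ctol)
        fwd <- relaxed_scan(member, config$coordinate,
                            scan_values(qi, qN, config$scan_step),
                            config$backend, provenance = prov,
                            gtol = config$gtol, ctol = config$ctol)
        traj <- stitch(bwd, fwd)
        list(traj = traj,
             events = extract_reactions(traj, config$backend,
                                        gtol = config$gtol,
                                        ctol = config$ctol))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed <- failed + 1L
        next
      }
      if (!all(res$traj$flags)) flagged <- flagged + 1L else {
        completed <- completed + 1L
      }
      events <- c(events, res$events)
    }
  }
  if (completed + flagged == 0L) {
    stop("no trajectory completed; ", failed, " of ", launched, " failed")
  }

  tab <- aggregate_reactions(events, s1$ensemble)
  report <- structure(list(
    table = tab, q0 = q0, qi_values = qi_values, qN = qN,
    ensemble_sizes = ensemble_sizes,
    ledger = c(launched = launched, completed = completed,
               flagged = flagged, failed = failed),
    equilibrium_ensemble = s1$ensemble,
    events = events,
    elapsed_s = proc.time()[["elapsed"]] - t0,
    config = config), class = "run_report")
  if (!is.null(config$outdir)) write_run_report(report, config$outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    "<run report: %d reactions from %d trajectories (%.1f s)>\n",
    nrow(x$table), x$ledger[["launched"]], x$elapsed_s))
  if (nrow(x$table)) {
    print(as.data.frame(x$table)[, c("reactant_smiles", "product_smiles",
                                     "count", "dE_act_kcal", "dE_rxn_kcal")])
  }
  invisible(x)
}

#' Write run artifacts to a directory
#'
#' Writes `reactions.csv`/`reactions.json` plus per-reaction transition
#' structures (via [write_reaction_table()]), the equilibrium ensemble as a
#' multi-frame XYZ, and `report.json` with the run summary and resolved
#' configuration.
#'
#' @param report a `run_report`
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reaction_table(report$table, dir)
  if (length(report$equilibrium_ensemble$members)) {
    write_xyz(report$equilibrium_ensemble$members,
              file.path(dir, "equilibrium_ensemble.xyz"))
  }
  cfg <- report$config
  summary <- list(
    q0 = report$q0, qi_values = report$qi_values, qN = report$qN,
    ensemble_sizes = report$ensemble_sizes,
    ledger = as.list(report$ledger),
    elapsed_s = report$elapsed_s,
    config = list(seed = cfg$seed, budget = cfg$budget,
                  stretch_factors = cfg$stretch_factors,
                  qmax_factor = cfg$qmax_factor, scan_step = cfg$scan_step,
                  timestep = cfg$timestep, temperature = cfg$temperature,
                  md_time_per_atom = cfg$md_time_per_atom,
                  k_per_atom = cfg$k_per_atom, alpha = cfg$alpha,
                  snapshot_interval = cfg$snapshot_interval,
                  md_restraint_k = cfg$md_restraint_k))
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
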