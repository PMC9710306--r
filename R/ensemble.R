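#' Conformer pruning thresholds
#'
#' Two optimized structures are duplicates when their RMSD, energy difference
#' and (finite) rotational constants are all within threshold simultaneously;
#' structures more than `ewin` above the best member are discarded outright.
#'
#' @param rmsd_thr duplicate RMSD threshold in Angstrom (default 0.125)
#' @param energy_thr duplicate energy window in kcal/mol (default 0.05)
#' @param rotconst_rel_thr relative rotational-constant threshold (default 0.01)
#' @param ewin max energy above the ensemble best, kcal/mol (default 35)
#' @return object of class `prune_thresholds`
#' @export
prune_thresholds <- function(rmsd_thr = 0.125, energy_thr = 0.05,
                             rotconst_rel_thr = 0.01, ewin = 35) {
  vals <- c(rmsd_thr, energy_thr, rotconst_rel_thr, ewin)
  if (any(vals <= 0)) stop("all pruning thresholds must be > 0")
  structure(list(rmsd_thr = rmsd_thr, energy_thr = energy_thr,
                 rotconst_rel_thr = rotconst_rel_thr, ewin = ewin),
            class = "prune_thresholds")
}

# Duplicate test: RMSD AND energy AND rotational constants all within
# thresholds. Only finite constants are compared (linear molecules carry an
# Inf sentinel on the vanishing moment).
is_duplicate <- function(a, b, thr) {
  de <- abs(a$energy - b$energy) * HARTREE_TO_KCAL
  if (de >= thr$energy_thr) return(FALSE)
  if (superpose_rmsd(a, b)$rmsd >= thr$rmsd_thr) return(FALSE)
  ra <- rotational_constants(a)
  rb <- rotational_constants(b)
  fin <- is.finite(ra) & is.finite(rb)
  if (any(is.finite(ra) != is.finite(rb))) return(FALSE)
  if (any(fin)) {
    rel <- abs(ra[fin] - rb[fin]) / pmax(abs(rb[fin]), 1e-12)
    if (any(rel >= thr$rotconst_rel_thr)) return(FALSE)
  }
  TRUE
}

#' Conformer ensemble
#'
#' @param members list of energy-tagged geometries, sorted ascending by energy
#' @param constr the [constraint()] the members satisfy (or NULL)
#' @return object of class `conformer_ensemble`
#' @export
conformer_ensemble <- function(members, constr = NULL) {
  e <- vapply(members, function(m) m$energy, numeric(1))
  if (is.unsorted(e)) stop("ensemble members must be sorted by energy")
  structure(list(members = members, constraint = constr),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  e <- ensemble_energies(x)
  cat(sprintf("<conformer ensemble: %d members, E %.6f..%.6f Ha>\n",
              length(x$members),
              if (length(e)) min(e) else NA, if (length(e)) max(e) else NA))
  invisible(x)
}

#' Member energies of an ensemble
#' @param ens a `conformer_ensemble`
#' @return numeric vector (Hartree)
#' @export
ensemble_energies <- function(ens) {
  vapply(ens$members, function(m) m$energy, numeric(1))
}

# Core pruning pass over energy-tagged geometries. Stable sort by
# (energy, input index) makes the retained representative of each duplicate
# class the lowest-energy member, tie-broken to the earlier-indexed input.
prune_members <- function(members, thr) {
  if (!length(members)) {
    return(list(kept = list(), report = data.frame()))
  }
  e <- vapply(members, function(m) m$energy, numeric(1))
  ord <- order(e, seq_along(members))
  kept <- list()
  action <- character(length(members))
  ebest <- e[ord[1]]
  for (idx in ord) {
    m <- members[[idx]]
    if ((m$energy - ebest) * HARTREE_TO_KCAL > thr$ewin) {
      action[idx] <- "dropped:ewin"
      next
    }
    dup <- FALSE
    for (kmem in kept) {
      if (is_duplicate(m, kmem, thr)) { dup <- TRUE; break }
    }
    action[idx] <- if (dup) "dropped:duplicate" else "kept"
    if (!dup) kept[[length(kept) + 1L]] <- m
  }
  list(kept = kept,
       report = data.frame(index = seq_along(members), energy = e,
                           action = action))
}

#' Optimize raw snapshots and prune to a distinct conformer ensemble
#'
#' Each snapshot is constrained-minimized (under `constr`, if given), then
#' duplicates are removed (joint RMSD / energy / rotational-constant rule,
#' lower-energy representative retained) and members above `thr$ewin` kcal/mol
#' over the best are discarded. Snapshots whose optimization fails or does not
#' converge are dropped with a warning; if none survive, an empty ensemble is
#' returned rather than an error.
#'
#' @param snapshots list of geometries (e.g. from [run_metadynamics()])
#' @param constr a [constraint()] or NULL
#' @param backend a backend
#' @param thr a [prune_thresholds()]
#' @param ... passed to [constrained_minimize()]
#' @return a `conformer_ensemble` with attribute `report` (pruning audit
#'   data.frame)
#' @export
optimize_and_prune <- function(snapshots, constr = NULL, backend,
                               thr = prune_thresholds(), ...) {
  if (!length(snapshots)) stop("no snapshots supplied")
  cons <- if (is.null(constr)) list() else list(constr)
  opt <- list()
  for (s in snapshots) {
    g <- tryCatch(constrained_minimize(s, cons, backend, ...),
                  error = function(e) NULL)
    if (!is.null(g) && isTRUE(attr(g, "converged"))) {
      opt[[length(opt) + 1L]] <- g
    }
  }
  if (!length(opt)) {
    warning("no snapshot survived optimization; returning empty ensemble")
    return(structure(conformer_ensemble(list(), constr),
                     report = data.frame()))
  }
  pr <- prune_members(opt, thr)
  e <- vapply(pr$kept, function(m) m$energy, numeric(1))
  structure(conformer_ensemble(pr$kept[order(e)], constr),
            report = pr$report)
}

#' Re-prune an existing ensemble
#'
#' Applies the duplicate and energy-window rules to already-optimized members.
#' Pruning a pruned ensemble is a no-op.
#'
#' @param ens a `conformer_ensemble`
#' @param thr a [prune_thresholds()]
#' @return a `conformer_ensemble`
#' @export
prune_ensemble <- function(ens, thr = prune_thresholds()) {
  pr <- prune_members(ens$members, thr)
  e <- vapply(pr$kept, function(m) m$energy, numeric(1))
  structure(conformer_ensemble(pr$kept[order(e)], ens$constraint),
            report = pr$report)
}
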