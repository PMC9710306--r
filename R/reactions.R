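#' Geometric bond perception
#'
#' Two atoms are bonded when their distance is at most
#' `scale * (r_cov(A) + r_cov(B))`, with single-bond covalent radii from the
#' bundled table. Returns the molecular graph: atoms, bond list, and connected
#' fragments.
#'
#' @param geom a `geometry`
#' @param scale covalent-radius scale factor (default 1.2)
#' @return object of class `molecular_graph`: list with `elements`, `bonds`
#'   (2-column matrix of 1-based atom index pairs, i < j), `fragments`
#'   (list of atom index vectors, one per connected component), `charge`
#' @export
perceive_bonds <- function(geom, scale = 1.2) {
  n <- n_atoms(geom)
  r <- covalent_radius(geom$elements)
  bonds <- matrix(integer(0), ncol = 2)
  adj <- vector("list", n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- sqrt(sum((geom$coords[i, ] - geom$coords[j, ])^2))
        if (d <= scale * (r[i] + r[j])) {
          bonds <- rbind(bonds, c(i, j))
          adj[[i]] <- c(adj[[i]], j)
          adj[[j]] <- c(adj[[j]], i)
        }
      }
    }
  }
  # connected components by BFS, deterministic order
  comp <- integer(n)
  ncomp <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    queue <- s
    comp[s] <- ncomp
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) { comp[w] <- ncomp; queue <- c(queue, w) }
      }
    }
  }
  fragments <- lapply(seq_len(ncomp), function(k) which(comp == k))
  structure(list(elements = geom$elements, bonds = bonds,
                 fragments = fragments, charge = geom$charge),
            class = "molecular_graph")
}

# Standard valences used by the formal-charge heuristic.
STANDARD_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                      P = 3, S = 2, Cl = 1, Br = 1, I = 1)

# Heuristic per-atom formal charges: distribute the total charge over atoms
# with a valence deficit (negative charge: most electronegative first by
# larger atomic number within CHNOPS/halogens; positive charge: reverse).
# Returns NULL when the heuristic cannot place the full charge.
assign_formal_charges <- function(elements, bonds, total_charge) {
  n <- length(elements)
  charges <- integer(n)
  if (total_charge == 0L) return(charges)
  degree <- integer(n)
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      degree[bonds[b, 1]] <- degree[bonds[b, 1]] + 1L
      degree[bonds[b, 2]] <- degree[bonds[b, 2]] + 1L
    }
  }
  syms <- element_symbol(elements)
  val <- STANDARD_VALENCE[syms]
  deficit <- ifelse(is.na(val), 0L, pmax(0L, as.integer(val - degree)))
  remaining <- total_charge
  if (total_charge < 0) {
    # electronegativity proxy: O > N > halogens > S > C ...
    en_rank <- c(F = 1, O = 2, Cl = 3, N = 4, Br = 5, I = 6, S = 7, C = 8,
                 P = 9, H = 10)
    ord <- order(ifelse(is.na(en_rank[syms]), 99, en_rank[syms]),
                 seq_len(n))
    for (i in ord) {
      while (remaining < 0 && deficit[i] > 0) {
        charges[i] <- charges[i] - 1L
        deficit[i] <- deficit[i] - 1L
        remaining <- remaining + 1L
      }
    }
  } else {
    # protonate-like positive charges on over-coordinated N/O/S first
    surplus <- ifelse(is.na(val), 0L, pmax(0L, as.integer(degree - val)))
    ord <- order(-surplus, seq_len(n))
    for (i in ord) {
      while (remaining > 0 && surplus[i] > 0) {
        charges[i] <- charges[i] + 1L
        surplus[i] <- surplus[i] - 1L
        remaining <- remaining - 1L
      }
    }
  }
  if (remaining != 0L) return(NULL)
  charges
}

# V2000 MOL block from elements/coords/bonds with explicit per-atom valence
# fields so Open Babel adds no implicit hydrogens (all H are explicit here).
mol_block <- function(elements, coords, bonds, formal_charges) {
  n <- length(elements)
  degree <- integer(n)
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      degree[bonds[b, 1]] <- degree[bonds[b, 1]] + 1L
      degree[bonds[b, 2]] <- degree[bonds[b, 2]] + 1L
    }
  }
  val_field <- ifelse(degree == 0L, 15L, degree)  # 15 encodes zero valence
  lines <- c("mol", " reaxplore", "",
             sprintf("%3d%3d  0  0  1  0  0  0  0  0999 V2000",
                     n, nrow(bonds)))
  lines <- c(lines, sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0%3d  0  0  0  0  0  0",
    coords[, 1], coords[, 2], coords[, 3],
    element_symbol(elements), val_field))
  if (nrow(bonds)) {
    lines <- c(lines, sprintf("%3d%3d  1  0", bonds[, 1], bonds[, 2]))
  }
  chg <- which(formal_charges != 0L)
  if (length(chg)) {
    for (i in chg) {
      lines <- c(lines, sprintf("M  CHG  1 %3d %3d", i, formal_charges[i]))
    }
  }
  c(lines, "M  END", "$$$$")
}

# Fallback identifier when SMILES canonicalization fails: per-fragment
# Hill-formula string annotated with the total charge.
formula_fallback <- function(elements, fragments, charge) {
  frag_strings <- vapply(fragments, function(idx) {
    syms <- element_symbol(elements[idx])
    tab <- table(syms)
    ord <- c(intersect(c("C", "H"), names(tab)),
             sort(setdiff(names(tab), c("C", "H"))))
    paste0(vapply(ord, function(s) {
      if (tab[[s]] == 1) s else paste0(s, tab[[s]])
    }, character(1)), collapse = "")
  }, character(1))
  paste0(paste(sort(frag_strings), collapse = "."),
         if (charge != 0) sprintf("{%+d}", charge) else "")
}

#' Canonical SMILES of a geometry
#'
#' Perceives bonds geometrically, assigns heuristic formal charges, and
#' converts the resulting molecular graph to canonical SMILES with Open Babel
#' (via ChemmineOB). Fragment SMILES are sorted lexicographically and joined
#' with dots, so bimolecular complexes compare equal regardless of atom order.
#' With `drop_metals`, atoms in `metal_set` (default: d-block elements) are
#' removed before graph construction to avoid spurious bond changes around
#' metal centers. If canonicalization fails, a charge-annotated formula string
#' is returned instead (deterministic, logged via a warning).
#'
#' @param geom a `geometry`
#' @param drop_metals remove metal atoms before conversion (default FALSE)
#' @param metal_set atomic numbers treated as metals
#' @param scale bond-perception scale factor (default 1.2)
#' @return canonical SMILES string (fragments dot-joined, sorted)
#' @export
to_canonical_smiles <- function(geom, drop_metals = FALSE,
                                metal_set = TRANSITION_METALS, scale = 1.2) {
  elements <- geom$elements
  coords <- geom$coords
  charge <- geom$charge
  if (drop_metals) {
    keep <- !(elements %in% metal_set)
    if (!any(keep)) return("")
    elements <- elements[keep]
    coords <- coords[keep, , drop = FALSE]
  }
  sub <- geometry(elements, coords, charge = charge,
                  multiplicity = geom$multiplicity)
  graph <- perceive_bonds(sub, scale = scale)
  charges <- assign_formal_charges(elements, graph$bonds, charge)
  if (is.null(charges)) {
    warning("formal-charge assignment failed; using formula fallback")
    return(formula_fallback(elements, graph$fragments, charge))
  }
  mol <- paste(mol_block(elements, coords, graph$bonds, charges),
               collapse = "\n")
  smi <- tryCatch({
    raw <- ChemmineOB::convertFormat("SDF", "CAN", mol)
    strsplit(raw, "[\t\n]")[[1]][1]
  }, error = function(e) NA_character_)
  if (is.na(smi) || !nzchar(smi)) {
    warning("SMILES canonicalization failed; using formula fallback")
    return(formula_fallback(elements, graph$fragments, charge))
  }
  paste(sort(strsplit(smi, ".", fixed = TRUE)[[1]]), collapse = ".")
}

#' Locate energy minima of a trajectory
#'
#' Indices of local minima of the frame-energy sequence. An endpoint counts as
#' a minimum when the sequence does not decrease away from it, so a constant
#' profile yields exactly the two endpoints.
#'
#' @param traj a `trajectory` (>= 2 frames)
#' @return integer vector of frame indices
#' @export
locate_minima <- function(traj) {
  e <- trajectory_energies(traj)
  n <- length(e)
  if (n < 2) stop("locate_minima needs at least 2 frames")
  idx <- integer(0)
  if (e[1] <= e[2]) idx <- c(idx, 1L)
  if (n > 2) {
    for (j in 2:(n - 1)) {
      if (e[j] < e[j - 1] && e[j] <= e[j + 1]) idx <- c(idx, j)
    }
  }
  if (e[n] <= e[n - 1]) idx <- c(idx, n)
  unique(idx)
}

#' Extract reaction events from a stitched trajectory
#'
#' Each trajectory energy minimum is re-optimized without constraints to
#' verify it is a stable species, then converted to canonical SMILES.
#' Consecutive minima with different SMILES yield one reaction event whose
#' transition-structure frame is the highest-energy frame strictly between the
#' two minima (ties resolved to the earliest frame). If an unconstrained
#' re-optimization relaxes to a different species than the raw frame, the
#' relaxed species is used (an unstable intermediate, noted in the event).
#'
#' @param traj a stitched reactant-to-product `trajectory`
#' @param backend backend used for the unconstrained re-optimizations
#' @param drop_metals passed to [to_canonical_smiles()]
#' @param ... passed to [constrained_minimize()]
#' @return list of `reaction_event` objects; each has fields
#'   `reactant_smiles`, `product_smiles`, `ts_frame_index`, `ts_geometry`,
#'   `ts_energy`, `reactant_frame_index`, `product_frame_index`,
#'   `reactant_energy`, `product_energy` (re-optimized, Hartree),
#'   `ts_flagged` (TRUE when the TS frame's scan step had not converged),
#'   `provenance`
#' @export
extract_reactions <- function(traj, backend, drop_metals = FALSE, ...) {
  minima <- locate_minima(traj)
  if (length(minima) < 2) return(list())
  e <- trajectory_energies(traj)
  relaxed <- list()
  smiles <- character(length(minima))
  for (k in seq_along(minima)) {
    g <- constrained_minimize(traj$frames[[minima[k]]], list(), backend, ...)
    relaxed[[k]] <- g
    smiles[k] <- to_canonical_smiles(g, drop_metals = drop_metals)
  }
  events <- list()
  for (k in seq_len(length(minima) - 1)) {
    if (smiles[k] == smiles[k + 1]) next
    i0 <- minima[k]; i1 <- minima[k + 1]
    if (i1 - i0 < 2) {
      # adjacent minima cannot bracket a transition structure; skip
      next
    }
    between <- (i0 + 1):(i1 - 1)
    ts_idx <- between[which.max(e[between])]
    events[[length(events) + 1L]] <- structure(
      list(reactant_smiles = smiles[k], product_smiles = smiles[k + 1],
           ts_frame_index = ts_idx, ts_geometry = traj$frames[[ts_idx]],
           ts_energy = e[ts_idx],
           reactant_frame_index = i0, product_frame_index = i1,
           reactant_energy = relaxed[[k]]$energy,
           product_energy = relaxed[[k + 1]]$energy,
           ts_flagged = !traj$flags[ts_idx],
           provenance = traj$provenance),
      class = "reaction_event")
  }
  events
}

#' Aggregate reaction events into a reaction table
#'
#' Rows are keyed by the (reactant SMILES, product SMILES) pair. For each row
#' the guess transition structure is the lowest-energy transition structure
#' over all events, the estimated activation energy is its energy minus the
#' energy of the most stable reactant conformer (the step-1 equilibrium
#' ensemble), and the reaction energy uses the best re-optimized product
#' conformer seen, against the same reference.
#'
#' @param events list of `reaction_event` objects (possibly across many
#'   trajectories)
#' @param reactant_ensemble the equilibrium `conformer_ensemble` providing the
#'   reference energy
#' @return a `reaction_table`: data.frame with columns `reactant_smiles`,
#'   `product_smiles`, `count`, `dE_act_kcal`, `dE_rxn_kcal`, `approximate`
#'   (TRUE when the best TS frame was flagged non-converged), plus attribute
#'   `best_ts` (list of TS geometries, one per row)
#' @export
aggregate_reactions <- function(events, reactant_ensemble) {
  if (!length(reactant_ensemble$members)) {
    stop("reactant ensemble is empty; no reference energy")
  }
  eref <- min(ensemble_energies(reactant_ensemble))
  if (!length(events)) {
    tab <- data.frame(reactant_smiles = character(0),
                      product_smiles = character(0),
                      count = integer(0), dE_act_kcal = numeric(0),
                      dE_rxn_kcal = numeric(0), approximate = logical(0),
                      stringsAsFactors = FALSE)
    return(structure(tab, best_ts = list(), reference_energy = eref,
                     class = c("reaction_table", "data.frame")))
  }
  keys <- vapply(events, function(ev) {
    paste(ev$reactant_smiles, ev$product_smiles, sep = ">>")
  }, character(1))
  ukeys <- unique(keys)
  rows <- vector("list", length(ukeys))
  best_ts <- vector("list", length(ukeys))
  for (r in seq_along(ukeys)) {
    evs <- events[keys == ukeys[r]]
    ts_e <- vapply(evs, function(ev) ev$ts_energy, numeric(1))
    best <- which.min(ts_e)
    prod_e <- min(vapply(evs, function(ev) ev$product_energy, numeric(1)))
    rows[[r]] <- data.frame(
      reactant_smiles = evs[[1]]$reactant_smiles,
      product_smiles = evs[[1]]$product_smiles,
      count = length(evs),
      dE_act_kcal = (ts_e[best] - eref) * HARTREE_TO_KCAL,
      dE_rxn_kcal = (prod_e - eref) * HARTREE_TO_KCAL,
      approximate = evs[[best]]$ts_flagged,
      stringsAsFactors = FALSE)
    best_ts[[r]] <- evs[[best]]$ts_geometry
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$dE_act_kcal)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, best_ts = best_ts[ord], reference_energy = eref,
            class = c("reaction_table", "data.frame"))
}

#' Write a reaction table to CSV and JSON
#'
#' Also exports each row's best transition-structure guess as a single-frame
#' XYZ under `<dir>/ts/` and records the path in the table.
#'
#' @param tab a `reaction_table`
#' @param dir output directory (created if missing)
#' @return the augmented data.frame, invisibly
#' @export
write_reaction_table <- function(tab, dir) {
  dir.create(file.path(dir, "ts"), showWarnings = FALSE, recursive = TRUE)
  best_ts <- attr(tab, "best_ts")
  paths <- character(nrow(tab))
  for (r in seq_len(nrow(tab))) {
    paths[r] <- file.path("ts", sprintf("ts_%03d.xyz", r))
    write_xyz(best_ts[[r]], file.path(dir, paths[r]))
  }
  out <- as.data.frame(tab)
  out$ts_xyz_path <- paths
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "count"
  out[num] <- lapply(out[num], function(x) round(x, 6))
  utils::write.csv(out, file.path(dir, "reactions.csv"), row.names = FALSE)
  jsonlite::write_json(out, file.path(dir, "reactions.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(out)
}
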