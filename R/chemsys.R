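#' Molecular geometry
#'
#' Core container for a molecular structure: atomic numbers, Cartesian
#' coordinates in Angstrom, total charge and spin multiplicity, and an
#' optional potential energy tag in Hartree.
#'
#' @param elements atomic numbers (integer vector) or element symbols
#'   (character vector)
#' @param coords numeric N x 3 matrix of Cartesian coordinates in Angstrom
#' @param charge integer total charge (default 0)
#' @param multiplicity positive integer spin multiplicity (default 1)
#' @param energy optional potential energy in Hartree
#' @return an object of class `geometry`
#' @export
geometry <- function(elements, coords, charge = 0L, multiplicity = 1L,
                     energy = NULL) {
  if (is.character(elements)) elements <- element_number(elements)
  elements <- as.integer(elements)
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(elements) != nrow(coords)) {
    stop("length(elements) [", length(elements),
         "] must equal number of coordinate rows [", nrow(coords), "]")
  }
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  if (multiplicity < 1) stop("multiplicity must be >= 1")
  if (!is.null(energy) && !is.finite(energy)) {
    stop("energy, when present, must be finite")
  }
  structure(
    list(elements = elements, coords = coords,
         charge = as.integer(charge), multiplicity = as.integer(multiplicity),
         energy = energy),
    class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry: %d atoms [%s], charge %d, mult %d%s>\n",
              n_atoms(x), paste(element_symbol(x$elements), collapse = " "),
              x$charge, x$multiplicity,
              if (is.null(x$energy)) "" else sprintf(", E = %.8f Ha", x$energy)))
  invisible(x)
}

#' Number of atoms in a geometry
#' @param geom a `geometry`
#' @return integer atom count
#' @export
n_atoms <- function(geom) length(geom$elements)

#' Replace the coordinates of a geometry
#'
#' Returns a copy with new coordinates; the energy tag is dropped unless
#' supplied, since it no longer describes the structure.
#' @param geom a `geometry`
#' @param coords new N x 3 coordinate matrix (Angstrom)
#' @param energy optional energy (Hartree) for the new structure
#' @return a `geometry`
#' @export
set_coords <- function(geom, coords, energy = NULL) {
  geometry(geom$elements, coords, geom$charge, geom$multiplicity, energy)
}

#' Internal coordinate definition
#'
#' A distance (2 atoms, Angstrom), bending angle (3 atoms, degrees) or
#' dihedral angle (4 atoms, degrees) defined over 1-based atom indices.
#'
#' @param kind one of "distance", "angle", "dihedral"
#' @param atoms 2, 3 or 4 distinct 1-based atom indices
#' @return an object of class `int_coord`
#' @export
int_coord <- function(kind = c("distance", "angle", "dihedral"), atoms) {
  kind <- match.arg(kind)
  need <- c(distance = 2L, angle = 3L, dihedral = 4L)[[kind]]
  atoms <- as.integer(atoms)
  if (length(atoms) != need) {
    stop(kind, " coordinate needs ", need, " atom indices, got ", length(atoms))
  }
  if (anyDuplicated(atoms)) stop("atom indices must be distinct")
  if (any(atoms < 1)) stop("atom indices are 1-based and must be >= 1")
  structure(list(kind = kind, atoms = atoms), class = "int_coord")
}

#' @export
print.int_coord <- function(x, ...) {
  cat(sprintf("<%s(%s)>\n", x$kind, paste(x$atoms, collapse = ",")))
  invisible(x)
}

check_indices <- function(geom, coord) {
  if (any(coord$atoms > n_atoms(geom))) {
    stop("coordinate refers to atom index beyond the ", n_atoms(geom),
         " atoms present")
  }
}

#' Activation schedule for the driven coordinate
#'
#' Holds the equilibrium value q0 of the activating coordinate, the
#' intermediate activation values at which constrained conformer searches are
#' run, the maximal scanned value qN, and the relaxed-scan increment.
#'
#' @param coordinate an [int_coord()]
#' @param q0 equilibrium value of the coordinate
#' @param intermediates ordered activation values strictly between q0 and qN
#' @param qN maximal scanned value
#' @param scan_step positive scan increment (Angstrom or degrees)
#' @return an object of class `activation_schedule`
#' @export
activation_schedule <- function(coordinate, q0, intermediates, qN, scan_step) {
  stopifnot(inherits(coordinate, "int_coord"))
  if (scan_step <= 0) stop("scan_step must be > 0")
  seqv <- c(q0, intermediates, qN)
  if (!(all(diff(seqv) > 0) || all(diff(seqv) < 0))) {
    stop("q0, intermediates, qN must be strictly monotone ",
         "(stretching or compression)")
  }
  structure(list(coordinate = coordinate, q0 = q0,
                 intermediates = as.numeric(intermediates), qN = qN,
                 scan_step = scan_step),
            class = "activation_schedule")
}

#' Measure an internal coordinate
#'
#' @param geom a `geometry`
#' @param coord an [int_coord()]
#' @return distance in Angstrom (>= 0), angle in degrees in [0, 180],
#'   or dihedral in degrees in (-180, 180]
#' @export
measure <- function(geom, coord) {
  check_indices(geom, coord)
  x <- geom$coords
  a <- coord$atoms
  switch(coord$kind,
    distance = {
      sqrt(sum((x[a[1], ] - x[a[2], ])^2))
    },
    angle = {
      v1 <- x[a[1], ] - x[a[2], ]
      v2 <- x[a[3], ] - x[a[2], ]
      n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
      if (n1 < 1e-10 || n2 < 1e-10) {
        stop("degenerate angle: coincident atoms in definition")
      }
      cosang <- sum(v1 * v2) / (n1 * n2)
      acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    },
    dihedral = {
      b1 <- x[a[2], ] - x[a[1], ]
      b2 <- x[a[3], ] - x[a[2], ]
      b3 <- x[a[4], ] - x[a[3], ]
      n1 <- cross3(b1, b2)
      n2 <- cross3(b2, b3)
      if (sqrt(sum(n1^2)) < 1e-12 || sqrt(sum(n2^2)) < 1e-12) {
        stop("degenerate dihedral: collinear or coincident atoms in definition")
      }
      m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
      ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
      if (ang <= -180) ang <- ang + 360
      ang
    })
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Minimum RMSD over rigid-body superposition (Kabsch)
#'
#' Aligns `b` onto `a` with the optimal proper rotation and translation and
#' returns the minimized root-mean-square deviation. All atoms enter
#' unweighted and atom order is fixed by input (no permutation matching);
#' `heavy_only = TRUE` restricts the comparison to non-hydrogen atoms.
#'
#' @param a,b geometries with identical element sequences
#' @param heavy_only if TRUE, hydrogens are excluded from the fit
#' @return list with `rmsd` (Angstrom), `rotation` (3 x 3 proper rotation
#'   applied to centered `b`), `translation` (the offset such that
#'   `b %*% t(R) + translation` superposes onto `a`)
#' @export
superpose_rmsd <- function(a, b, heavy_only = FALSE) {
  if (!identical(a$elements, b$elements)) {
    stop("geometries have different element sequences; cannot superpose")
  }
  sel <- if (heavy_only) which(a$elements != 1L) else seq_len(n_atoms(a))
  if (length(sel) < 1) stop("no atoms selected for superposition")
  xa <- a$coords[sel, , drop = FALSE]
  xb <- b$coords[sel, , drop = FALSE]
  ca <- colMeans(xa); cb <- colMeans(xb)
  xac <- sweep(xa, 2, ca)
  xbc <- sweep(xb, 2, cb)
  R <- kabsch_rotation(xbc, xac)
  diffs <- xac - xbc %*% t(R)
  rmsd <- sqrt(sum(diffs^2) / length(sel))
  list(rmsd = rmsd, rotation = R, translation = ca - as.vector(R %*% cb))
}

# Optimal proper rotation R minimizing ||Y - X R^T||_F for centered X, Y.
kabsch_rotation <- function(X, Y) {
  H <- t(X) %*% Y
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  s$v %*% D %*% t(s$u)
}

#' Gradient of the superposition RMSD with respect to current coordinates
#'
#' Analytic gradient of [superpose_rmsd()] treating `current` as the variable
#' structure. By the envelope theorem the optimal rotation and translation
#' need not be differentiated, giving
#' d(rmsd)/dx_i = (x'_i - R y'_i) / (N * rmsd) with centered coordinates.
#' The RMSD gradient is singular at zero displacement; below `floor` a zero
#' matrix is returned (the metadynamics kernel chain rule vanishes smoothly
#' there as well).
#'
#' @param current,reference geometries with identical element sequences
#' @param floor RMSD (Angstrom) below which the zero gradient is returned
#' @return N x 3 gradient matrix (dimensionless, Angstrom/Angstrom)
#' @export
rmsd_gradient <- function(current, reference, floor = 1e-6) {
  fit <- superpose_rmsd(current, reference)
  n <- n_atoms(current)
  if (fit$rmsd < floor) return(matrix(0, n, 3))
  xc <- sweep(current$coords, 2, colMeans(current$coords))
  yc <- sweep(reference$coords, 2, colMeans(reference$coords))
  (xc - yc %*% t(fit$rotation)) / (n * fit$rmsd)
}

#' Principal rotational constants
#'
#' Diagonalizes the inertia tensor built from standard atomic masses and
#' returns the three rotational constants sorted descending. For a linear
#' molecule (one vanishing principal moment) the corresponding constant is
#' reported as `Inf`; duplicate detection downstream compares only the finite
#' constants.
#'
#' @param geom a `geometry` with at least 2 atoms
#' @param unit "MHz" (default) or "cm-1"
#' @return numeric vector of 3 constants, sorted descending
#' @export
rotational_constants <- function(geom, unit = c("MHz", "cm-1")) {
  unit <- match.arg(unit)
  if (n_atoms(geom) < 2) stop("rotational constants need at least 2 atoms")
  m <- element_mass(geom$elements)
  x <- sweep(geom$coords, 2, colSums(geom$coords * m) / sum(m))
  I <- matrix(0, 3, 3)
  r2 <- rowSums(x^2)
  for (k in 1:3) I[k, k] <- sum(m * (r2 - x[, k]^2))
  I[1, 2] <- I[2, 1] <- -sum(m * x[, 1] * x[, 2])
  I[1, 3] <- I[3, 1] <- -sum(m * x[, 1] * x[, 3])
  I[2, 3] <- I[3, 2] <- -sum(m * x[, 2] * x[, 3])
  mom <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
  # numerical floor: moments below ~1e-8 amu A^2 are treated as zero (linear)
  consts <- ifelse(mom < 1e-8, Inf, ROTCONST_MHZ / mom)
  if (unit == "cm-1") consts <- consts * 1e6 / 2.99792458e10
  sort(consts, decreasing = TRUE)
}

#' Read a (multi-frame) XYZ file
#'
#' Parses the standard XYZ dialect where each frame is an atom count line, a
#' comment line, and one `symbol x y z` line per atom. An energy in Hartree is
#' picked up from a `E=<value>` token on the comment line when present.
#'
#' @param path file path
#' @param charge,multiplicity attached to every frame (XYZ does not carry them)
#' @return list of `geometry` frames
#' @export
read_xyz <- function(path, charge = 0L, multiplicity = 1L) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1) {
      stop("XYZ parse error at line ", i, ": expected atom count, got '",
           lines[i], "'")
    }
    if (i + 1L + nat > length(lines)) {
      stop("XYZ parse error: frame starting at line ", i, " declares ", nat,
           " atoms but the file ends early")
    }
    comment <- lines[i + 1L]
    energy <- NULL
    em <- regmatches(comment, regexpr("E=\\s*[-+0-9.eEdD]+", comment))
    if (length(em) == 1 && nzchar(em)) {
      energy <- as.numeric(gsub("[dD]", "e", sub("E=\\s*", "", em)))
    }
    syms <- character(nat)
    xyz <- matrix(NA_real_, nat, 3)
    for (k in seq_len(nat)) {
      ln <- i + 1L + k
      tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(tok) < 4) {
        stop("XYZ parse error at line ", ln, " (frame starting line ", i,
             "): expected 'symbol x y z'")
      }
      vals <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(vals)) {
        stop("XYZ parse error at line ", ln, ": non-numeric coordinate")
      }
      syms[k] <- tok[1]
      xyz[k, ] <- vals
    }
    z <- if (all(grepl("^[0-9]+$", syms))) as.integer(syms) else element_number(syms)
    frames[[length(frames) + 1L]] <-
      geometry(z, xyz, charge = charge, multiplicity = multiplicity,
               energy = energy)
    i <- i + 2L + nat
  }
  if (!length(frames)) stop("no frames found in '", path, "'")
  frames
}

#' Write geometries as a multi-frame XYZ file
#'
#' Frame energies, when present, are stored on the comment line as
#' `E=<value>`; extra comment text can be supplied per frame.
#'
#' @param frames a `geometry` or list of them
#' @param path output file path
#' @param comments optional character vector of extra comment text per frame
#' @return `path`, invisibly
#' @export
write_xyz <- function(frames, path, comments = NULL) {
  if (inherits(frames, "geometry")) frames <- list(frames)
  out <- character(0)
  for (j in seq_along(frames)) {
    g <- frames[[j]]
    cm <- if (!is.null(comments)) comments[[j]] else ""
    if (!is.null(g$energy)) {
      cm <- trimws(paste(sprintf("E=%.10f", g$energy), cm))
    }
    out <- c(out, as.character(n_atoms(g)), cm,
             sprintf("%-3s %18.10f %18.10f %18.10f",
                     element_symbol(g$elements),
                     g$coords[, 1], g$coords[, 2], g$coords[, 3]))
  }
  writeLines(out, path)
  invisible(path)
}
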