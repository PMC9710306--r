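# Physical constants and element data used across the package.
# Internal units: length in Angstrom, energy in Hartree, time in fs,
# mass in unified atomic mass units (amu), temperature in Kelvin.

## 1 Hartree in kcal/mol (user-facing reports are in kcal/mol)
HARTREE_TO_KCAL <- 627.509474

## Acceleration conversion: (Hartree/Angstrom)/amu -> Angstrom/fs^2
## = E_h[J] / (1 A[m] * 1 amu[kg]) expressed in A/fs^2
FORCE_TO_ACCEL <- 4.3597447222071e-18 / 1e-10 / 1.66053906660e-27 * 1e-20

## Boltzmann constant in amu A^2 fs^-2 K^-1
KB_MD <- 1.380649e-23 / (1.66053906660e-27 * 1e-10^2 / 1e-15^2)

## Rotational constant prefactor: B[MHz] = ROTCONST_MHZ / I[amu A^2]
## h / (8 pi^2 I), with I converted from amu A^2 to kg m^2, result in MHz.
ROTCONST_MHZ <- 6.62607015e-34 /
  (8 * pi^2 * 1.66053906660e-27 * 1e-20) / 1e6

## Element symbols indexed by atomic number (1..86)
ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn")

## Standard atomic weights (amu), indexed by atomic number (1..86)
ELEMENT_MASSES <- c(
  1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999, 18.998, 20.180,
  22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45, 39.948, 39.098, 40.078,
  44.956, 47.867, 50.942, 51.996, 54.938, 55.845, 58.933, 58.693, 63.546, 65.38,
  69.723, 72.630, 74.922, 78.971, 79.904, 83.798, 85.468, 87.62, 88.906, 91.224,
  92.906, 95.95, 98.0, 101.07, 102.906, 106.42, 107.868, 112.414, 114.818, 118.710,
  121.760, 127.60, 126.904, 131.293, 132.905, 137.327, 138.905, 140.116, 140.908, 144.242,
  145.0, 150.36, 151.964, 157.25, 158.925, 162.500, 164.930, 167.259, 168.934, 173.045,
  174.967, 178.49, 180.948, 183.84, 186.207, 190.23, 192.217, 195.084, 196.967, 200.592,
  204.38, 207.2, 208.980, 209.0, 210.0, 222.0)

## Covalent radii (Angstrom), single-bond values (Cordero et al. compilation),
## indexed by atomic number (1..86). Used by geometric bond perception.
COVALENT_RADII <- c(
  0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
  1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06, 2.03, 1.76,
  1.70, 1.60, 1.53, 1.39, 1.39, 1.32, 1.26, 1.24, 1.32, 1.22,
  1.22, 1.20, 1.19, 1.20, 1.20, 1.16, 2.20, 1.95, 1.90, 1.75,
  1.64, 1.54, 1.47, 1.46, 1.42, 1.39, 1.45, 1.44, 1.42, 1.39,
  1.39, 1.38, 1.39, 1.40, 2.44, 2.15, 2.07, 2.04, 2.03, 2.01,
  1.99, 1.98, 1.98, 1.96, 1.94, 1.92, 1.92, 1.89, 1.90, 1.87,
  1.87, 1.75, 1.70, 1.62, 1.51, 1.44, 1.41, 1.36, 1.36, 1.32,
  1.45, 1.46, 1.48, 1.40, 1.50, 1.50)

## d-block atomic numbers; default set removed before SMILES conversion
## when drop_metals is requested (spurious bond changes around metal centers).
TRANSITION_METALS <- c(21:30, 39:48, 71:80)

#' Convert element symbols to atomic numbers
#' @param symbols character vector of element symbols (e.g. "Cl")
#' @return integer vector of atomic numbers
#' @export
element_number <- function(symbols) {
  z <- match(symbols, ELEMENT_SYMBOLS)
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(symbols[is.na(z)], collapse = ", "))
  }
  as.integer(z)
}

#' Convert atomic numbers to element symbols
#' @param z integer vector of atomic numbers
#' @return character vector of element symbols
#' @export
element_symbol <- function(z) {
  if (any(z < 1 | z > length(ELEMENT_SYMBOLS))) {
    stop("atomic number out of supported range 1..", length(ELEMENT_SYMBOLS))
  }
  ELEMENT_SYMBOLS[z]
}

element_mass <- function(z) {
  if (any(z < 1 | z > length(ELEMENT_MASSES))) {
    stop("no mass tabulated for atomic number(s) ",
         paste(unique(z[z < 1 | z > length(ELEMENT_MASSES)]), collapse = ", "))
  }
  ELEMENT_MASSES[z]
}

covalent_radius <- function(z) {
  if (any(z < 1 | z > length(COVALENT_RADII))) {
    stop("no covalent radius tabulated for atomic number(s) ",
         paste(unique(z[z < 1 | z > length(COVALENT_RADII)]), collapse = ", "))
  }
  COVALENT_RADII[z]
}
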