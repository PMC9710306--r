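# Shared fixtures, built once per test session. The collinear-exchange
# fixtures carry their own brute-force grid-oracle results.

fixture_env <- new.env()

get_fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

exchange_symmetric <- function() {
  get_fixture("exchange_sym", function() make_collinear_exchange(oracle_n = 80))
}

exchange_asymmetric <- function(asym) {
  get_fixture(paste0("exchange_asym_", asym), function() {
    make_collinear_exchange(asymmetry = asym, oracle_n = 80)
  })
}

torsion_chain <- function() {
  get_fixture("torsion", function() make_torsion_chain())
}

# Morse diatomic test system (H2-like parameters)
diatomic_fixture <- function(r = 0.74) {
  params <- morse_params(list("H-H" = c(De = 0.17, a = 1.9, re = 0.74)))
  list(geom = geometry(c("H", "H"), rbind(c(0, 0, 0), c(r, 0, 0))),
       backend = toy_morse_backend(params),
       params = params, De = 0.17, a = 1.9, re = 0.74,
       coord = int_coord("distance", c(1, 2)))
}

# random rigid motion applied to a geometry
rigid_copy <- function(geom, seed) {
  set.seed(seed)
  th <- stats::runif(3, -pi, pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  set_coords(geom, geom$coords %*% t(Rz %*% Ry %*% Rx) +
               matrix(stats::runif(3, -3, 3), n_atoms(geom), 3, byrow = TRUE),
             energy = geom$energy)
}

# reduced-size workflow configuration for the toy exchange systems
exchange_run_config <- function(sys, seed, outdir = NULL,
                                stretch = c(1.2, 1.35, 1.5), budget = 12L) {
  run_config(sys$geometry, sys$coordinate, sys$backend,
             multiplicity = 2L, stretch_factors = stretch,
             budget = budget, seed = seed, outdir = outdir)
}

# hand-built reaction event for aggregation arithmetic tests
fake_event <- function(reactant, product, ts_energy_ha, product_energy_ha,
                       ts_geom, flagged = FALSE) {
  structure(list(reactant_smiles = reactant, product_smiles = product,
                 ts_frame_index = 2L, ts_geometry = ts_geom,
                 ts_energy = ts_energy_ha,
                 reactant_frame_index = 1L, product_frame_index = 3L,
                 reactant_energy = ts_energy_ha - 0.01,
                 product_energy = product_energy_ha,
                 ts_flagged = flagged, provenance = list()),
            class = "reaction_event")
}

# tiny geometry with a prescribed energy, for table arithmetic
tagged_diatomic <- function(energy_ha, r = 0.9) {
  geometry(c("H", "H"), rbind(c(0, 0, 0), c(r, 0, 0)), energy = energy_ha)
}
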