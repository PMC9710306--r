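#' Energy/gradient result
#'
#' The uniform contract every backend returns: potential energy in Hartree,
#' an N x 3 gradient in Hartree/Angstrom, and the engine's own convergence
#' self-report.
#'
#' @param energy energy in Hartree
#' @param gradient N x 3 numeric matrix, Hartree/Angstrom
#' @param converged logical engine self-report
#' @param info optional list of engine diagnostics
#' @return object of class `energy_gradient`
#' @export
energy_gradient <- function(energy, gradient, converged = TRUE, info = NULL) {
  gradient <- matrix(as.numeric(gradient), ncol = 3)
  if (converged && !is.finite(energy)) {
    stop("backend reported convergence with non-finite energy")
  }
  structure(list(energy = energy, gradient = gradient,
                 converged = converged, info = info),
            class = "energy_gradient")
}

#' Evaluate a backend on a geometry
#'
#' @param backend a backend object (see [toy_morse_backend()],
#'   [external_engine_backend()])
#' @param geom a `geometry`
#' @return an [energy_gradient()]
#' @export
backend_evaluate <- function(backend, geom) {
  UseMethod("backend_evaluate")
}

#' Morse pair parameters for the toy reactive force field
#'
#' @param pairs named list; names are element pairs like `"H-Cl"` (order
#'   irrelevant), values are numeric vectors or lists with components
#'   `De` (well depth, Hartree), `a` (width, 1/Angstrom), `re` (equilibrium
#'   distance, Angstrom)
#' @param cutoff pair cutoff radius in Angstrom; interactions switch smoothly
#'   to exactly zero at the cutoff
#' @param switch_start distance where the C1 switching region begins
#'   (default 0.8 * cutoff)
#' @return object of class `morse_params`
#' @export
morse_params <- function(pairs, cutoff = 10, switch_start = 0.8 * cutoff) {
  norm <- list()
  for (nm in names(pairs)) {
    p <- as.list(pairs[[nm]])
    if (is.null(names(p)) || !all(c("De", "a", "re") %in% names(p))) {
      p <- stats::setNames(as.list(unlist(pairs[[nm]])[1:3]), c("De", "a", "re"))
    }
    if (p$De <= 0 || p$a <= 0 || p$re <= 0) {
      stop("Morse parameters for pair ", nm, " must all be > 0")
    }
    norm[[pair_key_symbols(strsplit(nm, "-", fixed = TRUE)[[1]])]] <- p
  }
  if (switch_start >= cutoff) stop("switch_start must be < cutoff")
  structure(list(pairs = norm, cutoff = cutoff, switch_start = switch_start),
            class = "morse_params")
}

pair_key_symbols <- function(two_symbols) {
  paste(sort(two_symbols), collapse = "-")
}

pair_key <- function(z1, z2) {
  pair_key_symbols(c(element_symbol(z1), element_symbol(z2)))
}

# C1 switching function and derivative: 1 below s0, 0 above s1.
switch_fn <- function(r, s0, s1) {
  if (r <= s0) return(c(1, 0))
  if (r >= s1) return(c(0, 0))
  t <- (r - s0) / (s1 - s0)
  c(1 - t * t * (3 - 2 * t), -6 * t * (1 - t) / (s1 - s0))
}

#' Toy reactive force field: pairwise Morse potentials
#'
#' A sum of Morse terms `De * ((1 - exp(-a (r - re)))^2 - 1)` over all atom
#' pairs inside the cutoff, with a C1 switch to exactly zero at the cutoff.
#' This is the simplest potential that supports bond breaking and formation,
#' so every stage of the workflow can be exercised and checked against
#' brute-force grid oracles without an external engine. It makes no claim to
#' quantitative chemistry.
#'
#' @param params a [morse_params()]
#' @param label optional backend label
#' @return backend object usable with [backend_evaluate()]
#' @export
toy_morse_backend <- function(params, label = "toy-morse") {
  stopifnot(inherits(params, "morse_params"))
  structure(list(params = params, label = label),
            class = c("morse_backend", "backend"))
}

#' @export
backend_evaluate.morse_backend <- function(backend, geom) {
  p <- backend$params
  x <- geom$coords
  n <- n_atoms(geom)
  energy <- 0
  grad <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dvec <- x[i, ] - x[j, ]
      r <- sqrt(sum(dvec^2))
      if (r >= p$cutoff) next
      key <- pair_key(geom$elements[i], geom$elements[j])
      pp <- p$pairs[[key]]
      if (is.null(pp)) {
        stop("no Morse parameters for element pair ", key)
      }
      ex <- exp(-pp$a * (r - pp$re))
      v <- pp$De * ((1 - ex)^2 - 1)
      dv <- 2 * pp$De * pp$a * ex * (1 - ex)
      sw <- switch_fn(r, p$switch_start, p$cutoff)
      energy <- energy + v * sw[1]
      dEdr <- dv * sw[1] + v * sw[2]
      g <- dEdr * dvec / r
      grad[i, ] <- grad[i, ] + g
      grad[j, ] <- grad[j, ] - g
    }
  }
  energy_gradient(energy, grad, converged = TRUE)
}

#' Closed-form Morse pair energy
#'
#' Energy of a single Morse pair at separation `r`, including the cutoff
#' switch, exactly as the toy backend computes it. Used as an independent
#' reference in scans over diatomics.
#'
#' @param r separation (Angstrom); vectorized
#' @param De,a,re Morse parameters
#' @param params optional [morse_params()] from which the switch is taken
#' @return energy in Hartree
#' @export
morse_energy <- function(r, De, a, re, params = NULL) {
  v <- De * ((1 - exp(-a * (r - re)))^2 - 1)
  if (!is.null(params)) {
    s <- vapply(r, function(ri) switch_fn(ri, params$switch_start,
                                          params$cutoff)[1], numeric(1))
    v <- v * s
    v[r >= params$cutoff] <- 0
  }
  v
}

#' Backend driving an external engine through files
#'
#' Runs an external command per evaluation: the geometry is written as XYZ
#' into a fresh numbered subdirectory of `workdir` (retained for audit), the
#' command template is expanded, and the engine's output file is parsed into
#' an [energy_gradient()]. Results are memoized on a coordinate hash rounded
#' to 1e-6 Angstrom, so identical geometries trigger a single invocation.
#'
#' Template placeholders: `{xyz}` input path, `{out}` output path, `{charge}`,
#' `{mult}`, `{natoms}`. The default parser expects a plain-text output file:
#' line 1 `energy <Hartree>`, then one `gx gy gz` line (Hartree/Angstrom) per
#' atom.
#'
#' @param command_template shell command with placeholders
#' @param workdir directory for engine exchange files (created if missing)
#' @param parser function(out_path, n_atoms) -> [energy_gradient()]
#' @param label backend label
#' @return backend object usable with [backend_evaluate()]
#' @export
external_engine_backend <- function(command_template, workdir,
                                    parser = parse_engine_output,
                                    label = "external") {
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  structure(list(command_template = command_template, workdir = workdir,
                 parser = parser, label = label,
                 cache = new.env(parent = emptyenv()),
                 counter = new.env(parent = emptyenv())),
            class = c("external_backend", "backend"))
}

geometry_cache_key <- function(geom) {
  paste(c(geom$elements, geom$charge, geom$multiplicity,
          sprintf("%.6f", round(geom$coords, 6))), collapse = "|")
}

#' Default parser for external engine output
#' @param out_path path to the engine output file
#' @param n_atoms expected atom count
#' @return an [energy_gradient()]
#' @export
parse_engine_output <- function(out_path, n_atoms) {
  lines <- readLines(out_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1 + n_atoms) {
    stop("engine output too short: expected energy line + ", n_atoms,
         " gradient lines, got ", length(lines))
  }
  etok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  energy <- suppressWarnings(as.numeric(etok[length(etok)]))
  if (is.na(energy)) stop("could not parse energy from '", lines[1], "'")
  grad <- matrix(NA_real_, n_atoms, 3)
  for (k in seq_len(n_atoms)) {
    tok <- suppressWarnings(as.numeric(strsplit(trimws(lines[1 + k]), "\\s+")[[1]]))
    if (length(tok) < 3 || anyNA(tok[1:3])) {
      stop("could not parse gradient line ", k, ": '", lines[1 + k], "'")
    }
    grad[k, ] <- tok[1:3]
  }
  energy_gradient(energy, grad, converged = TRUE)
}

#' @export
backend_evaluate.external_backend <- function(backend, geom) {
  key <- geometry_cache_key(geom)
  if (!is.null(backend$cache[[key]])) return(backend$cache[[key]])
  idx <- (backend$counter$n <- if (is.null(backend$counter$n)) 1L
          else backend$counter$n + 1L)
  jobdir <- file.path(backend$workdir, sprintf("eval_%05d", idx))
  dir.create(jobdir, showWarnings = FALSE, recursive = TRUE)
  xyz <- file.path(jobdir, "input.xyz")
  out <- file.path(jobdir, "engine.out")
  write_xyz(geom, xyz)
  cmd <- backend$command_template
  subs <- c("{xyz}" = xyz, "{out}" = out,
            "{charge}" = as.character(geom$charge),
            "{mult}" = as.character(geom$multiplicity),
            "{natoms}" = as.character(n_atoms(geom)))
  for (nm in names(subs)) cmd <- gsub(nm, subs[[nm]], cmd, fixed = TRUE)
  status <- system(paste(cmd, ">", shQuote(file.path(jobdir, "stdout.log")),
                         "2>", shQuote(file.path(jobdir, "stderr.log"))))
  if (status != 0) {
    err <- tryCatch(readLines(file.path(jobdir, "stderr.log")),
                    error = function(e) character(0))
    stop(structure(class = c("engine_failure", "error", "condition"),
                   list(message = paste0("external engine exited with status ",
                                         status, " in ", jobdir,
                                         if (length(err)) paste0(": ",
                                           paste(utils::tail(err, 5),
                                                 collapse = " | ")) else ""),
                        call = sys.call(), jobdir = jobdir, status = status,
                        stderr = err)))
  }
  eg <- tryCatch(backend$parser(out, n_atoms(geom)), error = function(e) {
    stop(structure(class = c("engine_failure", "error", "condition"),
                   list(message = paste0("failed to parse engine output in ",
                                         jobdir, ": ", conditionMessage(e)),
                        call = sys.call(), jobdir = jobdir, status = 0L,
                        stderr = character(0))))
  })
  backend$cache[[key]] <- eg
  eg
}

#' Probe a backend with a single evaluation
#'
#' Used by the driver before launching a run: a failure here aborts with the
#' engine diagnostics instead of deep inside a trajectory.
#' @param backend a backend
#' @param geom a `geometry`
#' @return TRUE invisibly, or an error
#' @export
backend_probe <- function(backend, geom) {
  eg <- backend_evaluate(backend, geom)
  if (!is.finite(eg$energy)) stop("backend probe returned non-finite energy")
  invisible(TRUE)
}
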