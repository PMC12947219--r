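## Energy backends.
##
## The MFCC combination consumes a backend contract: evaluate(atom system)
## -> total energy in kcal/mol, deterministic and permutation-invariant.
## The built-in classical backend sums dielectric-screened Coulomb plus
## Lennard-Jones terms; the quantum-chemistry route is write-only input-deck
## generation plus log-energy parsing (no engine is executed here).

#' Uniform dielectric model
#'
#' Uniform relative-permittivity screening of the Coulomb term, standing in
#' for a continuum-solvent treatment in classical mode.  Typical values for
#' protein interiors and interfaces are 10 and 40.
#'
#' @param epsilon Relative permittivity (>= 1).
#' @return A `dielectric_model`.
#' @export
dielectric_model <- function(epsilon = 40) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon < 1) {
    stop("epsilon must be a single number >= 1")
  }
  structure(list(epsilon = epsilon), class = "dielectric_model")
}

# normalise input (fragment_system or atom data.frame) to an atom table
.atom_table <- function(x) {
  if (inherits(x, "fragment_system")) return(x$atoms)
  if (is.data.frame(x)) {
    need <- c("x", "y", "z", "charge", "epsilon", "rmin_half")
    miss <- setdiff(need, names(x))
    if (length(miss) > 0) stop("atom set lacks column(s): ",
                               paste(miss, collapse = ", "))
    return(x)
  }
  stop("not an atom set: expected a fragment_system or data.frame")
}

.check_parameterized <- function(a) {
  if (anyNA(a$charge) || anyNA(a$epsilon) || anyNA(a$rmin_half)) {
    stop("unparameterized atom(s) in energy evaluation")
  }
}

# Coulomb + LJ energy over an explicit pair matrix (matrices of equal dim)
.pair_energy_matrix <- function(qq, eps_ij, rmin_ij, r, epsilon) {
  if (any(r < 0.1)) {
    stop("near-singular geometry: interatomic distance below 0.1 Angstrom")
  }
  s <- rmin_ij / r
  COULOMB_KCAL * qq / (epsilon * r) + eps_ij * (s^12 - 2 * s^6)
}

#' Pairwise interaction energy between two disjoint atom sets
#'
#' Sums `332.0637 qi qj / (eps rij) + eij ((rminij/rij)^12 - 2 (rminij/rij)^6)`
#' over all cross pairs, with Lorentz-Berthelot-style combination
#' (geometric-mean well depth, summed half-rmins).
#'
#' @param set_a,set_b Atom sets: `fragment_system`s or data.frames with
#'   columns `x`, `y`, `z`, `charge`, `epsilon`, `rmin_half`.
#' @param model A [dielectric_model()].
#' @return Energy in kcal/mol.
#' @export
pairwise_interaction_energy <- function(set_a, set_b,
                                        model = dielectric_model()) {
  stopifnot(inherits(model, "dielectric_model"))
  a <- .atom_table(set_a); b <- .atom_table(set_b)
  .check_parameterized(a); .check_parameterized(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  if (!is.null(a$id) && !is.null(b$id)) {
    shared <- intersect(a$id[!is.na(a$id)], b$id[!is.na(b$id)])
    if (length(shared) > 0) stop("atom sets are not disjoint")
  }
  dx <- outer(a$x, b$x, "-"); dy <- outer(a$y, b$y, "-")
  dz <- outer(a$z, b$z, "-")
  r <- sqrt(dx^2 + dy^2 + dz^2)
  e <- .pair_energy_matrix(outer(a$charge, b$charge),
                           sqrt(outer(a$epsilon, b$epsilon)),
                           outer(a$rmin_half, b$rmin_half, "+"),
                           r, model$epsilon)
  sum(e)
}

# exclusion mask (1-2 and 1-3 pairs) from a local bond list
.exclusion_matrix <- function(n, bonds) {
  adj <- matrix(FALSE, n, n)
  if (!is.null(bonds) && nrow(bonds) > 0) {
    adj[bonds] <- TRUE
    adj[bonds[, 2:1, drop = FALSE]] <- TRUE
  }
  one3 <- (adj %*% adj) > 0
  excl <- adj | one3
  diag(excl) <- TRUE
  excl
}

#' Total classical energy of one atom system
#'
#' Sums Coulomb and Lennard-Jones terms over all intra-set atom pairs,
#' excluding directly bonded (1-2) and angle (1-3) pairs derived from the
#' covalent topology.  A `fragment_system` carries its own bond list; for a
#' bare data.frame pass `bonds` explicitly (local row indices) or none for a
#' fully non-bonded set.
#'
#' @param x A `fragment_system` or atom data.frame.
#' @param model A [dielectric_model()].
#' @param bonds Optional two-column matrix of local row indices.
#' @param exclusions `"12_13"` (default) or `"none"`.
#' @return Energy in kcal/mol (0 for fewer than two atoms).
#' @export
total_energy <- function(x, model = dielectric_model(), bonds = NULL,
                         exclusions = c("12_13", "none")) {
  stopifnot(inherits(model, "dielectric_model"))
  exclusions <- match.arg(exclusions)
  a <- .atom_table(x)
  if (is.null(bonds) && inherits(x, "fragment_system")) bonds <- x$bonds
  .check_parameterized(a)
  n <- nrow(a)
  if (n < 2) return(0)
  dx <- outer(a$x, a$x, "-"); dy <- outer(a$y, a$y, "-")
  dz <- outer(a$z, a$z, "-")
  r <- sqrt(dx^2 + dy^2 + dz^2)
  excl <- .exclusion_matrix(n, if (exclusions == "none") NULL else bonds)
  r[excl] <- Inf                       # excluded pairs contribute nothing
  if (any(r[upper.tri(r)] < 0.1)) {
    stop("near-singular geometry: interatomic distance below 0.1 Angstrom")
  }
  s <- outer(a$rmin_half, a$rmin_half, "+") / r
  e <- COULOMB_KCAL * outer(a$charge, a$charge) / (model$epsilon * r) +
    sqrt(outer(a$epsilon, a$epsilon)) * (s^12 - 2 * s^6)
  sum(e[upper.tri(e)])
}

#' Classical pairwise energy backend
#'
#' Builds the energy-backend contract consumed by [mfcc_residue_energy()]
#' and [radius_sweep()]: `evaluate(system)` returns the total classical
#' energy of the system at the given uniform dielectric.
#'
#' @param epsilon Relative permittivity (default 40).
#' @param exclusions Passed to [total_energy()].
#' @return An `energy_backend` list with `evaluate`, `name`, `epsilon`,
#'   `level`.
#' @export
classical_backend <- function(epsilon = 40, exclusions = "12_13") {
  dm <- dielectric_model(epsilon)
  structure(list(
    name = "classical",
    epsilon = epsilon,
    level = sprintf("Coulomb/LJ, uniform dielectric (epsilon = %g)", epsilon),
    evaluate = function(system) total_energy(system, dm,
                                             exclusions = exclusions)),
    class = "energy_backend")
}

#' Level-of-theory description for quantum-chemistry decks
#'
#' @param functional Exchange-correlation functional (default `"B97D"`, a
#'   dispersion-corrected GGA).
#' @param basis Basis set (default `"6-311+G(d,p)"`).
#' @param solvent_model Continuum model keyword (default `"CPCM"`).
#' @return A `qm_level` list.
#' @export
qm_level <- function(functional = "B97D", basis = "6-311+G(d,p)",
                     solvent_model = "CPCM") {
  structure(list(functional = functional, basis = basis,
                 solvent_model = solvent_model), class = "qm_level")
}

# integer total charge of a system, from stored formal charges if the model
# was parameterized (link hydrogens are neutral H atoms, not charge carriers)
.system_formal_charge <- function(system, tol = 1e-6) {
  a <- .atom_table(system)
  real <- if (!is.null(a$id)) a[is.na(a$id) | a$id > 0, , drop = FALSE] else a
  if (anyNA(real$charge)) stop("cannot derive total charge: missing charges")
  q <- sum(real$charge)
  fq <- round(q)
  if (abs(q - fq) > tol) {
    stop("total formal charge (", format(q), ") is not an integer")
  }
  as.integer(fq)
}

#' Write a quantum-chemistry input deck
#'
#' Emits a Gaussian-dialect single-point input for one fragment system:
#' route line with functional, basis and continuum-solvent keywords, total
#' charge and multiplicity, and Cartesian coordinates in Angstrom.  Output
#' is byte-stable for fixed input.  No engine is executed by this package.
#'
#' @param system A `fragment_system` or atom data.frame.
#' @param level A [qm_level()].
#' @param model A [dielectric_model()] supplying the solvent permittivity.
#' @param charge Total charge; derived from the system's formal charges when
#'   `NULL` (non-integer charge sums are an error).
#' @param multiplicity Spin multiplicity (default 1).
#' @param title Deck title line.
#' @return The deck as a single character string.
#' @export
write_qm_deck <- function(system, level = qm_level(),
                          model = dielectric_model(), charge = NULL,
                          multiplicity = 1, title = "MFCC fragment") {
  stopifnot(inherits(level, "qm_level"), inherits(model, "dielectric_model"))
  a <- .atom_table(system)
  if (nrow(a) == 0) stop("empty atom system")
  if (is.null(charge)) charge <- .system_formal_charge(system)
  if (abs(charge - round(charge)) > 1e-9) {
    stop("total formal charge (", charge, ") is not an integer")
  }
  route <- sprintf("#P %s/%s SCRF=(%s,Read) NoSymm SP",
                   level$functional, level$basis, level$solvent_model)
  coords <- sprintf(" %-2s  %14.8f %14.8f %14.8f", a$elem, a$x, a$y, a$z)
  paste(c(route, "", title, "",
          sprintf("%d %d", as.integer(round(charge)),
                  as.integer(multiplicity)),
          coords, "",
          sprintf("eps=%.1f", model$epsilon), "", ""),
        collapse = "\n")
}

#' Write the four decks of a fragment quadruple
#'
#' @param quadruple A `fragment_quadruple`.
#' @param dir Output directory (created if needed).
#' @param level,model Passed to [write_qm_deck()].
#' @return Named character vector of the four file paths.
#' @export
write_quadruple_decks <- function(quadruple, dir, level = qm_level(),
                                  model = dielectric_model()) {
  stopifnot(inherits(quadruple, "fragment_quadruple"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  systems <- c("sys_l_crc", "sys_l_cc", "sys_crc", "sys_cc")
  key <- gsub("[^A-Za-z0-9]", "_", quadruple$residue_key)
  paths <- file.path(dir, sprintf("%s_%s.gjf", key, systems))
  for (i in seq_along(systems)) {
    deck <- write_qm_deck(quadruple[[systems[i]]], level = level,
                          model = model,
                          title = paste("MFCC", quadruple$residue_key,
                                        systems[i]))
    writeLines(deck, paths[i], sep = "")
  }
  stats::setNames(paths, systems)
}

#' Parse the converged SCF energy from a quantum-chemistry log
#'
#' Returns the last `SCF Done` energy found, converted from hartree to
#' kcal/mol (factor 627.5095).  A missing energy line or a non-convergence
#' marker is a parse error.
#'
#' @param text Log content: character vector of lines, a single string, or a
#'   path to an existing file.
#' @return Energy in kcal/mol.
#' @export
parse_qm_energy <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  text <- unlist(strsplit(text, "\n", fixed = TRUE))
  if (any(grepl("Convergence failure|Error termination", text))) {
    stop("calculation did not converge")
  }
  hits <- regmatches(text,
                     regexpr("SCF Done:[^=]*=?\\s*(-?[0-9]+\\.[0-9]+([DdEe][+-]?[0-9]+)?)",
                             text))
  if (length(hits) == 0) stop("no SCF energy line found")
  num <- sub(".*?(-?[0-9]+\\.[0-9]+([DdEe][+-]?[0-9]+)?).*", "\\1",
             hits[length(hits)])
  hartree <- as.numeric(gsub("[Dd]", "E", num))
  hartree * HARTREE_KCAL
}

#' Read or write a fragment energy cache
#'
#' CSV cache keyed by (complex, residue, system, epsilon) so an external
#' quantum-chemistry campaign can be resumed and merged.
#'
#' @param path CSV path.
#' @param cache Data.frame with columns `complex`, `residue`, `system`,
#'   `epsilon`, `energy_kcal`.
#' @return `read_energy_cache`: the cache data.frame.  `write_energy_cache`:
#'   `path`, invisibly.  Duplicate keys keep the last entry.
#' @export
read_energy_cache <- function(path) {
  cache <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("complex", "residue", "system", "epsilon", "energy_kcal")
  miss <- setdiff(need, names(cache))
  if (length(miss) > 0) stop("energy cache lacks column(s): ",
                             paste(miss, collapse = ", "))
  key <- do.call(paste, cache[c("complex", "residue", "system", "epsilon")])
  cache[!duplicated(key, fromLast = TRUE), need]
}

#' @rdname read_energy_cache
#' @export
write_energy_cache <- function(cache, path) {
  if (file.exists(path)) {
    cache <- rbind(read_energy_cache(path), cache)
    key <- do.call(paste, cache[c("complex", "residue", "system", "epsilon")])
    cache <- cache[!duplicated(key, fromLast = TRUE), ]
  }
  utils::write.csv(cache, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
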