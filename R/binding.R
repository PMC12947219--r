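## Per-residue MFCC energies, radius sweep, convergence, ranking and
## ligand-region aggregation.

#' Four-term MFCC interaction energy of one residue
#'
#' Evaluates the backend on the four capped systems and combines them as
#' `E(L-CRC) - E(L-CC) - E(CRC) + E(CC)`: the internal energies of the
#' capped fragments cancel, leaving the ligand-residue interaction energy.
#'
#' @param quadruple A `fragment_quadruple` from [cleave_and_cap()].
#' @param backend An energy backend (e.g. [classical_backend()]).
#' @return Energy in kcal/mol, with the four term energies attached as the
#'   `"terms"` attribute.
#' @export
mfcc_residue_energy <- function(quadruple, backend) {
  stopifnot(inherits(quadruple, "fragment_quadruple"),
            inherits(backend, "energy_backend"))
  systems <- c("sys_l_crc", "sys_l_cc", "sys_crc", "sys_cc")
  e <- vapply(systems, function(s) {
    tryCatch(backend$evaluate(quadruple[[s]]),
             error = function(err) stop("backend failed on system ", s, ": ",
                                        conditionMessage(err), call. = FALSE))
  }, numeric(1))
  out <- e[["sys_l_crc"]] - e[["sys_l_cc"]] - e[["sys_crc"]] + e[["sys_cc"]]
  attr(out, "terms") <- e
  out
}

#' Minimum residue-ligand contact distance
#'
#' Global minimum over all residue-atom/ligand-atom pairs, hydrogens
#' included.  Ties are broken deterministically by lowest atom id (residue
#' atom first, then ligand atom).
#'
#' @param model A `structure_model`.
#' @param residue_key Residue key or printed label.
#' @return List with `distance` (Angstrom), `residue_atom`, `ligand_atom`
#'   (names) and `residue_atom_id`, `ligand_atom_id`.
#' @export
residue_min_distance <- function(model, residue_key) {
  stopifnot(inherits(model, "structure_model"))
  key <- .resolve_residue_key(model, residue_key)
  ra <- residue_atoms(model, key)
  la <- ligand_atoms(model)
  if (nrow(ra) == 0 || nrow(la) == 0) stop("empty atom set")
  ra <- ra[order(ra$id), , drop = FALSE]
  la <- la[order(la$id), , drop = FALSE]
  d <- sqrt(outer(ra$x, la$x, "-")^2 + outer(ra$y, la$y, "-")^2 +
              outer(ra$z, la$z, "-")^2)
  dmin <- min(d)
  hit <- which(d == dmin, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
  list(distance = dmin,
       residue_atom = ra$name[hit[1]], ligand_atom = la$name[hit[2]],
       residue_atom_id = ra$id[hit[1]], ligand_atom_id = la$id[hit[2]])
}

#' Radius schedule for the pocket sweep
#'
#' Radii increase by `step` from `step` up to `r_max` (the half-integer
#' schedule r = R/2, R = 1, 2, 3, ... for the default 0.5 A step).
#'
#' @param r_max Largest radius (Angstrom), `r_max >= step`.
#' @param step Increment (Angstrom, default 0.5).
#' @return Numeric vector of radii.
#' @export
radius_schedule <- function(r_max, step = 0.5) {
  if (!is.numeric(r_max) || !is.numeric(step) || step <= 0 || r_max < step) {
    stop("need r_max >= step > 0")
  }
  step * seq_len(floor(r_max / step + 1e-9))
}

#' Convergence radius of a cumulative energy series
#'
#' The convergence radius is the smallest radius from which the change in
#' cumulative total energy between consecutive radii stays below
#' `threshold` (fractional, relative to the current total) through the end
#' of the schedule.  A step with zero total is non-convergent unless its
#' difference is also zero.
#'
#' @param energy A `radius_sweep` result, or a numeric vector of cumulative
#'   energies (kcal/mol).
#' @param radii Radii matching `energy` when a bare vector is given.
#' @param threshold Fractional criterion (default 0.10).
#' @return The convergence radius (Angstrom), or `NA` if never attained.
#' @export
detect_convergence <- function(energy, radii = NULL, threshold = 0.10) {
  if (inherits(energy, "radius_sweep")) {
    radii <- energy$radii
    energy <- energy$cumulative_energy
  }
  if (is.null(radii)) radii <- seq_along(energy)
  n <- length(energy)
  if (n < 2 || length(radii) != n) {
    stop("need at least two radii with matching energies")
  }
  d <- abs(diff(energy))
  e <- abs(energy[-1])
  ok <- ifelse(e == 0, d == 0, d < threshold * e)
  persist <- rev(cumprod(rev(ok)) > 0)   # criterion holds from here onward
  k <- which(persist)[1]
  if (is.na(k)) NA_real_ else radii[k + 1L]
}

#' Sweep the binding-pocket radius
#'
#' Computes each residue's MFCC energy once, then accumulates total binding
#' energy over concentric distance shells: a residue is included at radius r
#' iff its minimum atom-atom distance to the ligand is <= r.  Residues
#' beyond `r_max` are not evaluated.
#'
#' @param model A parameterized `structure_model`.
#' @param backend Energy backend (default [classical_backend()] at the
#'   model's default dielectric).
#' @param scheme A [cap_scheme()].
#' @param r_max,step Radius schedule (Angstrom), see [radius_schedule()].
#' @param region_map Optional [region_map()] used to assign each residue to
#'   a ligand region via its closest ligand atom.
#' @param threshold Convergence criterion passed to [detect_convergence()].
#' @return A `radius_sweep` list: `radii`, `included_residues` (nested
#'   per-radius key sets), `n_residues`, `cumulative_energy`,
#'   `convergence_radius`, `records` (per-residue data.frame), `epsilon`.
#' @export
radius_sweep <- function(model, backend = classical_backend(model$dielectric_default),
                         scheme = cap_scheme(), r_max = 10, step = 0.5,
                         region_map = NULL, threshold = 0.10) {
  stopifnot(inherits(model, "structure_model"))
  if (!model$parameterized && identical(backend$name, "classical")) {
    stop("model must be parameterized for the classical backend")
  }
  radii <- radius_schedule(r_max, step)

  keys <- model$residues$key
  md <- lapply(keys, residue_min_distance, model = model)
  dist <- vapply(md, `[[`, numeric(1), "distance")
  keep <- which(dist <= r_max)

  records <- data.frame(
    residue_key = keys[keep],
    label = model$residues$label[keep],
    chain = model$residues$chain[keep],
    resno = model$residues$resno[keep],
    resid = model$residues$resid[keep],
    energy = NA_real_,
    min_distance = dist[keep],
    closest_residue_atom = vapply(md[keep], `[[`, character(1), "residue_atom"),
    closest_ligand_atom = vapply(md[keep], `[[`, character(1), "ligand_atom"),
    closest_ligand_atom_id = vapply(md[keep], `[[`, numeric(1), "ligand_atom_id"),
    region = NA_character_,
    epsilon = if (is.null(backend$epsilon)) NA_real_ else backend$epsilon,
    stringsAsFactors = FALSE)

  for (i in seq_along(keep)) {
    k <- records$residue_key[i]
    q <- cleave_and_cap(model, k, scheme)
    records$energy[i] <- tryCatch(
      as.numeric(mfcc_residue_energy(q, backend)),
      error = function(e) stop("energy evaluation failed for residue ",
                               records$label[i], ": ", conditionMessage(e),
                               call. = FALSE))
    if (!is.null(region_map)) {
      records$region[i] <- assign_region(model,
                                         records$closest_ligand_atom_id[i],
                                         region_map)
    }
  }

  included <- lapply(radii, function(r) records$residue_key[records$min_distance <= r])
  cumulative <- vapply(included, function(k) {
    sum(records$energy[records$residue_key %in% k])
  }, numeric(1))

  out <- list(radii = radii,
              included_residues = included,
              n_residues = lengths(included),
              cumulative_energy = cumulative,
              records = records,
              epsilon = records$epsilon[1],
              r_max = r_max, step = step,
              convergence_radius = NA_real_)
  out$convergence_radius <- detect_convergence(cumulative, radii, threshold)
  class(out) <- "radius_sweep"
  out
}

#' @export
print.radius_sweep <- function(x, ...) {
  cat("radius_sweep:", length(x$radii), "radii up to", max(x$radii), "A;",
      nrow(x$records), "residues\n")
  cat("  total energy at r_max:",
      sprintf("%.2f kcal/mol", x$cumulative_energy[length(x$radii)]), "\n")
  cat("  convergence radius:",
      if (is.na(x$convergence_radius)) "not attained" else
        paste0(x$convergence_radius, " A"), "\n")
  invisible(x)
}

#' Rank residues by interaction energy
#'
#' Stable sort by energy ascending (strongest attraction first, repulsive
#' contributions last), ties broken by residue number.
#'
#' @param records A per-residue data.frame with an `energy` column and
#'   either `resno` or a `residue`/`label` column ending in the residue
#'   number, or a `radius_sweep` result.
#' @return The sorted data.frame with a `rank` column prepended.
#' @export
rank_residues <- function(records) {
  if (inherits(records, "radius_sweep")) records <- records$records
  stopifnot(is.data.frame(records), nrow(records) > 0,
            "energy" %in% names(records))
  resno <- records$resno
  if (is.null(resno)) {
    lab <- records$label
    if (is.null(lab)) lab <- records$residue
    if (is.null(lab)) stop("no resno, label or residue column to break ties")
    resno <- as.integer(sub("^[A-Za-z]+", "", lab))
  }
  out <- records[order(records$energy, resno), , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Ligand-region map
#'
#' A partition of the ligand's heavy atoms into chemically defined regions
#' (e.g. catechol ring, amine arm) used to attribute residue contacts to
#' ligand moieties.
#'
#' @param regions Named list: region label -> character vector of ligand
#'   heavy-atom names; or a named character vector atom -> region.
#' @return A `region_map`: named character vector atom name -> region label.
#' @export
region_map <- function(regions) {
  if (is.list(regions)) {
    map <- stats::setNames(rep(names(regions), lengths(regions)),
                           unlist(regions))
  } else if (is.character(regions) && !is.null(names(regions))) {
    map <- regions
  } else {
    stop("regions must be a named list or named character vector")
  }
  if (anyDuplicated(names(map))) {
    stop("region map is not a partition: duplicated atom(s)")
  }
  structure(map, class = "region_map")
}

#' Check a region map against a model's ligand
#'
#' Verifies the partition property: every ligand heavy atom assigned to
#' exactly one region.
#'
#' @param map A [region_map()].
#' @param model A `structure_model`.
#' @return `TRUE`, invisibly; errors otherwise.
#' @export
validate_region_map <- function(map, model) {
  la <- ligand_atoms(model)
  heavy <- la$name[la$elem != "H"]
  miss <- setdiff(heavy, names(map))
  if (length(miss) > 0) {
    stop("ligand heavy atom(s) not covered by region map: ",
         paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read/write a region map as JSON
#'
#' JSON object region label -> array of ligand atom names.
#'
#' @param path JSON file path.
#' @param map A [region_map()].
#' @return `read_region_map`: a `region_map`.  `write_region_map`: `path`,
#'   invisibly.
#' @export
read_region_map <- function(path) {
  region_map(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_region_map
#' @export
write_region_map <- function(map, path) {
  regions <- split(names(map), factor(unname(unclass(map)),
                                      levels = unique(unname(unclass(map)))))
  jsonlite::write_json(regions, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Assign a residue contact to a ligand region
#'
#' The region is that of the ligand heavy atom closest to the residue; a
#' closest hydrogen delegates to the heavy atom it is bonded to.
#'
#' @param model A `structure_model` (supplies the ligand topology for
#'   hydrogen delegation).
#' @param closest_ligand_atom Ligand atom id or atom name.
#' @param map A [region_map()].
#' @return The region label.
#' @export
assign_region <- function(model, closest_ligand_atom, map) {
  stopifnot(inherits(model, "structure_model"))
  la <- ligand_atoms(model)
  if (is.numeric(closest_ligand_atom)) {
    i <- match(closest_ligand_atom, la$id)
  } else {
    i <- match(closest_ligand_atom, la$name)
  }
  if (is.na(i)) stop("not a ligand atom: ", closest_ligand_atom)
  if (la$elem[i] == "H") {
    nb <- c(model$bonds[model$bonds[, 1] == la$id[i], 2],
            model$bonds[model$bonds[, 2] == la$id[i], 1])
    nb <- nb[nb %in% la$id]
    if (length(nb) == 0) stop("ligand hydrogen ", la$name[i],
                              " has no bonded heavy atom")
    i <- match(nb[1], la$id)
  }
  lab <- unname(unclass(map)[la$name[i]])
  if (is.na(lab)) stop("ligand atom ", la$name[i], " not covered by region map")
  lab
}

#' Aggregate per-residue energies by ligand region
#'
#' Group sums of residue interaction energies over their assigned ligand
#' regions.  The sum over regions equals the sum over records exactly;
#' regions of the map with no residues report zero.
#'
#' @param records Data.frame with columns `energy` and `region` (e.g. the
#'   `records` of a [radius_sweep()] run with a region map, or a published
#'   ranking table), or a `radius_sweep` result.
#' @param map Optional [region_map()]; its region labels fix the output
#'   order and contribute zero rows for empty regions.
#' @return Data.frame with columns `region`, `n_residues`, `energy`.
#' @export
aggregate_regional_energies <- function(records, map = NULL) {
  if (inherits(records, "radius_sweep")) records <- records$records
  stopifnot(is.data.frame(records),
            all(c("energy", "region") %in% names(records)))
  if (anyNA(records$region)) {
    stop("every record must carry a region assignment")
  }
  levels <- unique(records$region)
  if (!is.null(map)) {
    levels <- unique(c(unique(unname(unclass(map))), levels))
  }
  f <- factor(records$region, levels = levels)
  data.frame(
    region = levels,
    n_residues = as.integer(table(f)),
    energy = as.numeric(tapply(records$energy, f, sum, default = 0)),
    stringsAsFactors = FALSE)
}
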