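## Structure reading, validation, parameter assignment.
##
## The in-memory container is a `structure_model`: a list holding
##   atoms     - data.frame(id, name, elem, resid, chain, resno, x, y, z,
##               charge, epsilon, rmin_half, is_ligand)
##   residues  - data.frame(key, chain, resno, resid, label,
##               n_neighbor, c_neighbor, formal_charge)
##   ligand    - list(code, atom_ids, formal_charge)
##   bonds     - two-column integer matrix of atom ids (covalent topology)
##   dielectric_default, parameterized, source
## Coordinates are Angstrom throughout; residue numbering is preserved
## verbatim from the input so residues can be reported as printed (ASP106).

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

# single-bond covalent radii (Angstrom) for bond perception
.COV_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
                F = 0.57, CL = 1.02, BR = 1.20, I = 1.39)

.KNOWN_ELEMENTS <- c(names(.COV_RADII), "NA", "K", "MG", "CA", "ZN", "FE",
                     "MN", "CU", "SE", "B")

# element from a PDB-style atom name ("HB1" -> H, "OD1" -> O, "SG" -> S)
.elem_from_name <- function(name) {
  toupper(substr(gsub("^[0-9]+", "", name), 1, 1))
}

.cov_radius <- function(elem) {
  r <- .COV_RADII[toupper(elem)]
  r[is.na(r)] <- 0.77
  unname(r)
}

.residue_key <- function(chain, resno) paste0(chain, ":", resno)

# covalent bond perception for one atom block (a residue or the ligand):
# heavy-heavy pairs within 1.3x the radius sum; each hydrogen bonds to its
# nearest heavy atom only
.intra_bonds <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  heavy <- atoms$elem != "H"
  out <- list()
  hv <- which(heavy)
  if (length(hv) >= 2) {
    for (a in seq_along(hv)) {
      for (b in seq_len(a - 1L)) {
        i <- hv[a]; j <- hv[b]
        cut <- 1.3 * (.cov_radius(atoms$elem[i]) + .cov_radius(atoms$elem[j]))
        if (d[i, j] <= cut) out[[length(out) + 1L]] <- c(atoms$id[j], atoms$id[i])
      }
    }
  }
  for (i in which(!heavy)) {
    if (length(hv) == 0) next
    j <- hv[which.min(d[i, hv])]
    out[[length(out) + 1L]] <- c(atoms$id[i], atoms$id[j])
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

# full covalent topology: intra-residue + peptide + disulfide + intra-ligand;
# never between ligand and receptor
.build_bonds <- function(atoms, residues, ligand_ids) {
  parts <- list()
  rec <- atoms[!atoms$is_ligand, , drop = FALSE]
  for (k in unique(rec$residue_key)) {
    parts[[length(parts) + 1L]] <- .intra_bonds(rec[rec$residue_key == k, , drop = FALSE])
  }
  if (length(ligand_ids) > 0) {
    parts[[length(parts) + 1L]] <-
      .intra_bonds(atoms[atoms$id %in% ligand_ids, , drop = FALSE])
  }
  # peptide bonds between consecutive residues of a chain: C(i)-N(i+1)
  if (nrow(residues) > 1) {
    for (i in seq_len(nrow(residues) - 1L)) {
      r1 <- residues[i, ]; r2 <- residues[i + 1L, ]
      if (r1$chain != r2$chain) next
      c1 <- rec[rec$residue_key == r1$key & rec$name == "C", , drop = FALSE]
      n2 <- rec[rec$residue_key == r2$key & rec$name == "N", , drop = FALSE]
      if (nrow(c1) == 1 && nrow(n2) == 1) {
        dd <- sqrt(sum((unlist(c1[, c("x", "y", "z")]) -
                        unlist(n2[, c("x", "y", "z")]))^2))
        if (dd > 1.1 && dd < 1.8) {
          parts[[length(parts) + 1L]] <- cbind(c1$id, n2$id)
        }
      }
    }
  }
  # disulfide bridges: SG-SG pairs across residues closer than 2.3 A
  sg <- rec[rec$name == "SG", , drop = FALSE]
  if (nrow(sg) > 1) {
    for (a in seq_len(nrow(sg) - 1L)) {
      for (b in seq(a + 1L, nrow(sg))) {
        dd <- sqrt(sum((unlist(sg[a, c("x", "y", "z")]) -
                        unlist(sg[b, c("x", "y", "z")]))^2))
        if (dd < 2.3) parts[[length(parts) + 1L]] <- cbind(sg$id[a], sg$id[b])
      }
    }
  }
  bonds <- do.call(rbind, parts[lengths(parts) > 0])
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  storage.mode(bonds) <- "integer"
  unname(bonds)
}

# assemble a structure_model from a normalised atom data.frame
.make_model <- function(atoms, ligand_code, dielectric_default = 40,
                        source = NA_character_) {
  stopifnot(!anyDuplicated(atoms$id))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in structure")
  }
  bad <- setdiff(unique(atoms$elem), .KNOWN_ELEMENTS)
  if (length(bad) > 0) stop("unknown element(s): ", paste(bad, collapse = ", "))

  rec <- atoms[!atoms$is_ligand, , drop = FALSE]
  atoms$residue_key <- ifelse(atoms$is_ligand, "LIG",
                              .residue_key(atoms$chain, atoms$resno))
  rec <- atoms[!atoms$is_ligand, , drop = FALSE]
  keys <- unique(rec$residue_key)
  first <- match(keys, rec$residue_key)
  residues <- data.frame(
    key = keys,
    chain = rec$chain[first],
    resno = rec$resno[first],
    resid = rec$resid[first],
    stringsAsFactors = FALSE)
  residues$label <- paste0(residues$resid, residues$resno)
  residues$n_neighbor <- NA_character_
  residues$c_neighbor <- NA_character_
  residues$formal_charge <- NA_integer_

  lig_ids <- atoms$id[atoms$is_ligand]
  bonds <- .build_bonds(atoms, residues, lig_ids)

  # neighbour links follow actual peptide bonds (symmetric by construction)
  if (nrow(bonds) > 0 && nrow(residues) > 1) {
    nm <- atoms$name[match(bonds[, 1], atoms$id)]
    nm2 <- atoms$name[match(bonds[, 2], atoms$id)]
    pep <- which(nm == "C" & nm2 == "N")
    for (p in pep) {
      k1 <- atoms$residue_key[match(bonds[p, 1], atoms$id)]
      k2 <- atoms$residue_key[match(bonds[p, 2], atoms$id)]
      residues$c_neighbor[residues$key == k1] <- k2
      residues$n_neighbor[residues$key == k2] <- k1
    }
  }

  model <- list(
    atoms = atoms,
    residues = residues,
    ligand = list(code = ligand_code, atom_ids = lig_ids,
                  formal_charge = NA_integer_),
    bonds = bonds,
    dielectric_default = dielectric_default,
    parameterized = all(is.finite(atoms$charge)) && nrow(atoms) > 0,
    source = source)
  class(model) <- "structure_model"
  model
}

#' Read a receptor-ligand structure
#'
#' Reads a PDB or mmCIF file (through bio3d), splits the receptor from the
#' ligand, and builds the covalent topology.  Chain and residue ordering are
#' preserved verbatim.  Waters, ions and het groups other than the selected
#' ligand are dropped with a message.  For atoms with alternate locations the
#' highest-occupancy conformer is kept and the discarded ones are reported.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param format_hint One of `"auto"` (by extension), `"pdb"`, `"mmcif"`.
#' @param ligand Het code of the ligand (e.g. `"AMX"`).  If `NULL` and the
#'   file contains exactly one non-water het group, that group is used.
#' @param model_index For multi-model PDB files, which MODEL to read; with
#'   more than one model and no index this is an error.
#' @param dielectric Default relative permittivity stored on the model.
#' @return A `structure_model`.
#' @export
read_structure <- function(path, format_hint = c("auto", "pdb", "mmcif"),
                           ligand = NULL, model_index = NULL,
                           dielectric = 40) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- format_hint
  if (fmt == "auto") {
    fmt <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (fmt == "mmcif") bio3d::read.cif(path) else {
      n_models <- sum(grepl("^MODEL", readLines(path, warn = FALSE)))
      if (n_models > 1 && is.null(model_index)) {
        stop("file contains ", n_models, " models; give model_index")
      }
      if (n_models > 1) {
        multi <- bio3d::read.pdb(path, multi = TRUE)
        if (model_index > nrow(multi$xyz)) stop("model_index out of range")
        multi$atom[, c("x", "y", "z")] <-
          matrix(multi$xyz[model_index, ], ncol = 3, byrow = TRUE)
        multi
      } else {
        bio3d::read.pdb(path)
      }
    },
    error = function(e) stop("cannot parse ", path, " as ", fmt, ": ",
                             conditionMessage(e)))
  at <- pdb$atom

  # alternate locations: keep the highest-occupancy conformer
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    site <- paste(at$chain, at$resno, at$resid, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- rep(TRUE, nrow(at))
    for (s in unique(site[alt != ""])) {
      idx <- which(site == s)
      if (length(idx) > 1) {
        best <- idx[which.max(occ[idx])]
        keep[setdiff(idx, best)] <- FALSE
      }
    }
    if (any(!keep)) {
      message("dropped ", sum(!keep), " alternate-location atom(s)")
      at <- at[keep, , drop = FALSE]
    }
  }

  het <- at$type == "HETATM"
  het_codes <- setdiff(unique(at$resid[het]), c("HOH", "WAT", "DOD"))
  if (is.null(ligand)) {
    if (length(het_codes) == 1) {
      ligand <- het_codes
    } else {
      stop("ligand selector required; het codes present: ",
           paste(het_codes, collapse = ", "))
    }
  }
  is_lig <- at$resid == ligand
  if (!any(is_lig)) stop("ligand selector '", ligand, "' matches no atoms")
  drop <- het & !is_lig
  if (any(drop)) {
    message("dropped ", sum(drop), " het atom(s): ",
            paste(unique(at$resid[drop]), collapse = ", "))
    at <- at[!drop, , drop = FALSE]
    is_lig <- at$resid == ligand
  }

  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  elem <- toupper(trimws(elem))
  miss <- is.na(elem) | elem == ""
  elem[miss] <- .elem_from_name(at$elety[miss])

  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"

  atoms <- data.frame(
    id = seq_len(nrow(at)),
    name = trimws(at$elety),
    elem = elem,
    resid = trimws(at$resid),
    chain = chain,
    resno = at$resno,
    x = at$x, y = at$y, z = at$z,
    charge = NA_real_, epsilon = NA_real_, rmin_half = NA_real_,
    is_ligand = is_lig,
    stringsAsFactors = FALSE)
  .make_model(atoms, ligand_code = ligand, dielectric_default = dielectric,
              source = path)
}

#' Validate the protonation of a model
#'
#' Compares each residue's atom names against its template in a parameter
#' table and reports missing hydrogens or heavy atoms.  Residues without a
#' template yield a warning entry, not a failure: structures must arrive
#' pre-protonated, and this check only flags implausible hydrogen counts.
#'
#' @param model A `structure_model`.
#' @param table Parameter table defining the templates
#'   (default [default_parameter_table()]).
#' @return A list with `pass` (logical) and `issues`, a data.frame with
#'   columns `residue`, `atom`, `type` (`missing_hydrogen`,
#'   `missing_heavy_atom` or `unknown_residue`).
#' @export
validate_protonation <- function(model, table = default_parameter_table()) {
  stopifnot(inherits(model, "structure_model"))
  issues <- list()
  add <- function(res, atom, type) {
    issues[[length(issues) + 1L]] <<-
      data.frame(residue = res, atom = atom, type = type,
                 stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(model$residues))) {
    res <- model$residues[i, ]
    tmpl <- .template_atoms(table, res$resid)
    if (is.null(tmpl)) {
      add(res$label, NA_character_, "unknown_residue")
      next
    }
    have <- model$atoms$name[model$atoms$residue_key == res$key]
    for (a in setdiff(tmpl, have)) {
      add(res$label, a,
          if (.elem_from_name(a) == "H") "missing_hydrogen" else "missing_heavy_atom")
    }
  }
  issues <- if (length(issues) > 0) do.call(rbind, issues) else
    data.frame(residue = character(0), atom = character(0),
               type = character(0), stringsAsFactors = FALSE)
  structure(list(pass = !any(issues$type %in%
                               c("missing_hydrogen", "missing_heavy_atom")),
                 issues = issues),
            class = "protonation_report")
}

#' @export
print.protonation_report <- function(x, ...) {
  cat("protonation check:", if (x$pass) "PASS" else "FAIL", "\n")
  if (nrow(x$issues) > 0) print(x$issues)
  invisible(x)
}

#' Attach partial charges and Lennard-Jones parameters
#'
#' Joins a parameter table onto every atom of the model.  Every
#' (residue name, atom name) pair and every ligand atom must be covered;
#' a missing entry is an error naming the offending atom.  Per-residue charge
#' sums are checked against the template formal charge to 1e-6 e, and the
#' resulting integer formal charges are stored per residue and for the
#' ligand.
#'
#' @param model A `structure_model`.
#' @param table Parameter table (see [read_parameter_table()]).
#' @return The parameterized `structure_model`.
#' @export
assign_parameters <- function(model, table = default_parameter_table()) {
  stopifnot(inherits(model, "structure_model"))
  key_tab <- paste(table$residue, table$atom)
  key_atm <- paste(model$atoms$resid, model$atoms$name)
  hit <- match(key_atm, key_tab)
  if (anyNA(hit)) {
    bad <- which(is.na(hit))[1]
    a <- model$atoms[bad, ]
    where <- if (a$is_ligand) paste0("ligand ", a$resid) else
      paste0(a$resid, a$resno)
    stop("no parameters for atom '", a$name, "' of ", where)
  }
  model$atoms$charge <- table$charge[hit]
  model$atoms$epsilon <- table$epsilon[hit]
  model$atoms$rmin_half <- table$rmin_half[hit]

  for (i in seq_len(nrow(model$residues))) {
    k <- model$residues$key[i]
    q <- sum(model$atoms$charge[model$atoms$residue_key == k])
    fq <- .template_formal_charge(table, model$residues$resid[i])
    if (abs(q - fq) > 1e-6) {
      stop("charge sum of ", model$residues$label[i], " (", q,
           ") deviates from template formal charge ", fq)
    }
    model$residues$formal_charge[i] <- fq
  }
  lig_q <- sum(model$atoms$charge[model$atoms$is_ligand])
  model$ligand$formal_charge <- as.integer(round(lig_q))
  if (abs(lig_q - round(lig_q)) > 1e-6) {
    stop("ligand charge sum (", lig_q, ") is not integral")
  }
  model$parameterized <- TRUE
  model
}

#' Total formal charge of a parameterized model
#' @param model A parameterized `structure_model`.
#' @return Integer: sum of residue formal charges plus the ligand's.
#' @export
model_formal_charge <- function(model) {
  stopifnot(inherits(model, "structure_model"), model$parameterized)
  sum(model$residues$formal_charge) + model$ligand$formal_charge
}

# atom rows for one residue key (or "LIG")
residue_atoms <- function(model, key) {
  model$atoms[model$atoms$residue_key == key, , drop = FALSE]
}

# atom rows of the ligand
ligand_atoms <- function(model) {
  model$atoms[model$atoms$is_ligand, , drop = FALSE]
}

#' Write a model back to PDB
#'
#' Normalized PDB writer (through bio3d) used for round-trips and fragment
#' debugging.  Ligand atoms are emitted as HETATM records.
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$is_ligand, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, eleno = a$id,
                   elety = a$name, chain = a$chain,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)), elesy = a$elem)
  invisible(path)
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model: ", nrow(x$residues), " residues, ",
      length(x$ligand$atom_ids), " ligand atoms (", x$ligand$code, "), ",
      nrow(x$atoms), " atoms total\n", sep = "")
  cat("  parameterized:", x$parameterized,
      " dielectric default:", x$dielectric_default, "\n")
  invisible(x)
}
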