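## Peptide-bond cleavage, conjugate caps and link hydrogens.
##
## For residue Ri the four MFCC systems are
##   sys_l_crc : ligand + C(i-1) Ri C(i+1)
##   sys_l_cc  : ligand + C(i-1) C(i+1)
##   sys_crc   :          C(i-1) Ri C(i+1)
##   sys_cc    :          C(i-1) C(i+1)
## Each cut covalent bond is terminated by exactly one link hydrogen placed
## on the kept atom along the direction of the removed neighbour.  Cap atoms
## are the same data.frame rows across paired systems, so coordinate identity
## holds bit-exactly.

#' Capping scheme for MFCC fragmentation
#'
#' @param cap_extent `"whole_adjacent_residue"` (default: each conjugate cap
#'   is the full neighbouring residue, cut at its distal peptide bond) or
#'   `"backbone_only"` (caps keep only backbone atoms; cheaper).
#' @param nh_bond_length,ch_bond_length,sh_bond_length Link-hydrogen bond
#'   lengths (Angstrom) when the kept atom is N, C or S.
#' @param cut_disulfides Cut S-S bridges and cap SG with hydrogen, so CYS
#'   residues remain independent fragments.
#' @param link_charge Partial charge given to link hydrogens in classical
#'   mode (the generic aliphatic-H charge of the default table).  The MFCC
#'   cancellation makes the result insensitive to this value except through
#'   ligand-link-hydrogen terms.
#' @param link_epsilon,link_rmin_half LJ parameters for link hydrogens.
#' @return A `cap_scheme` list.
#' @export
cap_scheme <- function(cap_extent = c("whole_adjacent_residue", "backbone_only"),
                       nh_bond_length = 1.01, ch_bond_length = 1.09,
                       sh_bond_length = 1.34, cut_disulfides = TRUE,
                       link_charge = 0.09, link_epsilon = 0.022,
                       link_rmin_half = 1.32) {
  cap_extent <- match.arg(cap_extent)
  lens <- c(nh_bond_length, ch_bond_length, sh_bond_length)
  if (any(lens <= 0.8) || any(lens >= 1.8)) {
    stop("link-hydrogen bond lengths must lie in (0.8, 1.8) Angstrom")
  }
  structure(list(cap_extent = cap_extent,
                 nh_bond_length = nh_bond_length,
                 ch_bond_length = ch_bond_length,
                 sh_bond_length = sh_bond_length,
                 cut_disulfides = cut_disulfides,
                 link_charge = link_charge,
                 link_epsilon = link_epsilon,
                 link_rmin_half = link_rmin_half),
            class = "cap_scheme")
}

.link_length <- function(scheme, kept_elem) {
  switch(toupper(kept_elem),
         N = scheme$nh_bond_length,
         S = scheme$sh_bond_length,
         scheme$ch_bond_length)
}

#' Place a link hydrogen along a cut bond
#'
#' The hydrogen saturating a dangling valence lies on the segment from the
#' kept atom towards the removed neighbour, at the scheme's bond length for
#' the kept atom's element (N-H 1.01, C-H 1.09, S-H 1.34 Angstrom by
#' default).
#'
#' @param kept_atom,removed_neighbor Single-row atom data.frames (or lists)
#'   with `x`, `y`, `z` and `elem`.
#' @param scheme A [cap_scheme()].
#' @return A one-row atom data.frame for the hydrogen (name `"HL"`), carrying
#'   the scheme's link-hydrogen charge and LJ parameters.
#' @export
place_link_hydrogen <- function(kept_atom, removed_neighbor,
                                scheme = cap_scheme()) {
  p <- c(kept_atom$x, kept_atom$y, kept_atom$z)
  q <- c(removed_neighbor$x, removed_neighbor$y, removed_neighbor$z)
  v <- q - p
  len <- sqrt(sum(v^2))
  if (len < 1e-6) stop("coincident atoms: cannot orient link hydrogen")
  h <- p + .link_length(scheme, kept_atom$elem) * v / len
  data.frame(id = NA_integer_, name = "HL", elem = "H",
             resid = "LNK", chain = "Z", resno = 0L,
             x = h[1], y = h[2], z = h[3],
             charge = scheme$link_charge, epsilon = scheme$link_epsilon,
             rmin_half = scheme$link_rmin_half, is_ligand = FALSE,
             residue_key = "LNK", stringsAsFactors = FALSE)
}

.BACKBONE_NAMES <- c("N", "HN", "CA", "HA", "HA1", "HA2", "C", "O", "OXT")

# atom ids contributed by residue `key` when used as a conjugate cap
.cap_atom_ids <- function(model, key, scheme) {
  at <- residue_atoms(model, key)
  if (scheme$cap_extent == "backbone_only") {
    at <- at[at$name %in% .BACKBONE_NAMES, , drop = FALSE]
  }
  at$id
}

# build one fragment system from a set of receptor atom ids (+ ligand),
# terminating every cut covalent bond with a link hydrogen.  `link_pool` is
# an environment cache keyed by "kept|removed" so identical cuts across
# systems of one quadruple reuse the same hydrogen row.
.build_system <- function(model, receptor_ids, include_ligand, scheme,
                          link_pool, label) {
  ids <- receptor_ids
  if (include_ligand) ids <- c(model$ligand$atom_ids, ids)
  atoms <- model$atoms[match(ids, model$atoms$id), , drop = FALSE]

  bonds <- model$bonds
  link_rows <- list()
  link_bonds <- list()
  if (nrow(bonds) > 0 && length(receptor_ids) > 0) {
    in1 <- bonds[, 1] %in% receptor_ids
    in2 <- bonds[, 2] %in% receptor_ids
    cut <- which(xor(in1, in2))
    for (b in cut) {
      kept_id <- if (in1[b]) bonds[b, 1] else bonds[b, 2]
      gone_id <- if (in1[b]) bonds[b, 2] else bonds[b, 1]
      if (model$atoms$is_ligand[match(gone_id, model$atoms$id)]) next
      kept <- model$atoms[match(kept_id, model$atoms$id), ]
      gone <- model$atoms[match(gone_id, model$atoms$id), ]
      if (kept$elem == "S" && gone$elem == "S" && !scheme$cut_disulfides) {
        stop("disulfide spans the fragment boundary and cut_disulfides is FALSE")
      }
      ck <- paste0(kept_id, "|", gone_id)
      if (is.null(link_pool[[ck]])) {
        link_pool[[ck]] <- place_link_hydrogen(kept, gone, scheme)
      }
      h <- link_pool[[ck]]
      link_rows[[length(link_rows) + 1L]] <- h
      link_bonds[[length(link_bonds) + 1L]] <- c(kept_id, NA_integer_)
    }
  }

  n_real <- nrow(atoms)
  n_link <- length(link_rows)
  if (n_link > 0) {
    lh <- do.call(rbind, link_rows)
    lh$id <- -(seq_len(n_link))          # negative ids mark link hydrogens
    atoms <- rbind(atoms, lh)
  }
  # local bond list (row indices into `atoms`)
  keep_b <- matrix(integer(0), ncol = 2)
  if (nrow(bonds) > 0) {
    both <- bonds[bonds[, 1] %in% ids & bonds[, 2] %in% ids, , drop = FALSE]
    if (nrow(both) > 0) {
      keep_b <- cbind(match(both[, 1], atoms$id), match(both[, 2], atoms$id))
    }
  }
  if (n_link > 0) {
    kb <- vapply(seq_len(n_link),
                 function(i) match(link_bonds[[i]][1], atoms$id), integer(1))
    keep_b <- rbind(keep_b, cbind(kb, n_real + seq_len(n_link)))
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, bonds = keep_b, n_link = n_link,
                 label = label),
            class = "fragment_system")
}

#' Cleave out one residue and build its four MFCC systems
#'
#' Cuts the peptide bonds around residue `residue_key`, builds the conjugate
#' caps from the flanking residues, saturates every cut bond with a link
#' hydrogen, and returns the four atom systems of the MFCC energy
#' difference.  For terminal residues only the existing-side cap is present;
#' a residue with no neighbours yields empty caps with a warning.
#'
#' @param model A `structure_model` (parameterized if a classical backend
#'   will consume the result).
#' @param residue_key Residue key (`"chain:resno"`) or printed label
#'   (`"ASP106"`, unique labels only).
#' @param scheme A [cap_scheme()].
#' @return A `fragment_quadruple`: list with `fragment_system`s `sys_l_crc`,
#'   `sys_l_cc`, `sys_crc`, `sys_cc`, the per-system `link_hydrogens`
#'   data.frames, and `residue_key`.
#' @export
cleave_and_cap <- function(model, residue_key, scheme = cap_scheme()) {
  stopifnot(inherits(model, "structure_model"))
  key <- .resolve_residue_key(model, residue_key)
  res <- model$residues[model$residues$key == key, ]
  nb <- c(res$n_neighbor, res$c_neighbor)
  nb <- nb[!is.na(nb)]
  if (length(nb) == 0) {
    warning("residue ", res$label, " has no neighbours; caps are empty")
  }
  cap_ids <- unlist(lapply(nb, .cap_atom_ids, model = model, scheme = scheme))
  ri_ids <- residue_atoms(model, key)$id

  pool <- new.env(parent = emptyenv())
  sys_crc <- .build_system(model, c(cap_ids, ri_ids), FALSE, scheme, pool, "crc")
  sys_cc <- .build_system(model, cap_ids, FALSE, scheme, pool, "cc")
  # ligand systems reuse the receptor-side rows (bit-exact cap identity)
  with_lig <- function(sys, label) {
    lig <- ligand_atoms(model)
    atoms <- rbind(lig, sys$atoms)
    lig_bonds <- model$bonds[model$bonds[, 1] %in% lig$id &
                             model$bonds[, 2] %in% lig$id, , drop = FALSE]
    lb <- cbind(match(lig_bonds[, 1], atoms$id), match(lig_bonds[, 2], atoms$id))
    if (nrow(sys$bonds) > 0) {
      bonds <- cbind(match(sys$atoms$id[sys$bonds[, 1]], atoms$id),
                     match(sys$atoms$id[sys$bonds[, 2]], atoms$id))
    } else {
      bonds <- matrix(integer(0), ncol = 2)
    }
    rownames(atoms) <- NULL
    structure(list(atoms = atoms, bonds = rbind(lb, bonds),
                   n_link = sys$n_link, label = label),
              class = "fragment_system")
  }
  q <- list(sys_l_crc = with_lig(sys_crc, "l_crc"),
            sys_l_cc = with_lig(sys_cc, "l_cc"),
            sys_crc = sys_crc,
            sys_cc = sys_cc,
            residue_key = key,
            scheme = scheme)
  q$link_hydrogens <- lapply(q[1:4], function(s) {
    s$atoms[s$atoms$id < 0 & !is.na(s$atoms$id), , drop = FALSE]
  })
  class(q) <- "fragment_quadruple"
  q
}

# accept "A:106" keys or unique printed labels like "ASP106"
.resolve_residue_key <- function(model, residue_key) {
  if (residue_key %in% model$residues$key) return(residue_key)
  if (residue_key == "LIG" || residue_key == model$ligand$code) {
    stop("the ligand cannot be fragmented as a residue")
  }
  hit <- which(model$residues$label == residue_key)
  if (length(hit) == 1) return(model$residues$key[hit])
  if (length(hit) > 1) stop("ambiguous residue label: ", residue_key)
  stop("unknown residue: ", residue_key)
}

#' Fragment every residue of the receptor
#'
#' @param model A `structure_model`.
#' @param scheme A [cap_scheme()].
#' @param keys Residue keys to fragment (default: all).
#' @return Named list of `fragment_quadruple`s.
#' @export
fragment_all <- function(model, scheme = cap_scheme(),
                         keys = model$residues$key) {
  out <- lapply(keys, cleave_and_cap, model = model, scheme = scheme)
  names(out) <- keys
  out
}

#' Export a fragment system as a PDB file
#'
#' Debug writer: link hydrogens are flagged with element `H`, residue name
#' `LNK` and a formal charge tag in the charge column.
#'
#' @param system A `fragment_system`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragment_pdb <- function(system, path) {
  a <- system$atoms
  is_link <- !is.na(a$id) & a$id < 0
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$is_ligand, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$name,
                   chain = a$chain, o = rep(1, nrow(a)),
                   b = as.numeric(is_link),
                   elesy = a$elem)
  invisible(path)
}

#' @export
print.fragment_quadruple <- function(x, ...) {
  cat("fragment_quadruple for residue", x$residue_key, "\n")
  for (s in c("sys_l_crc", "sys_l_cc", "sys_crc", "sys_cc")) {
    cat(sprintf("  %-9s %3d atoms (%d link H)\n", s, nrow(x[[s]]$atoms),
                x[[s]]$n_link))
  }
  invisible(x)
}
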