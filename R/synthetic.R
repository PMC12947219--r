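## Deterministic synthetic receptor-ligand complexes.
##
## The generator emulates a small binding pocket: a short peptide chain
## wrapped around a small polar ligand bearing a protonated amine (+1), with
## residue nearest approaches spanning roughly 2-10 A and a mix of charged
## (ASP, LYS) and neutral residues so per-residue energies take both signs.
## Geometry is plausible (bonded C-N distances exactly 1.33 A, standard
## intra-residue bond lengths) but not relaxed: the classical backend only
## needs finite, non-singular coordinates.

.unitv <- function(v) v / sqrt(sum(v^2))

.perp_basis <- function(v) {
  v <- .unitv(v)
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unitv(a - sum(a * v) * v)
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  cbind(e1, e2)
}

# place n hydrogens on atom p given its heavy neighbours (list of 3-vectors)
.h_on <- function(p, nbrs, n, len) {
  v <- .unitv(Reduce(`+`, lapply(nbrs, function(q) .unitv(p - q))))
  if (length(nbrs) == 2) {
    w <- .unitv(c((nbrs[[1]] - p)[2] * (nbrs[[2]] - p)[3] -
                    (nbrs[[1]] - p)[3] * (nbrs[[2]] - p)[2],
                  (nbrs[[1]] - p)[3] * (nbrs[[2]] - p)[1] -
                    (nbrs[[1]] - p)[1] * (nbrs[[2]] - p)[3],
                  (nbrs[[1]] - p)[1] * (nbrs[[2]] - p)[2] -
                    (nbrs[[1]] - p)[2] * (nbrs[[2]] - p)[1]))
    eb <- .perp_basis(v)
    e1 <- if (n == 2) w else eb[, 1]
  } else {
    e1 <- .perp_basis(v)[, 1]
  }
  e2 <- .perp_basis(v)[, 2]
  dirs <- switch(as.character(n),
    "1" = list(v),
    "2" = list(.unitv(0.577 * v + 0.817 * e1),
               .unitv(0.577 * v - 0.817 * e1)),
    "3" = lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(th) {
      .unitv(0.334 * v + 0.943 * (cos(th) * e1 + sin(th) * e2))
    }),
    stop("unsupported hydrogen count"))
  t(vapply(dirs, function(d) p + len * d, numeric(3)))
}

# idealized local-coordinate template for one residue type.
# N sits at the origin and C on the +x axis so chaining residues along a
# 3.80 A step leaves a 1.33 A peptide C-N bond.
.residue_template <- function(resname) {
  at <- list()
  add <- function(name, p) at[[name]] <<- p
  N <- c(0, 0, 0); CA <- c(1.24, 0.95, 0); C <- c(2.47, 0, 0)
  add("N", N); add("CA", CA); add("C", C)
  add("O", C + 1.23 * .unitv(c(0.25, -1.18, 0.12)))
  add("HN", .h_on(N, list(CA, C - c(3.8, 0, 0)), 1, 1.01)[1, ])
  dir_cb <- c(0, 0.55, -0.84); dir_ha <- c(0, 0.55, 0.84)
  CB <- CA + 1.53 * .unitv(dir_cb)
  d1 <- c(0, 0.46, -1); d2 <- c(0, -0.46, -1)
  if (resname == "GLY") {
    add("HA1", CA + 1.09 * .unitv(dir_ha))
    add("HA2", CA + 1.09 * .unitv(dir_cb))
  } else {
    add("HA", CA + 1.09 * .unitv(dir_ha))
    add("CB", CB)
  }
  if (resname == "ALA") {
    h <- .h_on(CB, list(CA), 3, 1.09)
    add("HB1", h[1, ]); add("HB2", h[2, ]); add("HB3", h[3, ])
  } else if (resname == "SER") {
    OG <- CB + 1.42 * .unitv(d2); add("OG", OG)
    h <- .h_on(CB, list(CA, OG), 2, 1.09)
    add("HB1", h[1, ]); add("HB2", h[2, ])
    add("HG1", .h_on(OG, list(CB), 1, 0.96)[1, ])
  } else if (resname == "CYS") {
    SG <- CB + 1.81 * .unitv(d2); add("SG", SG)
    h <- .h_on(CB, list(CA, SG), 2, 1.09)
    add("HB1", h[1, ]); add("HB2", h[2, ])
    add("HG1", .h_on(SG, list(CB), 1, 1.34)[1, ])
  } else if (resname == "VAL") {
    CG1 <- CB + 1.53 * .unitv(c(0, 0.9, -0.9))
    CG2 <- CB + 1.53 * .unitv(c(0, -1.0, -0.35))
    add("CG1", CG1); add("CG2", CG2)
    add("HB", .h_on(CB, list(CA, CG1, CG2), 1, 1.09)[1, ])
    h <- .h_on(CG1, list(CB), 3, 1.09)
    add("HG11", h[1, ]); add("HG12", h[2, ]); add("HG13", h[3, ])
    h <- .h_on(CG2, list(CB), 3, 1.09)
    add("HG21", h[1, ]); add("HG22", h[2, ]); add("HG23", h[3, ])
  } else if (resname == "ASP") {
    CG <- CB + 1.52 * .unitv(d2); add("CG", CG)
    h <- .h_on(CB, list(CA, CG), 2, 1.09)
    add("HB1", h[1, ]); add("HB2", h[2, ])
    add("OD1", CG + 1.25 * .unitv(c(0, 0.95, -0.65)))
    add("OD2", CG + 1.25 * .unitv(c(0, -0.95, -0.65)))
  } else if (resname == "LYS") {
    CG <- CB + 1.53 * .unitv(d2); CD <- CG + 1.53 * .unitv(d1)
    CE <- CD + 1.53 * .unitv(d2); NZ <- CE + 1.49 * .unitv(d1)
    add("CG", CG); add("CD", CD); add("CE", CE); add("NZ", NZ)
    h <- .h_on(CB, list(CA, CG), 2, 1.09); add("HB1", h[1, ]); add("HB2", h[2, ])
    h <- .h_on(CG, list(CB, CD), 2, 1.09); add("HG1", h[1, ]); add("HG2", h[2, ])
    h <- .h_on(CD, list(CG, CE), 2, 1.09); add("HD1", h[1, ]); add("HD2", h[2, ])
    h <- .h_on(CE, list(CD, NZ), 2, 1.09); add("HE1", h[1, ]); add("HE2", h[2, ])
    h <- .h_on(NZ, list(CE), 3, 1.01)
    add("HZ1", h[1, ]); add("HZ2", h[2, ]); add("HZ3", h[3, ])
  } else if (resname == "PHE") {
    CG <- CB + 1.50 * .unitv(d2); add("CG", CG)
    h <- .h_on(CB, list(CA, CG), 2, 1.09); add("HB1", h[1, ]); add("HB2", h[2, ])
    u <- .unitv(CG - CB)
    ctr <- CG + 1.39 * u
    p <- .perp_basis(u)[, 1]
    vert <- function(theta) ctr + 1.39 * (cos(theta) * (-u) + sin(theta) * p)
    ring <- list(CD1 = vert(pi / 3), CE1 = vert(2 * pi / 3), CZ = vert(pi),
                 CD2 = vert(-pi / 3), CE2 = vert(-2 * pi / 3))
    for (nm in names(ring)) add(nm, ring[[nm]])
    for (nm in names(ring)) {
      add(sub("C", "H", nm), ctr + 2.47 * .unitv(ring[[nm]] - ctr))
    }
  } else if (!resname %in% c("GLY", "ALA")) {
    stop("no template for residue type ", resname)
  }
  m <- do.call(rbind, at)
  data.frame(atom = rownames(m), elem = .elem_from_name(rownames(m)),
             x = m[, 1], y = m[, 2], z = m[, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}

# synthetic ligand: protonated ethanolamine-like molecule, code AMX.
# full form 12 atoms (+1 on the amine); `n_atoms` below the full size keeps
# only the 7-atom protonated-amine core (still +1).
.ligand_template <- function(n_atoms = 12) {
  C1 <- c(0, 0, 0)
  O1 <- C1 + 1.38 * .unitv(c(-0.95, 1.0, 0))
  C2 <- C1 + 1.53 * .unitv(c(1.2, 0.95, 0))
  N1 <- C2 + 1.51 * .unitv(c(1.25, -0.85, 0))
  at <- list(O1 = O1, HO1 = .h_on(O1, list(C1), 1, 0.96)[1, ], C1 = C1)
  h <- .h_on(C1, list(O1, C2), 2, 1.09)
  at$H11 <- h[1, ]; at$H12 <- h[2, ]
  at$C2 <- C2
  h <- .h_on(C2, list(C1, N1), 2, 1.09)
  at$H21 <- h[1, ]; at$H22 <- h[2, ]
  at$N1 <- N1
  h <- .h_on(N1, list(C2), 3, 1.01)
  at$HN1 <- h[1, ]; at$HN2 <- h[2, ]; at$HN3 <- h[3, ]
  if (n_atoms < 12) {
    at <- at[c("C2", "H21", "H22", "N1", "HN1", "HN2", "HN3")]
  }
  m <- do.call(rbind, at)
  m <- sweep(m, 2, colMeans(m))            # centre at the origin
  data.frame(atom = rownames(m), elem = .elem_from_name(rownames(m)),
             x = m[, 1], y = m[, 2], z = m[, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Default region map for the synthetic ligand
#'
#' Two chemical regions: `i`, the hydroxymethyl arm (O1, C1); `ii`, the
#' protonated amine arm (C2, N1).  The amine-core ligand variant only has
#' region `ii` atoms.
#'
#' @param model Optional `structure_model`; when given, the map is restricted
#'   to heavy atoms actually present on its ligand.
#' @return A [region_map()].
#' @export
default_region_map <- function(model = NULL) {
  map <- region_map(list(i = c("O1", "C1"), ii = c("C2", "N1")))
  if (!is.null(model)) {
    la <- ligand_atoms(model)
    map <- region_map(unclass(map)[names(map) %in% la$name[la$elem != "H"]])
  }
  map
}

#' Specification of a synthetic toy complex
#'
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @param n_residues Chain length (>= 3).
#' @param ligand_n_atoms Ligand size: 12 (full hydroxy-amine ligand) or
#'   fewer for the 7-atom protonated-amine core.
#' @param distance_range Range (min, max) in Angstrom that residue nearest
#'   approaches to the ligand must fall in; must lie within (1.5, 12).
#' @param charge_profile Fraction of residues drawn from the charged types
#'   (alternating ASP/LYS).
#' @param epsilon Dielectric used for the ground-truth energies.
#' @return A `toy_complex_spec`.
#' @export
toy_complex_spec <- function(seed = 1, n_residues = 12, ligand_n_atoms = 12,
                             distance_range = c(2, 10),
                             charge_profile = 0.3, epsilon = 40) {
  stopifnot(n_residues >= 3, length(distance_range) == 2,
            distance_range[1] < distance_range[2],
            charge_profile >= 0, charge_profile <= 1)
  if (distance_range[1] <= 1.5 || distance_range[2] >= 12) {
    stop("distance_range must lie within (1.5, 12) Angstrom")
  }
  structure(list(seed = as.integer(seed), n_residues = as.integer(n_residues),
                 ligand_n_atoms = as.integer(ligand_n_atoms),
                 distance_range = as.numeric(distance_range),
                 charge_profile = charge_profile, epsilon = epsilon),
            class = "toy_complex_spec")
}

# direct Coulomb+LJ cross energy between two coordinate/parameter blocks,
# written as an explicit double loop: the independent ground-truth formula
.direct_cross_energy <- function(a, b, epsilon) {
  e <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      r <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$z[i] - b$z[j])^2)
      rmin <- a$rmin_half[i] + b$rmin_half[j]
      e <- e + 332.0637 * a$charge[i] * b$charge[j] / (epsilon * r) +
        sqrt(a$epsilon[i] * b$epsilon[j]) * ((rmin / r)^12 - 2 * (rmin / r)^6)
    }
  }
  e
}

#' Generate a deterministic synthetic receptor-ligand complex
#'
#' Builds a peptide chain of standard residues as a self-avoiding walk
#' around the synthetic ligand, with peptide C-N bonds of 1.33 A, nearest
#' approaches to the ligand inside `distance_range`, and a charged-residue
#' fraction given by `charge_profile`.  The returned ground truth carries
#' each residue's direct ligand-residue pairwise energy and minimum contact
#' distance, computed by plain pair enumeration independent of the pipeline
#' code.
#'
#' @param spec A [toy_complex_spec()].
#' @return List with `model` (parameterized `structure_model`),
#'   `ground_truth` (data.frame: `residue_key`, `label`, `energy`,
#'   `min_distance`, `closest_residue_atom`, `closest_ligand_atom`),
#'   `region_map` and `spec`.
#' @export
generate_toy_complex <- function(spec = toy_complex_spec()) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  withr::with_seed(spec$seed, .generate_toy_impl(spec))
}

.generate_toy_impl <- function(spec) {
  dmin <- spec$distance_range[1]; dmax <- spec$distance_range[2]
  n <- spec$n_residues
  lig <- .ligand_template(spec$ligand_n_atoms)

  n_charged <- round(spec$charge_profile * n)
  types <- c(rep(c("ASP", "LYS"), length.out = n_charged),
             sample(c("GLY", "ALA", "SER", "VAL", "PHE", "CYS"),
                    n - n_charged, replace = TRUE))
  types <- sample(types)

  templates <- lapply(types, .residue_template)
  lig_xyz <- as.matrix(lig[, c("x", "y", "z")])
  step_len <- 3.80

  rand_unit <- function() {
    repeat {
      v <- stats::runif(3, -1, 1)
      if ((s <- sum(v^2)) > 1e-4 && s < 1) return(v / sqrt(s))
    }
  }
  place_res <- function(tmpl, anchor, u, phi) {
    pb <- .perp_basis(u)
    yv <- cos(phi) * pb[, 1] + sin(phi) * pb[, 2]
    zv <- c(u[2] * yv[3] - u[3] * yv[2], u[3] * yv[1] - u[1] * yv[3],
            u[1] * yv[2] - u[2] * yv[1])
    rot <- cbind(u, yv, zv)
    xyz <- as.matrix(tmpl[, c("x", "y", "z")]) %*% t(rot)
    sweep(xyz, 2, anchor, "+")
  }
  min_dist <- function(a, b) {
    sqrt(min(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2 +
               outer(a[, 3], b[, 3], "-")^2))
  }

  # residue k's backbone axis u_k fixes residue k+1's anchor; propose axes
  # whose implied next anchor stays inside the contact shell
  shell_lo <- dmin + 0.8; shell_hi <- dmax - 0.8
  propose_axis <- function(anchor, last) {
    for (t in seq_len(60)) {
      u <- rand_unit()
      if (last) return(u)
      rn <- sqrt(sum((anchor + step_len * u)^2))
      if (rn >= shell_lo && rn <= shell_hi) return(u)
    }
    NULL
  }
  # template extents (max atom distance from the N anchor) for cheap
  # anchor-level prefilters before full atom-atom clash checks
  ext <- vapply(templates, function(t) {
    sqrt(max(t$x^2 + t$y^2 + t$z^2))
  }, numeric(1))
  lig_ext <- sqrt(max(lig$x^2 + lig$y^2 + lig$z^2))
  clash_cut <- 1.5

  # adjacent residues meet at the peptide junction: their 1-2/1-3 pairs
  # (C-N, C-CA, C-HN, O-N, CA-N) are legitimately close, every other cross
  # pair must keep ordinary non-bonded clearance
  junction_ok <- rbind(c("C", "N"), c("C", "CA"), c("C", "HN"),
                       c("O", "N"), c("CA", "N"))
  .junction_clash <- function(prev_xyz, prev_names, cur_xyz, cur_names) {
    d <- sqrt(outer(prev_xyz[, 1], cur_xyz[, 1], "-")^2 +
                outer(prev_xyz[, 2], cur_xyz[, 2], "-")^2 +
                outer(prev_xyz[, 3], cur_xyz[, 3], "-")^2)
    for (r in seq_len(nrow(junction_ok))) {
      i <- match(junction_ok[r, 1], prev_names)
      j <- match(junction_ok[r, 2], cur_names)
      if (!is.na(i) && !is.na(j)) d[i, j] <- Inf
    }
    min(d) < 1.25
  }

  # depth-first placement with backtracking: a residue that cannot be
  # placed sends the walk one step back to redraw its predecessor
  placed <- vector("list", n)
  anchors <- vector("list", n)
  budget <- 200000L
  k <- 1L
  streak <- 0L                           # consecutive dead ends
  while (k <= n) {
    if (budget <= 0L) stop("could not place the toy chain after bounded retries")
    done <- FALSE
    for (try in seq_len(300)) {
      budget <- budget - 1L
      anchor <- if (k == 1L) {
        stats::runif(1, shell_lo, shell_hi) * rand_unit()
      } else {
        anchors[[k - 1L]]$pos + step_len * anchors[[k - 1L]]$dir
      }
      u <- propose_axis(anchor, last = (k == n))
      if (is.null(u)) break
      phi <- stats::runif(1, 0, 2 * pi)
      xyz <- place_res(templates[[k]], anchor, u, phi)
      an <- sqrt(sum(anchor^2))
      d_lig <- if (an > ext[k] + lig_ext + dmax) Inf else min_dist(xyz, lig_xyz)
      if (d_lig < dmin || d_lig > dmax) next
      clash <- FALSE
      if (k > 2L) {
        for (m in seq_len(k - 2L)) {
          gap <- sqrt(sum((anchor - anchors[[m]]$pos)^2))
          if (gap > ext[k] + ext[m] + clash_cut) next
          if (min_dist(xyz, placed[[m]]) < clash_cut) { clash <- TRUE; break }
        }
      }
      if (!clash && k > 1L &&
          .junction_clash(placed[[k - 1L]], templates[[k - 1L]]$atom,
                          xyz, templates[[k]]$atom)) clash <- TRUE
      if (clash) next
      placed[[k]] <- xyz
      anchors[[k]] <- list(pos = anchor, dir = u)
      done <- TRUE
      break
    }
    if (done) {
      k <- k + 1L
      streak <- 0L
    } else if (streak >= 40L) {
      placed <- vector("list", n)        # persistent dead end: restart
      anchors <- vector("list", n)
      k <- 1L
      streak <- 0L
    } else {
      streak <- streak + 1L
      depth <- min(k - 1L, 1L + streak %/% 4L)
      if (depth > 0L) placed[seq(k - depth, k)] <- list(NULL)
      k <- max(1L, k - depth)            # backtrack and redraw predecessors
    }
  }

  rows <- list()
  for (k in seq_len(n)) {
    tmpl <- templates[[k]]
    rows[[k]] <- data.frame(
      name = tmpl$atom, elem = tmpl$elem, resid = types[k], chain = "A",
      resno = k, x = placed[[k]][, 1], y = placed[[k]][, 2],
      z = placed[[k]][, 3], is_ligand = FALSE, stringsAsFactors = FALSE)
  }
  rows[[n + 1]] <- data.frame(
    name = lig$atom, elem = lig$elem, resid = "AMX", chain = "L",
    resno = 1L, x = lig$x, y = lig$y, z = lig$z, is_ligand = TRUE,
    stringsAsFactors = FALSE)
  atoms <- do.call(rbind, rows)
  atoms <- cbind(id = seq_len(nrow(atoms)), atoms)
  atoms$charge <- NA_real_; atoms$epsilon <- NA_real_
  atoms$rmin_half <- NA_real_

  model <- .make_model(atoms, ligand_code = "AMX",
                       dielectric_default = spec$epsilon,
                       source = sprintf("toy_complex(seed=%d)", spec$seed))
  model <- assign_parameters(model, default_parameter_table())

  # ground truth by direct pair enumeration, independent of the pipeline
  la <- ligand_atoms(model)
  gt <- lapply(seq_len(nrow(model$residues)), function(i) {
    k <- model$residues$key[i]
    ra <- model$atoms[model$atoms$residue_key == k, , drop = FALSE]
    best <- c(Inf, NA, NA)
    for (p in seq_len(nrow(ra))) {
      for (q in seq_len(nrow(la))) {
        r <- sqrt((ra$x[p] - la$x[q])^2 + (ra$y[p] - la$y[q])^2 +
                    (ra$z[p] - la$z[q])^2)
        if (r < best[1]) best <- c(r, p, q)
      }
    }
    data.frame(residue_key = k, label = model$residues$label[i],
               energy = .direct_cross_energy(ra, la, spec$epsilon),
               min_distance = best[1],
               closest_residue_atom = ra$name[best[2]],
               closest_ligand_atom = la$name[best[3]],
               stringsAsFactors = FALSE)
  })
  list(model = model, ground_truth = do.call(rbind, gt),
       region_map = default_region_map(model), spec = spec)
}

#' Brute-force reference for the MFCC residue energy
#'
#' Independent oracle for the four-term MFCC combination under a strictly
#' pairwise-additive backend: the direct ligand-residue cross energy, plus
#' the ligand interaction with the link hydrogens of the capped-residue
#' system, minus the ligand interaction with the link hydrogens of the
#' caps-only system.  Link-hydrogen positions are recomputed here by direct
#' vector arithmetic from the covalent topology; no fragmentation code is
#' used.
#'
#' @param model A parameterized `structure_model`.
#' @param residue_key Residue key or label.
#' @param scheme A [cap_scheme()] (link-hydrogen lengths and parameters).
#' @param epsilon Dielectric constant.
#' @return Energy in kcal/mol.
#' @export
brute_force_reference <- function(model, residue_key, scheme = cap_scheme(),
                                  epsilon = model$dielectric_default) {
  stopifnot(inherits(model, "structure_model"), model$parameterized)
  key <- .resolve_residue_key(model, residue_key)
  res <- model$residues[model$residues$key == key, ]
  la <- ligand_atoms(model)
  ra <- model$atoms[model$atoms$residue_key == key, , drop = FALSE]

  nb <- c(res$n_neighbor, res$c_neighbor)
  nb <- nb[!is.na(nb)]
  link_h_for <- function(ids) {
    # hydrogens saturating every bond cut by restricting to `ids`
    out <- list()
    b <- model$bonds
    for (r in seq_len(nrow(b))) {
      i1 <- b[r, 1] %in% ids; i2 <- b[r, 2] %in% ids
      if (i1 == i2) next
      kept <- model$atoms[match(if (i1) b[r, 1] else b[r, 2], model$atoms$id), ]
      gone <- model$atoms[match(if (i1) b[r, 2] else b[r, 1], model$atoms$id), ]
      if (gone$is_ligand) next
      len <- switch(kept$elem, N = scheme$nh_bond_length,
                    S = scheme$sh_bond_length, scheme$ch_bond_length)
      v <- c(gone$x - kept$x, gone$y - kept$y, gone$z - kept$z)
      h <- c(kept$x, kept$y, kept$z) + len * v / sqrt(sum(v^2))
      out[[length(out) + 1L]] <- data.frame(
        x = h[1], y = h[2], z = h[3], charge = scheme$link_charge,
        epsilon = scheme$link_epsilon, rmin_half = scheme$link_rmin_half)
    }
    if (length(out) == 0) {
      data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                 charge = numeric(0), epsilon = numeric(0),
                 rmin_half = numeric(0))
    } else {
      do.call(rbind, out)
    }
  }
  cap_ids <- unlist(lapply(nb, function(k) {
    at <- model$atoms[model$atoms$residue_key == k, , drop = FALSE]
    if (scheme$cap_extent == "backbone_only") {
      at <- at[at$name %in% .BACKBONE_NAMES, , drop = FALSE]
    }
    at$id
  }))
  h_crc <- link_h_for(c(cap_ids, ra$id))
  h_cc <- link_h_for(cap_ids)

  .direct_cross_energy(la, ra, epsilon) +
    (if (nrow(h_crc) > 0) .direct_cross_energy(la, h_crc, epsilon) else 0) -
    (if (nrow(h_cc) > 0) .direct_cross_energy(la, h_cc, epsilon) else 0)
}

#' Write a toy complex to standard exchange files
#'
#' Emits the complex as PDB plus a parameter CSV and a regions JSON, so the
#' same readers used for real data can be exercised end to end.
#'
#' @param toy Result of [generate_toy_complex()].
#' @param dir Output directory (created if needed).
#' @return Named character vector with paths `pdb`, `params`, `regions`.
#' @export
write_toy_complex <- function(toy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(dir, "toy_complex.pdb")
  par <- file.path(dir, "toy_params.csv")
  reg <- file.path(dir, "toy_regions.json")
  write_structure_pdb(toy$model, pdb)
  tab <- default_parameter_table()
  used <- tab[tab$residue %in% unique(toy$model$atoms$resid), ]
  utils::write.csv(used, par, row.names = FALSE, quote = FALSE)
  write_region_map(toy$region_map, reg)
  c(pdb = pdb, params = par, regions = reg)
}
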