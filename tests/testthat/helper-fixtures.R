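# shared fixtures, built in code

# small deterministic complex reused across tests
fixture_toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_toy_complex(
        toy_complex_spec(seed = 11, n_residues = 6, charge_profile = 0.5))
    }
    cache
  }
})

# bare point-particle atom table for closed-form energy checks;
# ids drawn from a counter so independently built sets stay disjoint
.point_id_counter <- local({n <- 0L; function(k) {n <<- n + 1000L; n + seq_len(k)}})
point_atoms <- function(xyz, charge, epsilon = 0, rmin_half = 1) {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  data.frame(id = .point_id_counter(nrow(xyz)),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             charge = charge,
             epsilon = rep_len(epsilon, nrow(xyz)),
             rmin_half = rep_len(rmin_half, nrow(xyz)))
}

# independent double-loop Coulomb + LJ cross-energy (test-side oracle)
ref_cross_energy <- function(a, b, eps) {
  e <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    r <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2)
    rmin <- a$rmin_half[i] + b$rmin_half[j]
    e <- e + 332.0637 * a$charge[i] * b$charge[j] / (eps * r) +
      sqrt(a$epsilon[i] * b$epsilon[j]) * ((rmin / r)^12 - 2 * (rmin / r)^6)
  }
  e
}

# hand-assembled minimal structure_model (one residue + ligand point sets)
mini_model <- function(res_xyz, lig_xyz) {
  nr <- nrow(res_xyz <- matrix(res_xyz, ncol = 3, byrow = TRUE))
  nl <- nrow(lig_xyz <- matrix(lig_xyz, ncol = 3, byrow = TRUE))
  atoms <- data.frame(
    id = seq_len(nr + nl),
    name = c(paste0("R", seq_len(nr)), paste0("L", seq_len(nl))),
    elem = "C",
    resid = c(rep("GLY", nr), rep("LIG", nl)),
    chain = c(rep("A", nr), rep("L", nl)),
    resno = c(rep(1L, nr), rep(1L, nl)),
    x = c(res_xyz[, 1], lig_xyz[, 1]),
    y = c(res_xyz[, 2], lig_xyz[, 2]),
    z = c(res_xyz[, 3], lig_xyz[, 3]),
    charge = 0, epsilon = 0, rmin_half = 1,
    is_ligand = c(rep(FALSE, nr), rep(TRUE, nl)),
    stringsAsFactors = FALSE)
  mfccr:::.make_model(atoms, ligand_code = "LIG")
}
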