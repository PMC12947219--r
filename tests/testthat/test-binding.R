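# minimum distances, radius sweep, convergence, ranking, regions

test_that("minimum contact distance finds the global minimum with id tie-break", {
  m <- mini_model(res_xyz = c(0, 0, 0),
                  lig_xyz = c(3, 0, 0, 5, 0, 0))
  md <- residue_min_distance(m, m$residues$key[1])
  expect_equal(md$distance, 3)
  expect_identical(md$ligand_atom, "L1")

  # symmetric tie resolved towards the lowest atom ids
  m2 <- mini_model(res_xyz = c(0, 0, 0),
                   lig_xyz = c(3, 0, 0, -3, 0, 0))
  md2 <- residue_min_distance(m2, m2$residues$key[1])
  expect_identical(md2$ligand_atom, "L1")

  expect_error(residue_min_distance(m, "nope"), "unknown residue")
})

test_that("minimum distances match an exhaustive pair scan on random complexes", {
  for (seed in c(31, 32)) {
    toy <- generate_toy_complex(toy_complex_spec(seed = seed, n_residues = 5))
    m <- toy$model
    la <- mfccr:::ligand_atoms(m)
    for (k in m$residues$key) {
      ra <- mfccr:::residue_atoms(m, k)
      best <- Inf
      for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(la))) {
        best <- min(best, sqrt((ra$x[i] - la$x[j])^2 + (ra$y[i] - la$y[j])^2 +
                                 (ra$z[i] - la$z[j])^2))
      }
      expect_equal(residue_min_distance(m, k)$distance, best,
                   tolerance = 1e-12)
    }
  }
})

test_that("the radius schedule is an arithmetic grid from step to r_max", {
  expect_equal(radius_schedule(10, 0.5), seq(0.5, 10, by = 0.5))
  expect_length(radius_schedule(10, 0.5), 20)
  expect_equal(radius_schedule(1, 0.5), c(0.5, 1.0))
  expect_equal(radius_schedule(0.5, 0.5), 0.5)
  expect_error(radius_schedule(-1, 0.5))
  expect_error(radius_schedule(1, 0))
  expect_error(radius_schedule(0.3, 0.5))
})

test_that("convergence detection implements the persistent <10% rule", {
  # constant series converges at the second radius
  expect_equal(detect_convergence(c(-5, -5, -5, -5), radii = 1:4), 2)
  # worked arithmetic case: 3/33 = 9.1% then 0.5/33.5 = 1.5%
  expect_equal(detect_convergence(c(-10, -30, -33, -33.5), radii = 1:4), 3)
  # a transient pass that breaks later does not count
  expect_equal(detect_convergence(c(-10, -10.1, -30, -30.5), radii = 1:4), 4)
  # zero total: non-convergent unless the difference is also zero
  expect_equal(detect_convergence(c(5, 0, 0), radii = 1:3), 3)
  expect_true(is.na(detect_convergence(c(5, -5, 5), radii = 1:3)))
  expect_error(detect_convergence(c(1), radii = 1))
})

test_that("ranking sorts by energy with residue-number tie-break", {
  rec <- data.frame(residue = c("MET292", "ASP106", "VAL107"),
                    energy = c(1.40, -8.32, -4.50))
  ranked <- rank_residues(rec)
  expect_identical(ranked$residue, c("ASP106", "VAL107", "MET292"))
  tie <- data.frame(resno = c(7, 3, 5), energy = c(-1, -1, -1))
  expect_identical(rank_residues(tie)$resno, c(3, 5, 7))
  one <- data.frame(resno = 1, energy = 0.2)
  expect_equal(nrow(rank_residues(one)), 1)
})

test_that("region assignment uses the closest heavy atom with hydrogen delegation", {
  toy <- fixture_toy()
  m <- toy$model
  map <- toy$region_map
  expect_identical(assign_region(m, "N1", map), "ii")
  expect_identical(assign_region(m, "O1", map), "i")
  # amine hydrogens delegate to their nitrogen
  expect_identical(assign_region(m, "HN1", map), "ii")
  expect_identical(assign_region(m, "HO1", map), "i")
  expect_error(assign_region(m, "ZZ9", map), "not a ligand atom")
  expect_error(assign_region(m, "N1", region_map(list(a = "C1"))),
               "not covered")
})

test_that("the MFCC combination is E1 - E2 - E3 + E4", {
  fake_sys <- function(lab) structure(list(label = lab), class = "fragment_system")
  quad <- structure(list(sys_l_crc = fake_sys("l_crc"),
                         sys_l_cc = fake_sys("l_cc"),
                         sys_crc = fake_sys("crc"),
                         sys_cc = fake_sys("cc")),
                    class = "fragment_quadruple")
  backend <- structure(list(name = "fake", epsilon = NA, level = "fixed",
                            evaluate = function(s) {
                              switch(s$label, l_crc = 10, l_cc = 4,
                                     crc = 3, cc = 1)
                            }), class = "energy_backend")
  expect_equal(as.numeric(mfcc_residue_energy(quad, backend)), 4)
})

test_that("a far-separated ligand gives vanishing MFCC energies", {
  toy <- generate_toy_complex(toy_complex_spec(seed = 5, n_residues = 4))
  m <- toy$model
  # screened monopole-monopole Coulomb decays only as 1/r, so the +1 ligand
  # against fragment net charges needs a very large separation for |E| < 1e-6
  m$atoms$x[m$atoms$is_ligand] <- m$atoms$x[m$atoms$is_ligand] + 1e8
  b <- classical_backend(40)
  for (k in m$residues$key) {
    q <- cleave_and_cap(m, k)
    expect_lt(abs(as.numeric(mfcc_residue_energy(q, b))), 1e-6)
  }
})

test_that("the radius sweep nests inclusion sets and conserves the total", {
  toy <- fixture_toy()
  sw <- radius_sweep(toy$model, classical_backend(40),
                     region_map = toy$region_map)
  # nesting
  for (i in seq_along(sw$radii)[-1]) {
    expect_true(all(sw$included_residues[[i - 1]] %in% sw$included_residues[[i]]))
  }
  # geometry-forced inclusion counts
  expect_equal(sw$n_residues,
               vapply(sw$radii, function(r) sum(sw$records$min_distance <= r),
                      integer(1)))
  # conservation at r_max
  expect_equal(sw$cumulative_energy[length(sw$radii)], sum(sw$records$energy),
               tolerance = 1e-12)
  # every record carries a region and epsilon
  expect_false(anyNA(sw$records$region))
  expect_true(all(sw$records$epsilon == 40))
})

test_that("regional aggregation partitions the total and reports empty regions", {
  set.seed(13)
  rec <- data.frame(energy = runif(20, -10, 2),
                    region = sample(c("i", "ii"), 20, replace = TRUE))
  agg <- aggregate_regional_energies(rec, region_map(list(i = "A", ii = "B", iii = "C")))
  expect_setequal(agg$region, c("i", "ii", "iii"))
  expect_equal(agg$energy[agg$region == "iii"], 0)
  expect_equal(sum(agg$energy), sum(rec$energy), tolerance = 1e-12)
  # group sums equal an independent accumulation loop
  for (rg in c("i", "ii")) {
    s <- 0
    for (i in seq_len(nrow(rec))) if (rec$region[i] == rg) s <- s + rec$energy[i]
    expect_equal(agg$energy[agg$region == rg], s, tolerance = 1e-12)
  }
  expect_error(aggregate_regional_energies(data.frame(energy = 1, region = NA)),
               "region")
})
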