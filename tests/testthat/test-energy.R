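# classical backend and quantum-chemistry I/O

test_that("screened Coulomb term matches the closed form", {
  a <- point_atoms(c(0, 0, 0), charge = 1)
  b <- point_atoms(c(3.320637, 0, 0), charge = 1)
  a$epsilon <- 0; b$epsilon <- 0
  expect_equal(pairwise_interaction_energy(a, b, dielectric_model(10)),
               10, tolerance = 1e-9)
  expect_equal(pairwise_interaction_energy(a, b, dielectric_model(40)),
               2.5, tolerance = 1e-9)
})

test_that("LJ minimum identity holds at the combined rmin", {
  a <- point_atoms(c(0, 0, 0), charge = 0, epsilon = 0.2, rmin_half = 1.3)
  b <- point_atoms(c(2.8, 0, 0), charge = 0, epsilon = 0.3, rmin_half = 1.5)
  expect_equal(pairwise_interaction_energy(a, b, dielectric_model(40)),
               -sqrt(0.2 * 0.3), tolerance = 1e-12)
})

test_that("pairwise energy is symmetric and the Coulomb part scales with epsilon", {
  set.seed(9)
  a <- point_atoms(runif(12, -4, 4), charge = runif(4, -1, 1),
                   epsilon = runif(4, 0, 0.3), rmin_half = runif(4, 1, 2))
  b <- point_atoms(runif(9, 5, 9), charge = runif(3, -1, 1),
                   epsilon = runif(3, 0, 0.3), rmin_half = runif(3, 1, 2))
  b$id <- b$id + 100
  expect_equal(pairwise_interaction_energy(a, b, dielectric_model(17)),
               pairwise_interaction_energy(b, a, dielectric_model(17)),
               tolerance = 1e-12)
  # LJ part is epsilon-invariant; Coulomb part scales as eps1/eps2
  lj <- local({a0 <- a; b0 <- b; a0$charge <- 0; b0$charge <- 0
    pairwise_interaction_energy(a0, b0, dielectric_model(10))})
  e10 <- pairwise_interaction_energy(a, b, dielectric_model(10))
  e40 <- pairwise_interaction_energy(a, b, dielectric_model(40))
  expect_equal(e10 - lj, 4 * (e40 - lj), tolerance = 1e-10)
  expect_error(pairwise_interaction_energy(a, a, dielectric_model(10)),
               "disjoint")
})

test_that("near-singular geometries are rejected", {
  a <- point_atoms(c(0, 0, 0), charge = 1)
  b <- point_atoms(c(0.05, 0, 0), charge = 1)
  expect_error(pairwise_interaction_energy(a, b), "near-singular")
})

test_that("total energy applies 1-2/1-3 exclusions and brute-force sums otherwise", {
  one <- point_atoms(c(0, 0, 0), charge = 1)
  expect_equal(total_energy(one), 0)

  two <- point_atoms(c(0, 0, 0, 1.5, 0, 0), charge = c(1, -1))
  expect_equal(total_energy(two, bonds = rbind(c(1L, 2L))), 0)

  # 3-atom non-bonded fixture against an explicit hand sum
  xyz <- c(0, 0, 0, 3, 0, 0, 0, 4, 0)
  tri <- point_atoms(xyz, charge = c(0.5, -0.3, 0.8),
                     epsilon = c(0.1, 0.2, 0.05), rmin_half = c(1.2, 1.4, 1.6))
  hand <- ref_cross_energy(tri[1, ], tri[2, ], 40) +
    ref_cross_energy(tri[1, ], tri[3, ], 40) +
    ref_cross_energy(tri[2, ], tri[3, ], 40)
  expect_equal(total_energy(tri, dielectric_model(40)), hand,
               tolerance = 1e-12)

  # 1-3 exclusion through a common neighbour
  expect_equal(total_energy(tri, dielectric_model(40),
                            bonds = rbind(c(1L, 2L), c(2L, 3L))), 0)
  expect_error(total_energy(point_atoms(c(0, 0, 0), charge = NA)),
               "unparameterized")
})

test_that("strict additivity holds across non-bonded unions", {
  set.seed(21)
  for (rep in 1:5) {
    a <- point_atoms(runif(15, -4, 4), charge = runif(5, -1, 1),
                     epsilon = runif(5, 0, 0.2), rmin_half = runif(5, 1, 1.6))
    b <- point_atoms(runif(12, 6, 12), charge = runif(4, -1, 1),
                     epsilon = runif(4, 0, 0.2), rmin_half = runif(4, 1, 1.6))
    b$id <- b$id + 50
    ab <- rbind(a, b)
    dm <- dielectric_model(40)
    expect_equal(total_energy(ab, dm),
                 total_energy(a, dm) + total_energy(b, dm) +
                   pairwise_interaction_energy(a, b, dm),
                 tolerance = 1e-10)
  }
})

test_that("classical backend is permutation-invariant", {
  m <- fixture_toy()$model
  q <- cleave_and_cap(m, m$residues$key[3])
  b <- classical_backend(40)
  e1 <- b$evaluate(q$sys_l_crc)
  set.seed(2)
  perm <- sample(nrow(q$sys_l_crc$atoms))
  inv <- order(perm)                    # old row index -> new row index
  sys2 <- q$sys_l_crc
  sys2$atoms <- sys2$atoms[perm, ]
  sys2$bonds <- matrix(inv[q$sys_l_crc$bonds], ncol = 2)
  expect_equal(b$evaluate(sys2), e1, tolerance = 1e-10)
})

test_that("QM decks embed the level of theory and are byte-stable", {
  m <- fixture_toy()$model
  q <- cleave_and_cap(m, m$residues$key[3])
  deck <- write_qm_deck(q$sys_crc, qm_level(), dielectric_model(40))
  expect_match(deck, "B97D", fixed = TRUE)
  expect_match(deck, "6-311+G(d,p)", fixed = TRUE)
  expect_match(deck, "CPCM", fixed = TRUE)
  expect_match(deck, "eps=40.0", fixed = TRUE)
  expect_identical(deck, write_qm_deck(q$sys_crc, qm_level(), dielectric_model(40)))

  # charged fragment: an ASP-only system carries charge -1
  asp_key <- m$residues$key[m$residues$resid == "ASP"]
  if (length(asp_key) > 0) {
    asp <- mfccr:::residue_atoms(m, asp_key[1])
    deck_asp <- write_qm_deck(asp, qm_level(), dielectric_model(40))
    expect_match(deck_asp, "\n-1 1\n", fixed = TRUE)
  }

  # non-integer total charge is an error
  frak <- mfccr:::residue_atoms(m, m$residues$key[1])
  frak$charge <- frak$charge + 0.1
  expect_error(write_qm_deck(frak), "not an integer")
})

test_that("quadruple decks respect the cap-identity invariants", {
  m <- fixture_toy()$model
  q <- cleave_and_cap(m, m$residues$key[3])
  d <- withr::local_tempdir()
  paths <- write_quadruple_decks(q, d, qm_level(), dielectric_model(40))
  expect_length(paths, 4)
  coord_lines <- function(p) {
    l <- readLines(p)
    grep("^ [A-Z]", l, value = TRUE)
  }
  crc <- coord_lines(paths["sys_crc"])
  l_crc <- coord_lines(paths["sys_l_crc"])
  # receptor-side block of the L system equals the receptor-only system
  expect_identical(tail(l_crc, length(crc)), crc)
  cc <- coord_lines(paths["sys_cc"])
  l_cc <- coord_lines(paths["sys_l_cc"])
  expect_identical(tail(l_cc, length(cc)), cc)
  # ligand block identical between the two L decks
  n_lig <- length(l_crc) - length(crc)
  expect_identical(l_crc[seq_len(n_lig)], l_cc[seq_len(n_lig)])
})

test_that("SCF energies are parsed with exact unit conversion", {
  expect_equal(parse_qm_energy("SCF Done: -1.000000"), -627.5095,
               tolerance = 1e-9)
  out <- c(" SCF Done:  E(RB97D) =  -948.12345678     A.U. after   12 cycles",
           " more output",
           " SCF Done:  E(RB97D) =  -948.12400000     A.U. after    3 cycles")
  expect_equal(parse_qm_energy(out), -948.124 * 627.5095, tolerance = 1e-6)
  expect_error(parse_qm_energy("no energy here"), "no SCF energy")
  expect_error(parse_qm_energy(c("SCF Done: -1.0", "Convergence failure")),
               "converge")
})

test_that("the energy cache round-trips and deduplicates", {
  d <- withr::local_tempdir()
  p <- file.path(d, "cache.csv")
  df <- data.frame(complex = "toy", residue = c("A:1", "A:2"),
                   system = "sys_crc", epsilon = 40,
                   energy_kcal = c(-1.5, 2.5))
  write_energy_cache(df, p)
  df2 <- data.frame(complex = "toy", residue = "A:1", system = "sys_crc",
                    epsilon = 40, energy_kcal = -9)
  write_energy_cache(df2, p)
  got <- read_energy_cache(p)
  expect_equal(nrow(got), 2)
  expect_equal(got$energy_kcal[got$residue == "A:1"], -9)
})
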