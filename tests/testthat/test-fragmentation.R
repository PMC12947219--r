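# peptide cleavage, conjugate caps and link hydrogens

test_that("link hydrogens are placed colinearly at element-specific lengths", {
  sch <- cap_scheme()
  kept_n <- data.frame(x = 0, y = 0, z = 0, elem = "N")
  gone_c <- data.frame(x = 1.33, y = 0, z = 0, elem = "C")
  h <- place_link_hydrogen(kept_n, gone_c, sch)
  expect_equal(c(h$x, h$y, h$z), c(1.01, 0, 0), tolerance = 1e-12)

  kept_c <- data.frame(x = 0, y = 0, z = 0, elem = "C")
  gone_n <- data.frame(x = 0, y = 1.33, z = 0, elem = "N")
  h <- place_link_hydrogen(kept_c, gone_n, sch)
  expect_equal(c(h$x, h$y, h$z), c(0, 1.09, 0), tolerance = 1e-12)

  # arbitrary orientations: length and direction from direct vector arithmetic
  set.seed(4)
  for (i in 1:20) {
    p <- runif(3, -5, 5); q <- runif(3, -5, 5)
    kept <- data.frame(x = p[1], y = p[2], z = p[3], elem = sample(c("N", "C", "S"), 1))
    gone <- data.frame(x = q[1], y = q[2], z = q[3], elem = "C")
    len <- switch(kept$elem, N = 1.01, C = 1.09, S = 1.34)
    h <- place_link_hydrogen(kept, gone, sch)
    hv <- c(h$x, h$y, h$z) - p
    expect_equal(sqrt(sum(hv^2)), len, tolerance = 1e-9)
    expect_equal(hv / sqrt(sum(hv^2)), (q - p) / sqrt(sum((q - p)^2)),
                 tolerance = 1e-9)
  }
  expect_error(place_link_hydrogen(kept_n, data.frame(x = 0, y = 0, z = 0, elem = "C"), sch),
               "coincident")
})

test_that("interior residues get two caps and terminal residues one", {
  m <- fixture_toy()$model
  n <- nrow(m$residues)
  q_mid <- cleave_and_cap(m, m$residues$key[3])
  # caps-only system replaces the removed residue by exactly two link H
  expect_equal(q_mid$sys_cc$n_link, q_mid$sys_crc$n_link + 2)
  # interior residue of a 6-chain: caps cut at both distal peptide bonds
  expect_equal(q_mid$sys_crc$n_link, 2)

  q_nt <- cleave_and_cap(m, m$residues$key[1])
  cap_keys <- unique(q_nt$sys_cc$atoms$residue_key[q_nt$sys_cc$atoms$id > 0])
  expect_identical(cap_keys, m$residues$key[2])     # only the C-side cap
  expect_equal(q_nt$sys_cc$n_link, q_nt$sys_crc$n_link + 1)

  expect_error(cleave_and_cap(m, "AMX"), "ligand")
})

test_that("cap atoms are identical across paired systems and ligand atoms across L systems", {
  m <- fixture_toy()$model
  for (k in m$residues$key[2:4]) {
    q <- cleave_and_cap(m, k)
    # receptor-side rows of sys_l_crc == sys_crc, bit-exact
    lcrc <- q$sys_l_crc$atoms[!q$sys_l_crc$atoms$is_ligand, ]
    rownames(lcrc) <- NULL
    expect_identical(lcrc, q$sys_crc$atoms)
    lcc <- q$sys_l_cc$atoms[!q$sys_l_cc$atoms$is_ligand, ]
    rownames(lcc) <- NULL
    expect_identical(lcc, q$sys_cc$atoms)
    # ligand rows identical between the two L systems
    expect_identical(q$sys_l_crc$atoms[q$sys_l_crc$atoms$is_ligand, ],
                     q$sys_l_cc$atoms[q$sys_l_cc$atoms$is_ligand, ])
    # every cut bond terminated by exactly one link hydrogen
    expect_equal(sum(q$sys_crc$atoms$id < 0), q$sys_crc$n_link)
    expect_equal(sum(q$sys_cc$atoms$id < 0), q$sys_cc$n_link)
  }
})

test_that("fragmenting every residue partitions the receptor atom set", {
  m <- fixture_toy()$model
  quads <- fragment_all(m)
  expect_length(quads, nrow(m$residues))
  ri_ids <- unlist(lapply(names(quads), function(k) {
    mfccr:::residue_atoms(m, k)$id
  }))
  expect_equal(sort(ri_ids), sort(m$atoms$id[!m$atoms$is_ligand]))
  expect_false(anyDuplicated(ri_ids) > 0)
})

test_that("an isolated residue yields empty caps with a warning", {
  tmpl <- mfccr:::.residue_template("ALA")
  atoms <- data.frame(id = seq_len(nrow(tmpl) + 1),
                      name = c(tmpl$atom, "C2"), elem = c(tmpl$elem, "C"),
                      resid = c(rep("ALA", nrow(tmpl)), "LIG"),
                      chain = c(rep("A", nrow(tmpl)), "L"),
                      resno = 1L,
                      x = c(tmpl$x, 8), y = c(tmpl$y, 0), z = c(tmpl$z, 0),
                      charge = 0, epsilon = 0, rmin_half = 1,
                      is_ligand = c(rep(FALSE, nrow(tmpl)), TRUE),
                      stringsAsFactors = FALSE)
  m <- mfccr:::.make_model(atoms, ligand_code = "LIG")
  expect_warning(q <- cleave_and_cap(m, m$residues$key[1]), "no neighbours")
  expect_equal(nrow(q$sys_cc$atoms), 0)
  expect_equal(q$sys_crc$n_link, 0)
})

test_that("disulfides are cut and SG capped at the S-H bond length", {
  # two CYS residues placed so their SG atoms sit 2.05 A apart
  t1 <- mfccr:::.residue_template("CYS")
  t2 <- mfccr:::.residue_template("CYS")
  sg1 <- unlist(t1[t1$atom == "SG", c("x", "y", "z")])
  sg2 <- unlist(t2[t2$atom == "SG", c("x", "y", "z")])
  # mirror the second residue in z and translate so SGs face each other
  t2$z <- -t2$z
  shift <- sg1 + c(0, 0, -2.05) - (sg2 * c(1, 1, -1))
  t2$x <- t2$x + shift[1]; t2$y <- t2$y + shift[2]; t2$z <- t2$z + shift[3]
  lig <- data.frame(atom = "C9", elem = "C", x = 10, y = 10, z = 0)
  blocks <- list(t1, t2, lig)
  resno <- c(1L, 5L, 1L)   # non-consecutive: no peptide bond between them
  resid <- c("CYS", "CYS", "LIG")
  chain <- c("A", "A", "L")
  atoms <- do.call(rbind, lapply(1:3, function(i) {
    b <- blocks[[i]]
    data.frame(name = b$atom, elem = b$elem, resid = resid[i],
               chain = chain[i], resno = resno[i], x = b$x, y = b$y, z = b$z,
               is_ligand = i == 3, stringsAsFactors = FALSE)
  }))
  atoms <- cbind(id = seq_len(nrow(atoms)), atoms)
  atoms$charge <- 0; atoms$epsilon <- 0; atoms$rmin_half <- 1
  m <- mfccr:::.make_model(atoms, ligand_code = "LIG")

  # the bridge is part of the topology
  sg_ids <- m$atoms$id[m$atoms$name == "SG"]
  expect_true(any(apply(m$bonds, 1, function(b) all(sort(b) == sort(sg_ids)))))

  q <- suppressWarnings(cleave_and_cap(m, "A:1", cap_scheme(cut_disulfides = TRUE)))
  lh <- q$sys_crc$atoms[q$sys_crc$atoms$id < 0, ]
  expect_equal(nrow(lh), 1)
  sg <- q$sys_crc$atoms[q$sys_crc$atoms$name == "SG" &
                          q$sys_crc$atoms$id > 0, ]
  d <- sqrt((lh$x - sg$x)^2 + (lh$y - sg$y)^2 + (lh$z - sg$z)^2)
  expect_equal(d, 1.34, tolerance = 1e-9)

  expect_error(suppressWarnings(
    cleave_and_cap(m, "A:1", cap_scheme(cut_disulfides = FALSE))),
    "disulfide")
})

test_that("backbone-only caps restrict cap atoms to the backbone", {
  m <- fixture_toy()$model
  q <- cleave_and_cap(m, m$residues$key[3],
                      cap_scheme(cap_extent = "backbone_only"))
  cap_at <- q$sys_cc$atoms[q$sys_cc$atoms$id > 0, ]
  expect_true(all(cap_at$name %in% mfccr:::.BACKBONE_NAMES))
  # side chains removed: one extra cut (CA-CB) per non-GLY cap
  n_cb_cuts <- sum(m$residues$resid[c(2, 4)] != "GLY")
  expect_equal(q$sys_cc$n_link, 2 + 2 + n_cb_cuts)
})
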