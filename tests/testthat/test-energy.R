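# Interaction centers and the class-pair contact potential.

test_that("interaction centers follow the CB / Gly-CA / reconstruction rule", {
  gseq <- strsplit(strrep("A", 20), "")[[1]]
  gseq[4] <- "G"
  toy <- make_toy_complex(fixture_spec(
    groove_len = 20, pep_len = 9,
    groove_seq = paste(gseq, collapse = ""),
    contact_plan = data.frame(groove_pos = 5, pep_pos = 3, dist = 3.0)))
  tpl <- preprocess_template(toy$model, "A", "C", groove_span = 20)
  ctr <- interaction_centers(tpl)

  hv <- role_atoms(tpl, "heavy")
  ca4 <- unlist(hv[hv$seq_id == 4 & hv$elety == "CA", c("x", "y", "z")])
  expect_equal(unname(ctr$groove["4", ]), unname(ca4))  # Gly -> CA
  cb7 <- unlist(hv[hv$seq_id == 7 & hv$elety == "CB", c("x", "y", "z")])
  expect_equal(unname(ctr$groove["7", ]), unname(cb7))  # CB kept
})

test_that("a missing CB is reconstructed at the ideal tetrahedral position", {
  # frozen oracle: CB solved numerically from |CB-CA| = 1.53 and both
  # N-CA-CB and C-CA-CB angles = 110.5 deg with L-chirality, for the
  # backbone N = (-0.572, 1.337, 0), CA = origin, C = (1.517, 0, 0)
  oracle <- c(-0.535817, -0.812029, 1.180851)
  got <- chimeraMHC:::.reconstruct_cb(c(-0.572, 1.337, 0), c(0, 0, 0),
                                      c(1.517, 0, 0))
  expect_equal(got, oracle, tolerance = 1e-5)

  # deleting a fixture CB: the reconstruction lands near the backbone,
  # not at the pseudo side chain, and centers stay finite
  toy <- make_toy_complex(planted_spec())
  tpl <- preprocess_template(toy$model, "A", "C", groove_span = 20)
  tpl2 <- tpl
  tpl2$atoms <- tpl2$atoms[!(tpl2$atoms$role == "heavy" &
                             tpl2$atoms$seq_id == 2 &
                             tpl2$atoms$elety == "CB"), ]
  ctr <- interaction_centers(tpl2)
  ca2 <- unlist(role_atoms(tpl, "heavy")[
    role_atoms(tpl, "heavy")$seq_id == 2 &
    role_atoms(tpl, "heavy")$elety == "CA", c("x", "y", "z")])
  expect_lt(sqrt(sum((ctr$groove["2", ] - ca2)^2)), 1.6)

  tpl3 <- tpl
  tpl3$atoms <- tpl3$atoms[!(tpl3$atoms$role == "heavy" &
                             tpl3$atoms$seq_id == 2 &
                             tpl3$atoms$elety %in% c("CB", "N")), ]
  expect_error(interaction_centers(tpl3), "lacks backbone")
})

test_that("pair energies follow the class matrix, cutoff and clash rules", {
  expect_equal(pair_energy("K", "D", 5.0), -2.0)
  expect_equal(pair_energy("K", "D", 9.0), 0.0)
  expect_equal(pair_energy("L", "L", 2.5), -1.0 + 10.0)
  expect_equal(pair_energy("K", "K", 5.0), 2.0)
  expect_equal(pair_energy("S", "K", 5.0), -0.5)
  expect_equal(pair_energy("A", "K", 5.0), 0.5)
  expect_equal(pair_energy("A", "S", 5.0), 0.0)
  expect_equal(pair_energy("G", "K", 4.0), 0.0)   # special: always 0
  expect_equal(pair_energy("X", "D", 2.0), 0.0)   # nonstandard: always 0
  expect_error(pair_energy("K", "D", -1), "negative")
  # symmetry of the potential
  for (a in c("K", "D", "S", "A", "G")) for (b in c("K", "D", "S", "A", "G")) {
    expect_equal(pair_energy(a, b, 5), pair_energy(b, a, 5))
  }
})

test_that("binding energy is zero when all centers are out of range", {
  toy <- make_toy_complex(fixture_spec(groove_len = 20, pep_len = 9,
                                       pep_seq = "KKKKKKKKK"))
  tpl <- preprocess_template(toy$model, "A", "C", groove_span = 20)
  vm <- thread_and_score(tpl, strrep("D", 20), "KKKKKKKKK")
  expect_equal(vm$E_bind, 0)
})

test_that("a single planted salt-bridge pair scores the matrix value", {
  s <- make_design_scenario()
  # anchor center at 4.46 A from the P9 Lys center: K-D = -2, plus the
  # hydrophobic-charged neighbour term at P8 (+0.5)
  vm <- thread_and_score(s$template, as.character(s$groove_allele),
                         s$pep_seq)
  expect_equal(vm$E_bind, -1.5)
  vm0 <- thread_and_score(s$template, as.character(s$base_allele),
                          s$pep_seq)
  expect_equal(vm0$E_bind, -0.5)
})

test_that("threading matches the brute-force double-loop oracle", {
  s <- make_design_scenario()
  seqs <- list(as.character(s$groove_allele), as.character(s$base_allele),
               strrep("K", 60), strrep("D", 60))
  for (gs in seqs) {
    expect_equal(thread_and_score(s$template, gs, s$pep_seq)$E_bind,
                 brute_force_ebind(s$template, gs, s$pep_seq))
  }
  tpl <- planted_template()
  expect_equal(
    thread_and_score(tpl, strrep("K", 20), strrep("E", 9))$E_bind,
    brute_force_ebind(tpl, strrep("K", 20), strrep("E", 9)))
})

test_that("binding energy is invariant under rigid motion of the complex", {
  s <- make_design_scenario()
  e0 <- thread_and_score(s$template, as.character(s$groove_allele),
                         s$pep_seq)$E_bind
  moved <- transform_model(s$template,
                           rotation_from_angles(0.7, -1.1, 2.2),
                           c(10, -3, 8))
  e1 <- thread_and_score(moved, as.character(s$groove_allele),
                         s$pep_seq)$E_bind
  expect_equal(e1, e0, tolerance = 1e-9)
})

test_that("substitutions outside the contact shell leave E_bind unchanged", {
  s <- make_design_scenario()
  base <- as.character(s$base_allele)
  decoy_on <- strsplit(base, "")[[1]]
  decoy_on[s$truth$decoy_position] <- "I"
  e_base <- thread_and_score(s$template, base, s$pep_seq)$E_bind
  e_decoy <- thread_and_score(s$template, paste(decoy_on, collapse = ""),
                              s$pep_seq)$E_bind
  expect_identical(e_decoy, e_base)
})

test_that("a charge-complementary pocket strictly lowers the binding energy", {
  s <- make_design_scenario()
  base <- strsplit(as.character(s$base_allele), "")[[1]]
  asp <- base; asp[s$truth$anchor_position] <- "D"
  e_ser <- thread_and_score(s$template, paste(base, collapse = ""),
                            s$pep_seq)$E_bind
  e_asp <- thread_and_score(s$template, paste(asp, collapse = ""),
                            s$pep_seq)$E_bind
  expect_lt(e_asp, e_ser)
})

test_that("determinism: identical inputs give bit-identical energies", {
  s <- make_design_scenario()
  v1 <- thread_and_score(s$template, as.character(s$groove_allele), s$pep_seq)
  v2 <- thread_and_score(s$template, as.character(s$groove_allele), s$pep_seq)
  expect_identical(v1$E_bind, v2$E_bind)
  expect_identical(v1$E_total, v2$E_total)
})
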