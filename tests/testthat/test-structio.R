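# Structure reading/writing, template preprocessing, distance and
# superposition primitives.

test_that("a minimal hand-written PDB parses into one chain, one residue", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.000  12.000  13.000  1.00  0.00           C",
    "END"), f)
  m <- read_structure(f)
  expect_s3_class(m, "StructureModel")
  expect_equal(chain_ids(m), "A")
  expect_equal(nrow(m$atoms), 1)
  expect_equal(m$atoms$aa, "A")
  expect_equal(unname(unlist(m$atoms[1, c("x", "y", "z")])), c(11, 12, 13))
})

test_that("write -> read round trip preserves sequence and coordinates", {
  toy <- make_toy_complex(planted_spec())
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy$model, f)
  back <- read_structure(f)
  expect_equal(chain_sequence(back, "A"), chain_sequence(toy$model, "A"))
  expect_equal(chain_sequence(back, "C"), chain_sequence(toy$model, "C"))
  # PDB coordinate fields carry 3 decimals
  expect_equal(back$atoms$x, round(toy$model$atoms$x, 3), tolerance = 1e-9)
  expect_equal(back$atoms$z, round(toy$model$atoms$z, 3), tolerance = 1e-9)
})

test_that("a file holding only waters is rejected as empty", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "HETATM    2  O   HOH A   2       3.000   0.000   0.000  1.00  0.00           O",
    "END"), f)
  expect_error(read_structure(f), "no protein chains")
})

test_that("altloc records resolve to the highest-occupancy atom", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 1)
  expect_equal(m$atoms$x, 9)
})

test_that("preprocessing renumbers the groove from 1 and keeps 2 chains", {
  toy <- make_toy_complex(fixture_spec(
    groove_len = 30, pep_len = 9, extra_chains = TRUE,
    contact_plan = data.frame(groove_pos = 5, pep_pos = 3, dist = 3.0)))
  # emulate author numbering starting at 1001
  m <- toy$model
  m$atoms$seq_id[m$atoms$chain == "A"] <-
    m$atoms$seq_id[m$atoms$chain == "A"] + 1000L
  tpl <- preprocess_template(m, "A", "C", groove_span = 30)
  hv <- role_atoms(tpl, "heavy")
  expect_equal(sort(unique(hv$seq_id)), 1:30)
  expect_equal(length(chain_ids(tpl)), 2)        # light chain + waters gone
  expect_equal(tpl$pep_len, 9)
  pp <- role_atoms(tpl, "peptide")
  expect_equal(sort(unique(pp$seq_id)), 1:9)
})

test_that("preprocessing preserves residue order and coordinates exactly", {
  toy <- make_toy_complex(planted_spec())
  tpl <- preprocess_template(toy$model, "A", "C", groove_span = 20)
  orig <- toy$model$atoms[toy$model$atoms$chain == "A", ]
  new <- role_atoms(tpl, "heavy")
  expect_equal(new$x, orig$x)
  expect_equal(new$aa, orig$aa)
})

test_that("a heavy chain shorter than the groove span is refused", {
  toy <- make_toy_complex(fixture_spec(groove_len = 10, pep_len = 9))
  expect_error(preprocess_template(toy$model, "A", "C", groove_span = 20),
               "cannot truncate")
  expect_error(preprocess_template(toy$model, "A", "Z", groove_span = 10),
               "no chain")
})

test_that("minimum heavy-atom distance follows two-point geometry", {
  res <- data.frame(chain = "A", role = "heavy", seq_id = 1, aa = "A",
                    resid = "ALA", elety = "CA", element = "C",
                    is_h = FALSE, x = 0, y = 0, z = 0, o = 1)
  partner <- res
  partner$x <- c(0); partner$z <- 4
  expect_equal(min_heavy_atom_distance(res, partner), 4.0)

  # minimum over several atoms
  partner2 <- rbind(partner, partner)
  partner2$z <- c(7.8, 3.2)
  expect_equal(min_heavy_atom_distance(res, partner2), 3.2)

  # hydrogens excluded
  withH <- rbind(partner2, partner2[1, ])
  withH$is_h <- c(FALSE, FALSE, TRUE)
  withH$z[3] <- 0.5
  expect_equal(min_heavy_atom_distance(res, withH), 3.2)
  allH <- partner2; allH$is_h <- TRUE
  expect_error(min_heavy_atom_distance(res, allH), "no heavy atoms")
})

test_that("planted fixture distances are recovered to 1e-6", {
  toy <- make_toy_complex(planted_spec(seed = 7))
  tpl <- preprocess_template(toy$model, "A", "C", groove_span = 20)
  pep <- role_atoms(tpl, "peptide")
  for (p in names(toy$truth$pep_min_dist)) {
    d <- min_heavy_atom_distance(
      residue_atoms(tpl, "A", as.integer(p)), pep)
    expect_equal(d, unname(toy$truth$pep_min_dist[p]), tolerance = 1e-6)
  }
})

test_that("superposition gives zero RMSD for identical and rigidly moved copies", {
  tpl <- planted_template()
  expect_equal(superpose_rmsd(tpl, tpl), 0, tolerance = 1e-9)
  mov <- transform_model(tpl, rotation_from_angles(pi / 2, 0.3, -1),
                         c(5, 5, 5))
  expect_equal(superpose_rmsd(tpl, mov), 0, tolerance = 1e-7)
  expect_equal(superpose_rmsd(tpl, mov, rmsd_selection = "all"), 0,
               tolerance = 1e-7)
})

test_that("a single displaced peptide atom gives RMSD sqrt(1/k)", {
  tpl <- planted_template()
  mov <- tpl
  idx <- which(mov$atoms$role == "peptide" & mov$atoms$elety == "CA" &
               mov$atoms$seq_id == 4)
  mov$atoms$z[idx] <- mov$atoms$z[idx] + 1.0
  k <- sum(!tpl$atoms$is_h & tpl$atoms$role == "peptide")
  expect_equal(superpose_rmsd(tpl, mov, rmsd_selection = "peptide_all_heavy"),
               sqrt(1 / k), tolerance = 1e-9)
  kb <- sum(tpl$atoms$role == "peptide" &
            tpl$atoms$elety %in% c("N", "CA", "C", "O"))
  expect_equal(superpose_rmsd(tpl, mov, rmsd_selection = "peptide_backbone"),
               sqrt(1 / kb), tolerance = 1e-9)
})

test_that("superposition RMSD is symmetric and rigid-invariant", {
  tpl <- planted_template()
  mov <- tpl
  pidx <- which(mov$atoms$role == "peptide")
  set.seed(42)
  mov$atoms$x[pidx] <- mov$atoms$x[pidx] + rnorm(length(pidx), 0, 0.3)
  r1 <- superpose_rmsd(tpl, mov)
  r2 <- superpose_rmsd(mov, tpl)
  expect_lt(abs(r1 - r2), 1e-6)
  mov2 <- transform_model(mov, rotation_from_angles(1, 2, 3), c(-4, 0, 9))
  expect_equal(superpose_rmsd(tpl, mov2), r1, tolerance = 1e-6)
})

test_that("mismatched fit selections are reported", {
  tpl <- planted_template()
  mov <- tpl
  mov$atoms <- mov$atoms[!(mov$atoms$role == "heavy" &
                           mov$atoms$seq_id == 2), ]
  expect_error(superpose_rmsd(tpl, mov), "unmatched")
})
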