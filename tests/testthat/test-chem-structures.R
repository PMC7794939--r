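test_that("molecule constructor enforces its invariants", {
  m <- molecule("eth", c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                data.frame(i = 1, j = 2, order = "1"))
  expect_s3_class(m, "molecule")
  expect_equal(n_atoms(m), 2L)

  coords <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  expect_error(molecule("x", c("H", "H"), coords), "heavy atom")
  expect_error(molecule("x", c("C", "C"), coords,
                        data.frame(i = 1, j = 1, order = "1")), "self-bond")
  expect_error(molecule("x", c("C", "C"), coords,
                        data.frame(i = c(1, 2), j = c(2, 1), order = "1")),
               "duplicate")
  expect_error(molecule("x", c("C", "C"), coords,
                        data.frame(i = 1, j = 3, order = "1")), "non-existent")
  expect_error(molecule("x", c("C", "C"), rbind(c(0, 0, 0))), "n x 3")
})

test_that("protein invariants: unique residue keys, one oxygen per water", {
  at <- data.frame(chain = "A", resno = c(1, 1, 2), insert = "",
                   resname = c("ALA", "ALA", "HOH"),
                   name = c("N", "CA", "O"), element = c("N", "C", "O"),
                   x = c(0, 1.5, 8), y = 0, z = 0)
  p <- protein_structure(at)
  expect_equal(sum(is_water(p)), 1L)

  bad <- at; bad$resname[2] <- "GLY"
  expect_error(protein_structure(bad), "duplicate residue key")
  badw <- at; badw$element[3] <- "N"; badw$name[3] <- "N"
  expect_error(protein_structure(badw), "exactly one oxygen")
})

test_that("selectors resolve to exactly one residue/atom or error", {
  cx <- make_reference_complex()
  idx <- resolve_selector(cx$protein, residue_selector("A", 51, "ALA"))
  expect_equal(unique(cx$protein$atoms$resname[idx]), "ALA")
  one <- resolve_selector(cx$protein, residue_selector("A", 51, atom = "N"))
  expect_length(one, 1L)
  expect_error(resolve_selector(cx$protein, residue_selector("A", 999)),
               "matches no residue")
  expect_error(resolve_selector(cx$protein,
                                residue_selector("A", 51, "GLY")), "expected residue")
  expect_error(resolve_selector(cx$protein,
                                residue_selector("A", 51, atom = "XX")), "resolves to 0")
})

test_that("PDB write -> read round trip preserves structure and coordinates", {
  cx <- make_reference_complex()
  f <- tempfile(fileext = ".pdb")
  write_pdb(cx$protein, f, ligand = cx$ligand, ligand_resname = "LIG")
  back <- read_pdb(f, ligand_resname = "LIG")

  expect_equal(nrow(back$protein$atoms), nrow(cx$protein$atoms))
  expect_equal(length(unique(back$protein$atoms$key[is_water(back$protein)])), 1L)
  expect_equal(protein_coords(back$protein), protein_coords(cx$protein),
               tolerance = 1e-3)
  expect_equal(n_atoms(back$ligand), n_atoms(cx$ligand))
  expect_equal(toupper(back$ligand$atoms$element),
               toupper(cx$ligand$atoms$element))
  expect_equal(conformer_coords(back$ligand), conformer_coords(cx$ligand),
               tolerance = 1e-3)
})

test_that("a minimal synthetic PDB parses with waters flagged", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.460   0.000   0.000  1.00  0.00           C",
    "ATOM      3  N   GLY A   2       3.000   1.000   0.000  1.00  0.00           N",
    "ATOM      4  CA  GLY A   2       4.460   1.000   0.000  1.00  0.00           C",
    "HETATM    5  O   HOH A  99       8.000   0.000   0.000  1.00  0.00           O",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  p <- read_pdb(f)
  expect_equal(length(unique(p$atoms$key)), 3L)
  expect_equal(sum(is_water(p)), 1L)
})

test_that("malformed and inconsistent PDB input is rejected with context", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.4x0   0.000   0.000  1.00  0.00           C"), f)
  expect_error(read_pdb(f), "line 2")

  # duplicate residue key with conflicting names
  f2 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  N   GLY A   1       3.000   0.000   0.000  1.00  0.00           N"), f2)
  expect_error(read_pdb(f2), "duplicate residue key")
})

test_that("SDF I/O: record order, multi-record, round trip, strictness", {
  hexa <- cbind(cos(0:5 * pi / 3) * 1.39, sin(0:5 * pi / 3) * 1.39, 0)
  bz <- molecule("benzene", rep("C", 6), hexa,
                 data.frame(i = 1:6, j = c(2:6, 1), order = "ar"))
  co <- molecule("carbonyl", c("C", "O"), rbind(c(0, 0, 0), c(1.23, 0, 0)),
                 data.frame(i = 1, j = 2, order = "2"))
  amm <- molecule("ammonium", "N", matrix(0, 1, 3), charges = 1L)
  f <- tempfile(fileext = ".sdf")
  write_molecules(list(bz, co, amm), f)
  back <- read_molecules(f)

  expect_length(back, 3L)
  expect_equal(vapply(back, `[[`, character(1), "name"),
               c("benzene", "carbonyl", "ammonium"))
  expect_true(same_connectivity(back[[1]], bz))
  expect_true(same_connectivity(back[[2]], co))
  expect_equal(back[[3]]$atoms$charge, 1L)
  expect_equal(conformer_coords(back[[1]]), conformer_coords(bz),
               tolerance = 1e-4)
})

test_that("SMILES input arrives with perceived aromaticity", {
  phe <- smiles_to_molecule("c1ccccc1O", "phenol")
  expect_equal(sum(heavy_atoms(phe)), 7L)
  fc <- feature_counts(phe)
  expect_equal(unname(fc["ARO"]), 1L)
})

test_that("multi-conformer SDF convention merges consecutive same-name records", {
  co <- molecule("c1", c("C", "O"), rbind(c(0, 0, 0), c(1.23, 0, 0)),
                 data.frame(i = 1, j = 2, order = "2"))
  co2 <- set_coords(co, rbind(c(1, 1, 1), c(2.23, 1, 1)))
  f <- tempfile(fileext = ".sdf")
  write_molecules(list(co, co2), f)
  merged <- read_molecules(f, merge_conformers = TRUE)
  expect_length(merged, 1L)
  expect_length(merged[[1]]$conformers, 2L)
})

test_that("trajectory I/O: frame order kept, atom mismatch names the model", {
  cx <- make_reference_complex()
  frames <- lapply(1:10, function(k) {
    base <- rbind(protein_coords(cx$protein), conformer_coords(cx$ligand))
    base + 0.01 * (k - 1)
  })
  tr <- trajectory(cx$protein, cx$ligand, frames)
  f <- tempfile(fileext = ".pdb")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(n_frames(back), 10L)
  # frames must be ordered by MODEL number: the constant per-frame offset
  # survives the round trip
  d1 <- back$frames[[10]][1, 1] - back$frames[[1]][1, 1]
  expect_equal(d1, 0.09, tolerance = 1e-3)

  # drop one atom from MODEL 5
  lines <- readLines(f)
  starts <- grep("^MODEL", lines)
  atom5 <- which(substr(lines, 1, 6) %in% c("ATOM  ", "HETATM"))
  atom5 <- atom5[atom5 > starts[5]][1]
  writeLines(lines[-atom5], f)
  expect_error(read_trajectory(f), "model 5")
})

test_that("pose and trajectory constructors validate their inputs", {
  cx <- make_reference_complex()
  expect_error(pose(cx$ligand, ""), "non-empty")
  expect_error(trajectory(cx$protein, cx$ligand,
                          list(rbind(protein_coords(cx$protein),
                                     conformer_coords(cx$ligand)))),
               "at least 2 frames")
  expect_error(trajectory(cx$protein, cx$ligand,
                          list(matrix(0, 3, 3), matrix(0, 3, 3))), "frame 1")
})
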