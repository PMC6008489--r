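test_that("toy PDB files load with exact coordinates and flags", {
  atoms <- rbind(
    toy_atom("ATOM", "N", resn = "GLY", resno = 1, x = 1.5, y = 2.25, z = -3, el = "N"),
    toy_atom("ATOM", "CA", resn = "GLY", resno = 1, x = 2.5, y = 2.25, z = -3),
    toy_atom("HETATM", "O1", resn = "LIG", resno = 9, x = 0.125, y = 0, z = 4, el = "O")
  )
  m <- read_structure(write_toy_pdb(atoms))
  expect_equal(nrow(m$atoms), 3)
  expect_equal(m$atoms$x, c(1.5, 2.5, 0.125))
  expect_equal(m$atoms$is_hetero, c(FALSE, FALSE, TRUE))
  expect_equal(m$atoms$element, c("N", "C", "O"))
  expect_error(read_structure(tempfile()), class = "fragscreen_input_error")
})

test_that("alternate locations keep the highest occupancy, ties to A", {
  atoms <- rbind(
    toy_atom("ATOM", "CA", alt = "A", resno = 1, x = 0, occ = 0.4),
    toy_atom("ATOM", "CA", alt = "B", resno = 1, x = 5, occ = 0.6),
    toy_atom("ATOM", "CB", alt = "A", resno = 1, x = 1, occ = 0.5,
             resn = "ALA"),
    toy_atom("ATOM", "CB", alt = "B", resno = 1, x = 6, occ = 0.5,
             resn = "ALA")
  )
  atoms$resn <- "ALA"
  m <- read_structure(write_toy_pdb(atoms))
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$x[m$atoms$atom_name == "CA"], 5)  # occupancy wins
  expect_equal(m$atoms$x[m$atoms$atom_name == "CB"], 1)  # tie -> altLoc A
})

test_that("elements are inferred from atom names when the column is blank", {
  atoms <- rbind(
    toy_atom("ATOM", "NZ", resn = "LYS", el = ""),
    toy_atom("ATOM", "1HB", resn = "LYS", x = 1, el = ""),
    toy_atom("HETATM", "CL1", resn = "LIG", x = 2, el = ""),
    toy_atom("HETATM", "C1", resn = "LIG", x = 3, el = "")
  )
  m <- read_structure(write_toy_pdb(atoms))
  expect_equal(m$atoms$element, c("N", "H", "CL", "C"))
})

test_that("distance is a metric on random atom coordinates", {
  expect_equal(measure_distance(list(x = 0, y = 0, z = 0),
                                list(x = 0, y = 0, z = 2.8)), 2.8)
  expect_equal(measure_distance(list(x = 1, y = 2, z = 2),
                                list(x = 0, y = 0, z = 0)), 3)
  set.seed(66)
  for (i in 1:50) {
    a <- list(x = runif(1, -50, 50), y = runif(1, -50, 50), z = runif(1, -50, 50))
    b <- list(x = runif(1, -50, 50), y = runif(1, -50, 50), z = runif(1, -50, 50))
    c_ <- list(x = runif(1, -50, 50), y = runif(1, -50, 50), z = runif(1, -50, 50))
    expect_equal(measure_distance(a, b), measure_distance(b, a))
    expect_equal(measure_distance(a, a), 0)
    expect_lte(measure_distance(a, c_),
               measure_distance(a, b) + measure_distance(b, c_) + 1e-12)
  }
})

test_that("H-bond search equals the brute-force all-pairs oracle", {
  set.seed(808)
  for (rep in 1:10) {
    n_pro <- sample(20:60, 1); n_lig <- sample(3:10, 1)
    pro <- do.call(rbind, lapply(seq_len(n_pro), function(i)
      toy_atom("ATOM", sample(c("N", "O", "CA", "CB"), 1), resn = "GLY",
               resno = i, x = runif(1, 0, 15), y = runif(1, 0, 15),
               z = runif(1, 0, 15),
               el = sample(c("N", "O", "C"), 1))))
    lig <- do.call(rbind, lapply(seq_len(n_lig), function(i)
      toy_atom("HETATM", paste0("X", i), resn = "LIG", resno = 99,
               x = runif(1, 0, 15), y = runif(1, 0, 15), z = runif(1, 0, 15),
               el = sample(c("N", "O", "C"), 1))))
    m <- read_structure(write_toy_pdb(rbind(pro, lig)))
    got <- find_hbonds(m, list(resname = "LIG"), list(hetero = FALSE),
                       max_dist = 3.5)
    want <- brute_hbonds(m, list(resname = "LIG"), list(hetero = FALSE), 3.5)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$distance, want$distance, tolerance = 1e-9)
      expect_equal(got$ligand_atom, want$ligand_atom)
      expect_equal(got$protein_atom, want$protein_atom)
    }
  }
})

test_that("contacts do not depend on atom order in the file", {
  set.seed(99)
  pro <- do.call(rbind, lapply(1:30, function(i)
    toy_atom("ATOM", sample(c("N", "O", "CA"), 1), resn = "ALA", resno = i,
             x = runif(1, 0, 12), y = runif(1, 0, 12), z = runif(1, 0, 12),
             el = sample(c("N", "O", "C"), 1))))
  lig <- do.call(rbind, lapply(1:5, function(i)
    toy_atom("HETATM", paste0("L", i), resn = "LIG", resno = 50,
             x = runif(1, 0, 12), y = runif(1, 0, 12), z = runif(1, 0, 12),
             el = c("N", "O", "C", "N", "O")[i])))
  all_atoms <- rbind(pro, lig)
  m1 <- read_structure(write_toy_pdb(all_atoms))
  m2 <- read_structure(write_toy_pdb(all_atoms[sample(nrow(all_atoms)), ]))
  h1 <- find_hbonds(m1, list(resname = "LIG"), list(hetero = FALSE))
  h2 <- find_hbonds(m2, list(resname = "LIG"), list(hetero = FALSE))
  expect_equal(h1[setdiff(names(h1), "serial")], h2[setdiff(names(h2), "serial")])
})

test_that("hinge fixture shows the canonical hydrogen-bond pattern", {
  m <- read_structure(extdata("synthetic_mps1_site.pdb"))
  hb <- find_hbonds(m, list(resname = "LIG", hetero = TRUE),
                    list(hetero = FALSE))
  expect_equal(nrow(hb), 3)
  # sorted by distance: K553 2.6 < G605 2.7 < E603 2.8
  expect_equal(hb$protein_resno, c(553, 605, 603))
  expect_equal(hb$distance, c(2.6, 2.7, 2.8), tolerance = 1e-9)
  # hinge carbonyl accepts from the ligand NH; G605 amide and K553 NZ donate
  expect_equal(hb$donor, c("protein", "protein", "ligand"))
  # nothing within a tight cutoff
  expect_equal(nrow(find_hbonds(m, list(resname = "LIG", hetero = TRUE),
                                list(hetero = FALSE), max_dist = 1)), 0)
  expect_error(find_hbonds(m, list(resname = "NOPE"), list(hetero = FALSE)),
               class = "fragscreen_input_error")
})

test_that("hydrophobic packing picks out the channel residues", {
  m <- read_structure(extdata("synthetic_mps1_site.pdb"))
  hp <- find_hydrophobic_contacts(m, list(resname = "LIG", hetero = TRUE),
                                  list(hetero = FALSE))
  expect_true(all(c("VAL", "ILE") %in% hp$protein_residue))
  expect_equal(hp$protein_resno[hp$protein_residue == "VAL"], 539)
  expect_equal(hp$protein_resno[hp$protein_residue == "ILE"], 663)
  far <- find_hydrophobic_contacts(m, list(resname = "LIG", hetero = TRUE),
                                   list(hetero = FALSE), max_dist = 0.5)
  expect_equal(nrow(far), 0)
})

test_that("pocket comparison reports gatekeeper and packing differences", {
  mps1 <- read_structure(extdata("synthetic_mps1_site.pdb"))
  aur <- read_structure(extdata("synthetic_aurora_a_pocket.pdb"))
  cmp <- compare_pocket_residues(mps1, aur, c("602" = 210, "663" = 273))
  expect_equal(cmp$residue_a, c("MET", "ILE"))
  expect_equal(cmp$residue_b, c("LEU", "ALA"))
  expect_false(any(cmp$same_amino_acid))
  # identity map on a model vs itself: everything conserved
  self <- compare_pocket_residues(mps1, mps1, c("602" = 602, "553" = 553))
  expect_true(all(self$same_amino_acid))
  # unmapped positions surface as NA, not errors
  miss <- compare_pocket_residues(mps1, aur, c("602" = 9999))
  expect_true(is.na(miss$residue_b) && is.na(miss$same_amino_acid))
})
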