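minimal_pdb <- function() {
  # two residues + one FE het + an altloc pair on residue 1
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB AALA A   1       2.000   1.000   0.000  0.40  0.00           C",
    "ATOM      4  CB BALA A   1       2.000  -1.000   0.000  0.60  0.00           C",
    "ATOM      5  N   GLY A   2       3.000   0.000   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       4.500   0.000   0.000  1.00  0.00           C",
    "HETATM    7 FE    FE A 901       8.000   0.000   0.000  1.00  0.00          FE",
    "END")
}

test_that("PDB reading separates het groups and resolves altlocs", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(minimal_pdb(), f)
  s <- read_pdb(f)
  res <- unique(s$atoms[c("resno", "resid")])
  expect_equal(nrow(res), 2L)
  expect_setequal(res$resid, c("ALA", "GLY"))
  # altloc: only the higher-occupancy CB kept (y = -1)
  cb <- s$atoms[s$atoms$elety == "CB", ]
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$y, -1)
  expect_equal(unique(s$het$resid), "FE")
  expect_error(read_pdb(withr::local_tempfile(fileext = ".pdb")), "not found")
})

test_that("residues_within applies an inclusive cutoff and is monotone", {
  st <- simulate_structure(structure_spec(seed = 40))
  got5 <- residues_within(st$structure, st$site$substrate_atoms, 5)
  got4 <- residues_within(st$structure, st$site$substrate_atoms, 4)
  expect_true(all(got4$resno %in% got5$resno))
  expect_true(all(got5$min_dist <= 5))
  # inclusive boundary
  one <- structure(list(
    atoms = data.frame(type = "ATOM", chain = "A", resno = 1, insert = "",
                       resid = "ALA", elety = "CA", x = 4.9, y = 0, z = 0,
                       o = 1),
    het = data.frame(), path = NA), class = "structure_model")
  expect_equal(nrow(residues_within(one, c(0, 0, 0), 5)), 1L)
  one$atoms$x <- 5.1
  expect_equal(nrow(residues_within(one, c(0, 0, 0), 5)), 0L)
  expect_error(residues_within(one, matrix(numeric(0), 0, 3), 5), "empty")
})

test_that("sidechain orientation compares centroid and CA distances", {
  mk <- function(ca, cb) structure(list(
    atoms = data.frame(type = "ATOM", chain = "A", resno = 1, insert = "",
                       resid = "SER", elety = c("CA", "CB"),
                       x = c(ca[1], cb[1]), y = c(ca[2], cb[2]),
                       z = c(ca[3], cb[3]), o = 1),
    het = data.frame(), path = NA), class = "structure_model")
  center <- c(0, 0, 0)
  expect_true(sidechain_inward(mk(c(8, 0, 0), c(6, 0, 0)), "A", 1, "", center))
  expect_false(sidechain_inward(mk(c(6, 0, 0), c(8, 0, 0)), "A", 1, "", center))
  # glycine: no sidechain heavy atoms -> FALSE with a flag
  gly <- structure(list(
    atoms = data.frame(type = "ATOM", chain = "A", resno = 1, insert = "",
                       resid = "GLY", elety = c("N", "CA", "C", "O"),
                       x = 1:4, y = 0, z = 0, o = 1),
    het = data.frame(), path = NA), class = "structure_model")
  g <- sidechain_inward(gly, "A", 1, "", center)
  expect_false(as.logical(g))
  expect_equal(attr(g, "flag"), "no_sidechain")
})

test_that("contact-residue triage reproduces planted roles", {
  # 3 inward at contact range, 2 outward, 5 far away, no cofactor residues
  st <- simulate_structure(structure_spec(n_contact = 3, n_lining = 2,
                                          n_cofactor = 0, n_background = 5,
                                          seed = 12))
  got <- select_contact_residues(st$structure, st$site)
  expect_equal(sum(got$role == "substrate_contact"), 3L)
  expect_equal(sum(got$role == "pocket_lining_only"), 2L)
  expect_equal(sum(got$role == "none"), 5L)
  # cofactor partition: sidechain 2.2 A from iron
  st2 <- simulate_structure(structure_spec(n_cofactor = 2, seed = 30))
  got2 <- select_contact_residues(st2$structure, st2$site)
  expect_equal(got2$role[match(st2$truth$resno, got2$resno)], st2$truth$role)
  cof <- got2[got2$role == "cofactor_coordinating", ]
  expect_true(all(cof$sc_dist_fe <= 2.6 | cof$sc_dist_og <= 3.5))
  # roles are mutually exclusive and exhaustive over within-cutoff residues
  within <- got2[got2$dist_substrate <= 5, ]
  expect_true(all(within$role != "none"))
  expect_true(all(table(got2$resno) == 1))
})

test_that("triage is invariant under rigid-body motion", {
  st <- simulate_structure(structure_spec(seed = 55))
  base <- select_contact_residues(st$structure, st$site)
  set.seed(9)
  theta <- stats::runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(theta[1]), -sin(theta[1]),
                 0, sin(theta[1]), cos(theta[1])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(theta[3]), -sin(theta[3]), 0,
                 sin(theta[3]), cos(theta[3]), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  R <- Rx %*% Rz
  shift <- c(12, -5, 30)
  tf <- function(m) sweep(m %*% t(R), 2, -shift)
  s2 <- st$structure
  s2$atoms[c("x", "y", "z")] <- tf(as.matrix(s2$atoms[c("x", "y", "z")]))
  s2$het[c("x", "y", "z")] <- tf(as.matrix(s2$het[c("x", "y", "z")]))
  site2 <- ligand_site(s2, "LIG", "FE", "AKG")
  moved <- select_contact_residues(s2, site2)
  expect_equal(moved$role, base$role)
  expect_equal(moved$dist_substrate, base$dist_substrate, tolerance = 1e-9)
  expect_equal(moved$sc_dist_fe, base$sc_dist_fe, tolerance = 1e-9)
})

test_that("column-residue mapping follows ungapped numbering", {
  st <- simulate_structure(structure_spec(n_contact = 2, n_lining = 1,
                                          n_cofactor = 1, sequence = "ACDWKL",
                                          seed = 3))
  fam <- make_family(c(ref = "AC-DWKL", oth = "ACQDWKL"), c("c1", "c2"))
  # ref has a gap at column 3; chain is ACDWKL
  expect_error(map_columns_to_residues(fam, "ref", st$structure, "A"),
               NA)
  cm <- map_columns_to_residues(fam, "ref", st$structure, "A")
  expect_equal(cm$column, c(1L, 2L, 4L, 5L, 6L, 7L))
  expect_equal(cm$resno, 1:6)
  expect_equal(cm$aa, strsplit("ACDWKL", "")[[1]])
  # mismatched chain rejected with the first offending position
  fam2 <- make_family(c(ref = "ACYWKL", oth = "ACQDWK"), c("c1", "c2"))
  expect_error(map_columns_to_residues(fam2, "ref", st$structure, "A"),
               "identity.*position 3")
})

test_that("motif projection labels exactly the covered residues", {
  st <- simulate_structure(structure_spec(n_contact = 3, n_lining = 0,
                                          n_cofactor = 0,
                                          sequence = strrep("A", 20), seed = 6))
  fam <- make_family(c(ref = strrep("A", 20), oth = strrep("A", 20)),
                     c("c1", "c2"))
  cm <- map_columns_to_residues(fam, "ref", st$structure, "A")
  arch <- data.frame(seq_id = "ref", motif_id = "7", start = 10L, end = 17L,
                     bits = 12)
  proj <- project_motifs(arch, cm)
  expect_equal(sum(proj$motif_id == "7", na.rm = TRUE), 8L)
  expect_equal(proj$resno[!is.na(proj$motif_id)], 10:17)
  pocket <- select_contact_residues(st$structure, st$site)
  comp <- pocket_motif_composition(pocket, proj)
  contact_res <- pocket$resno[pocket$role == "substrate_contact"]
  expect_equal(sum(comp), sum(contact_res %in% 10:17))
})
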