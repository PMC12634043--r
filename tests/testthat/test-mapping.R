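demo_aa <- load_forcefield("demo-aa")
demo_cg <- load_forcefield("demo-cg")
demo_maps <- load_mappings()
all_mods <- c(demo_aa$modifications, demo_cg$modifications)

repaired_molecule <- function(fx) {
  sys <- to_system(fx$record, infer_bonds(fx$record, "distance"), demo_aa)
  rr <- repair_molecule(sys$molecules[[1]], demo_aa, warning_ledger())
  rr <- resolve_modifications(rr$molecule, rr$reports, all_mods,
                              warning_ledger())
  rr$molecule
}

test_that("per-residue mappings cover a peptide completely", {
  mol <- repaired_molecule(make_structure("linear_peptide",
                                          sequence = c("GLY", "ALA", "CYS")))
  led <- warning_ledger()
  cover <- build_cover(mol, demo_maps, led, all_mods)
  expect_length(cover$placements, 3L)
  expect_length(cover$uncovered_atoms, 0L)
  expect_length(ledger_blocking(led), 0L)
})

test_that("a cyclic six-unit polyether is covered by the repeat-unit mapping", {
  mol <- repaired_molecule(make_structure("crown_ether", n_res = 6))
  cover <- build_cover(mol, demo_maps, warning_ledger(), all_mods)
  expect_length(cover$placements, 6L)
  expect_true(all(vapply(cover$placements, function(p)
    p$mapping$name == "PEO", logical(1))))
})

test_that("branched polyethylene units are matched by the branched-unit mapping", {
  mol <- repaired_molecule(make_structure("branched_polyethylene"))
  cover <- build_cover(mol, demo_maps, warning_ledger(), all_mods)
  expect_length(cover$placements, 7L)
  used <- vapply(cover$placements, function(p) p$mapping$name, character(1))
  expect_equal(sum(used == "PEB"), 3L)
  expect_equal(sum(used == "PEL"), 4L)
})

test_that("multi-residue mappings are placed before single-residue ones", {
  mol <- repaired_molecule(make_structure("crown_ether", n_res = 6))
  peo2 <- parse_mapping_text(c(
    "[ molecule ]", "PEO2", "[ scope ]", "PEO PEO", "[ martini ]", "EO2",
    "[ atoms ]", "1 1 C1 EO2", "2 1 C2 EO2", "3 1 O1 EO2",
    "4 2 C1 EO2", "5 2 C2 EO2", "6 2 O1 EO2"))[[1]]
  cover <- build_cover(mol, c(demo_maps, list(peo2)), warning_ledger(),
                       all_mods)
  used <- vapply(cover$placements, function(p) p$mapping$name, character(1))
  # the two-unit mapping claims all residues pairwise before the
  # single-unit mapping gets a chance
  expect_equal(used, rep("PEO2", 3L))
})

test_that("residues without a mapping are excluded with a warning", {
  mol <- repaired_molecule(make_structure("linear_peptide",
                                          sequence = c("GLY", "ALA", "GLY")))
  led <- warning_ledger()
  cover <- build_cover(mol, demo_maps[vapply(demo_maps, function(m)
    m$name != "ALA", logical(1))], led, all_mods)
  expect_length(cover$placements, 2L)
  expect_length(ledger_entries(led, "unrecognized-residue"), 1L)
})

square_bead_molecule <- function(drop_positions = integer()) {
  at <- data.frame(atom_name = c("C1", "C2", "C3", "C4"), resname = "SQR",
                   resid = 1L, chain = "A", element = "C",
                   x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = 0)
  for (i in drop_positions) at$x[i] <- at$y[i] <- at$z[i] <- NA_real_
  mol <- molgraph(at, rbind(c(1, 2), c(2, 3), c(3, 4)))
  map <- ff_mapping("SQR", "SQR", "B1", {
    a <- data.frame(residx = 1L, atom_name = at$atom_name)
    a$weights <- lapply(at$atom_name, function(n) c(B1 = 1))
    a
  })
  tff <- forcefield("sq", blocks = list(SQR = ff_block("SQR", molgraph(
    data.frame(atom_name = "B1", resname = "SQR", resid = 1L,
               particle_type = "P1", charge = 0, mass = 48)))))
  list(mol = mol, map = map, tff = tff)
}

test_that("bead positions are the weighted mean of available source atoms", {
  sq <- square_bead_molecule()
  cover <- build_cover(sq$mol, list(sq$map), warning_ledger())
  cg <- map_to_target(sq$mol, cover, sq$tff, warning_ledger())
  expect_equal(c(cg$atoms$x, cg$atoms$y, cg$atoms$z), c(0.5, 0.5, 0))

  # two of four atoms missing: midpoint of the remaining two, plus warning
  led <- warning_ledger()
  sq2 <- square_bead_molecule(drop_positions = c(3, 4))
  cover2 <- build_cover(sq2$mol, list(sq2$map), led)
  cg2 <- map_to_target(sq2$mol, cover2, sq$tff, led)
  expect_equal(c(cg2$atoms$x, cg2$atoms$y), c(0.5, 0))
  expect_match(ledger_entries(led, "missing-coordinates")[[1]]$message,
               "estimated")

  # all atoms missing: coordinate-free bead, warning
  led3 <- warning_ledger()
  sq3 <- square_bead_molecule(drop_positions = 1:4)
  cover3 <- build_cover(sq3$mol, list(sq3$map), led3)
  cg3 <- map_to_target(sq3$mol, cover3, sq$tff, led3)
  expect_true(is.na(cg3$atoms$x))
  expect_match(ledger_entries(led3, "missing-coordinates")[[1]]$message,
               "coordinate-free")
})

test_that("bead positions are equivariant under rigid translation", {
  fx <- make_structure("linear_peptide", n_res = 5)
  mol <- repaired_molecule(fx)
  cover <- build_cover(mol, demo_maps, warning_ledger(), all_mods)
  cg1 <- map_to_target(mol, cover, demo_cg, warning_ledger())
  shift <- c(1.25, -0.5, 3)
  mol2 <- mol
  mol2$atoms$x <- mol2$atoms$x + shift[1]
  mol2$atoms$y <- mol2$atoms$y + shift[2]
  mol2$atoms$z <- mol2$atoms$z + shift[3]
  cg2 <- map_to_target(mol2, build_cover(mol2, demo_maps, warning_ledger(),
                                         all_mods),
                       demo_cg, warning_ledger())
  expect_equal(cg2$atoms$x, cg1$atoms$x + shift[1])
  expect_equal(cg2$atoms$y, cg1$atoms$y + shift[2])
  expect_equal(cg2$atoms$z, cg1$atoms$z + shift[3])
})

test_that("bead count is conserved and edges follow mapped source bonds", {
  fx <- make_structure("two_chain_disulfide")
  mol <- repaired_molecule(fx)
  cover <- build_cover(mol, demo_maps, warning_ledger(), all_mods)
  cg <- map_to_target(mol, cover, demo_cg, warning_ledger())
  want <- sum(vapply(cover$placements, function(p)
    nrow(demo_cg$blocks[[p$mapping$name]]$graph$atoms), integer(1)))
  expect_equal(nrow(cg$atoms), want)
  # the disulfide SG-SG bond maps to an SC1-SC1 bead edge across chains
  sc1 <- which(cg$atoms$atom_name == "SC1")
  expect_length(sc1, 2L)
  hit <- apply(cg$edges, 1, function(e) all(sort(e) == sort(sc1)))
  expect_true(any(hit))
})

test_that("the identity mapping reproduces the input graph", {
  fx <- make_structure("linear_peptide", sequence = c("GLY", "ALA", "GLY"))
  mol <- repaired_molecule(fx)
  idmaps <- identity_mappings(demo_aa)
  cover <- build_cover(mol, idmaps, warning_ledger(), all_mods)
  aa2 <- map_to_target(mol, cover, demo_aa, warning_ledger())
  expect_equal(nrow(aa2$atoms), nrow(mol$atoms) - 0L)
  expect_equal(aa2$atoms$atom_name, mol$atoms$atom_name)
  expect_equal(nrow(aa2$edges), nrow(mol$edges))
  expect_equal(aa2$atoms$x, mol$atoms$x)
  # graphs are isomorphic under name matching
  ms <- subgraph_isomorphisms(aa2, mol, match_by_name, max_matches = 1)
  expect_length(ms, 1L)
})

test_that("virtual sites are constructed from their particles, in dependency order", {
  at <- data.frame(atom_name = c("B1", "B2", "B3", "V1", "V2"),
                   resname = "X", resid = 1L, particle_type = "P1",
                   x = c(0, 1, 0, NA, NA), y = c(0, 0, 1, NA, NA), z = 0)
  at$z[4:5] <- NA_real_
  at$x[4:5] <- NA_real_; at$y[4:5] <- NA_real_
  mol <- molgraph(at, rbind(c(1, 2), c(2, 3)), interactions = list(
    virtual_sitesn = list(
      bonded_interaction("virtual_sitesn", c(5L, 4L), "2"),   # V2 from V1
      bonded_interaction("virtual_sitesn", c(4L, 1L, 2L, 3L), "2"))))
  out <- construct_virtual_sites(mol)
  expect_equal(c(out$atoms$x[4], out$atoms$y[4]), c(1 / 3, 1 / 3))
  # vsite over one particle copies its position; chained site is finite
  expect_equal(c(out$atoms$x[5], out$atoms$y[5]), c(1 / 3, 1 / 3))
  expect_equal(out$atoms$mass[4:5], c(0, 0))
  # coordinate-free constructor propagates with a warning
  at2 <- at
  at2$x[1] <- at2$y[1] <- at2$z[1] <- NA_real_
  led <- warning_ledger()
  mol2 <- molgraph(at2, rbind(c(1, 2)), interactions = list(
    virtual_sitesn = list(bonded_interaction("virtual_sitesn",
                                             c(4L, 1L, 2L), "2"))))
  out2 <- construct_virtual_sites(mol2, led)
  expect_true(is.na(out2$atoms$x[4]))
  expect_length(ledger_entries(led, "missing-coordinates"), 1L)
})
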