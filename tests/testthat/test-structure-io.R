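pdb_line <- function(serial, name, resname, chain, resid, x, y, z,
                     altloc = " ", occ = 1, element = NULL) {
  el <- if (is.null(element)) toupper(substr(name, 1, 1)) else element
  sprintf("ATOM  %5d  %-3s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, altloc, resname, chain, resid, x, y, z, occ, 0, el)
}

test_that("PDB reading parses fixed columns and converts to nm", {
  lines <- c(pdb_line(1, "N", "GLY", "A", 1, 0, 0, 0),
             pdb_line(2, "CA", "GLY", "A", 1, 1.46, 0, 0),
             pdb_line(3, "C", "GLY", "A", 1, 2.98, 0, 0))
  rec <- read_pdb(lines)
  expect_equal(nrow(rec$atoms), 3L)
  expect_equal(rec$atoms$x[2], 0.146)
  expect_equal(nrow(rec$conect), 0L)
  expect_error(read_pdb(c("REMARK nothing")), "no atoms")
  bad <- lines
  bad[2] <- sub("   1.460", "  1.4x60", bad[2])
  expect_error(read_pdb(bad), "line 2")
})

test_that("CONECT records are symmetrized and altlocs resolved by occupancy", {
  lines <- c(pdb_line(1, "C1", "LIG", "A", 1, 0, 0, 0),
             pdb_line(2, "C2", "LIG", "A", 1, 1.5, 0, 0),
             "CONECT    1    2", "CONECT    2    1")
  rec <- read_pdb(lines)
  expect_equal(rec$conect, matrix(c(1L, 2L), ncol = 2))
  # two altlocs, keep the higher occupancy
  lines2 <- c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, altloc = "A", occ = 0.6),
              pdb_line(2, "CA", "ALA", "A", 1, 9, 9, 9, altloc = "B", occ = 0.4))
  rec2 <- read_pdb(lines2)
  expect_equal(nrow(rec2$atoms), 1L)
  expect_equal(rec2$atoms$altloc, "A")
  # occupancy tie: alphabetically first altloc wins
  lines3 <- c(pdb_line(1, "CA", "ALA", "A", 1, 9, 9, 9, altloc = "B", occ = 0.5),
              pdb_line(2, "CA", "ALA", "A", 1, 0, 0, 0, altloc = "A", occ = 0.5))
  expect_equal(read_pdb(lines3)$atoms$altloc, "A")
})

test_that("distance-based inference applies the covalent-radius criterion", {
  two_c <- function(d_nm) {
    structure_record(data.frame(
      atom_name = c("C1", "C2"), resname = "LIG", resid = 1L, chain = "A",
      element = "C", x = c(0, d_nm), y = 0, z = 0))
  }
  # 0.15 nm <= 1.2 * (0.076 + 0.076)
  expect_equal(nrow(infer_bonds(two_c(0.15), "distance")), 1L)
  # 0.30 nm > 0.1824 nm
  expect_equal(nrow(infer_bonds(two_c(0.30), "distance")), 0L)
  rec <- two_c(0.15)
  rec$atoms$x[2] <- NA_real_
  rec$atoms$y[2] <- NA_real_
  rec$atoms$z[2] <- NA_real_
  expect_error(infer_bonds(rec, "distance"), "C2")
})

test_that("conect strategy uses exactly the stated pairs", {
  rec <- structure_record(
    data.frame(atom_name = c("C1", "C2", "C3"), resname = "LIG", resid = 1L,
               chain = "A", element = "C", x = c(0, 5, 9), y = 0, z = 0),
    conect = rbind(c(1, 2), c(2, 3)))
  edges <- infer_bonds(rec, "conect")
  expect_equal(unname(edges), rbind(c(1L, 2L), c(2L, 3L)))
  # auto picks conect when records exist
  expect_identical(infer_bonds(rec, "auto"), edges)
})

test_that("hydrogens are capped at one bond (closest heavy atom)", {
  rec <- structure_record(data.frame(
    atom_name = c("N1", "C1", "H1"), resname = "LIG", resid = 1L, chain = "A",
    element = c("N", "C", "H"),
    x = c(0, 0.14, 0.09), y = c(0, 0, 0.05), z = 0))
  edges <- infer_bonds(rec, "distance")
  h_edges <- edges[edges[, 1] == 3 | edges[, 2] == 3, , drop = FALSE]
  expect_equal(nrow(h_edges), 1L)
})

test_that("name-based and distance-based inference agree on fixture peptides", {
  ff <- load_forcefield("demo-aa")
  for (seed in 1:3) {
    fx <- make_structure("linear_peptide", n_res = 5L + seed, seed = seed)
    expect_identical(infer_bonds(fx$record, "distance"),
                     infer_bonds(fx$record, "names", ff = ff))
  }
})

test_that("distance inference is independent of particle order", {
  fx <- make_structure("linear_peptide", n_res = 5)
  rec <- fx$record
  set.seed(3)
  perm <- sample(nrow(rec$atoms))
  rec2 <- rec
  rec2$atoms <- rec$atoms[perm, ]
  rec2$atoms$serial <- seq_len(nrow(rec2$atoms))
  e1 <- infer_bonds(rec, "distance")
  e2 <- infer_bonds(rec2, "distance")
  # map permuted edges back to original labels
  back <- match(seq_len(nrow(rec$atoms)), perm)
  e2_orig <- cbind(perm[e2[, 1]], perm[e2[, 2]])
  e2_orig <- e2_orig[order(pmin(e2_orig[, 1], e2_orig[, 2]),
                           pmax(e2_orig[, 1], e2_orig[, 2])), ]
  e1s <- cbind(pmin(e1[, 1], e1[, 2]), pmax(e1[, 1], e1[, 2]))
  expect_equal(unname(e1s), unname(cbind(pmin(e2_orig[, 1], e2_orig[, 2]),
                                         pmax(e2_orig[, 1], e2_orig[, 2]))))
})

test_that("bonded chains form one molecule, unbonded cofactors another", {
  fx <- make_structure("two_chain_disulfide")
  edges <- infer_bonds(fx$record, "distance")
  sys <- to_system(fx$record, edges)
  expect_length(sys$molecules, 1L)  # disulfide merges the chains
  # remove the S-S edge: two molecules
  at <- fx$record$atoms
  sg <- which(at$atom_name == "SG")
  keep <- !((edges[, 1] %in% sg) & (edges[, 2] %in% sg))
  sys2 <- to_system(fx$record, edges[keep, ])
  expect_length(sys2$molecules, 2L)
  # an unbonded single-residue ligand is its own molecule
  lig <- data.frame(atom_name = "C1", resname = "LIG", resid = 99L,
                    chain = "L", element = "C", x = 50, y = 50, z = 50,
                    icode = "", serial = max(at$serial) + 1L)
  at2 <- rbind(at[, names(lig)], lig)
  at2$serial <- seq_len(nrow(at2))
  sys3 <- to_system(structure_record(at2),
                    infer_bonds(structure_record(at2), "distance"))
  expect_length(sys3$molecules, 2L)
  # particle count conserved through read -> partition
  expect_equal(sum(vapply(sys3$molecules, function(m) nrow(m$atoms),
                          integer(1))), nrow(at2))
})

test_that("GRO round-trip preserves positions to format precision", {
  fx <- make_structure("linear_peptide", n_res = 4)
  sys <- to_system(fx$record, infer_bonds(fx$record, "distance"))
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(sys, path)
  rec2 <- read_gro(path)
  expect_equal(nrow(rec2$atoms), nrow(fx$record$atoms))
  expect_true(all(abs(rec2$atoms$x - fx$record$atoms$x) <= 5e-4 + 1e-12))
  expect_true(all(abs(rec2$atoms$z - fx$record$atoms$z) <= 5e-4 + 1e-12))
  # box line present and positive
  expect_true(all(attr(rec2, "box")[1:3] > 0))
})

test_that("PDB write/read round-trips names, residues and coordinates", {
  fx <- make_structure("two_chain_disulfide")
  sys <- to_system(fx$record, infer_bonds(fx$record, "distance"))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sys, path)
  rec2 <- read_pdb(path)
  expect_equal(nrow(rec2$atoms), nrow(fx$record$atoms))
  ord <- order(rec2$atoms$chain, rec2$atoms$resid, rec2$atoms$atom_name)
  ord0 <- order(fx$record$atoms$chain, fx$record$atoms$resid,
                fx$record$atoms$atom_name)
  expect_equal(rec2$atoms$atom_name[ord], fx$record$atoms$atom_name[ord0])
  expect_equal(rec2$atoms$x[ord], fx$record$atoms$x[ord0], tolerance = 1e-3)
  # CONECT records reproduce the edge set
  expect_gt(nrow(rec2$conect), 0L)
})

test_that("missing positions are written as a flagged sentinel, never silently", {
  at <- data.frame(atom_name = c("BB", "BB"), resname = "GLY",
                   resid = 1:2, chain = "A", particle_type = "P5",
                   x = c(0, NA), y = c(0, NA), z = c(0, NA))
  mol <- molgraph(at, rbind(c(1, 2)))
  path <- withr::local_tempfile(fileext = ".gro")
  expect_error(write_gro(mol, path), "lack positions")
  led <- warning_ledger()
  write_gro(mol, path, allow_missing = TRUE, ledger = led)
  expect_length(ledger_entries(led, "missing-coordinates"), 1L)
  rec <- read_gro(path)
  expect_equal(rec$atoms$x[2], 0)
})
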