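peptide_system <- function(...) {
  fx <- make_structure(...)
  edges <- infer_bonds(fx$record, "distance")
  list(sys = to_system(fx$record, edges), fx = fx)
}

demo_aa <- load_forcefield("demo-aa")
demo_cg <- load_forcefield("demo-cg")
all_mods <- c(demo_aa$modifications, demo_cg$modifications)

test_that("a misnamed atom is recovered from the element graph", {
  ps <- peptide_system("linear_peptide", sequence = c("GLY", "ALA", "GLY"))
  mol <- ps$sys$molecules[[1]]
  i <- which(mol$atoms$atom_name == "CA" & mol$atoms$resid == 2L)
  mol$atoms$atom_name[i] <- "CA1"
  led <- warning_ledger()
  rr <- repair_molecule(mol, demo_aa, led)
  expect_equal(rr$molecule$atoms$atom_name[i], "CA")
  rep2 <- rr$reports[["A|2|"]]
  expect_equal(rep2$renamed$old, "CA1")
  expect_length(rep2$missing, 0L)
  expect_length(rep2$extra, 0L)
  # renames are informational, not blocking
  expect_length(ledger_blocking(led), 0L)
  expect_length(ledger_entries(led, level = "info"), 1L)
})

test_that("an unexpected C-beta on glycine is flagged, a missing one added", {
  ps <- peptide_system("linear_peptide", sequence = c("ALA", "GLY", "ALA"),
                       corruption = "add_atom")
  led <- warning_ledger()
  rr <- repair_molecule(ps$sys$molecules[[1]], demo_aa, led)
  rep2 <- rr$reports[["A|2|"]]
  expect_length(rep2$extra, 1L)
  rr2 <- resolve_modifications(rr$molecule, rr$reports, all_mods, led)
  expect_length(ledger_entries(led, "unexpected-atoms"), 1L)

  # missing C-beta: coordinate-free node added, warning recorded
  ps3 <- peptide_system("linear_peptide", sequence = c("GLY", "ALA", "GLY"))
  mol3 <- ps3$sys$molecules[[1]]
  cb <- which(mol3$atoms$atom_name == "CB")
  mol3 <- subset_molgraph(mol3, setdiff(seq_len(nrow(mol3$atoms)), cb))
  led3 <- warning_ledger()
  rr3 <- repair_molecule(mol3, demo_aa, led3)
  expect_length(ledger_entries(led3, "missing-atoms"), 1L)
  added <- which(rr3$molecule$atoms$atom_name == "CB")
  expect_length(added, 1L)
  expect_true(is.na(rr3$molecule$atoms$x[added]))
  # the added node is bonded as the block prescribes (to CA)
  adj <- rr3$molecule$edges
  nb <- c(adj[adj[, 1] == added, 2], adj[adj[, 2] == added, 1])
  expect_equal(rr3$molecule$atoms$atom_name[nb], "CA")
})

test_that("unrecognized residue names warn and leave the residue unmodified", {
  at <- data.frame(atom_name = c("Q1", "Q2"), resname = "WAT", resid = 1L,
                   chain = "A", element = c("O", "H"),
                   x = c(0, 0.1), y = 0, z = 0)
  led <- warning_ledger()
  rr <- repair_molecule(molgraph(at, rbind(c(1, 2))), demo_aa, led)
  expect_length(ledger_entries(led, "unrecognized-residue"), 1L)
  expect_equal(rr$molecule$atoms$atom_name, c("Q1", "Q2"))
})

test_that("an extra ring proton resolves to the protonated-histidine modification", {
  rec <- make_structure("linear_peptide",
                        sequence = c("ALA", "HSP", "GLY"))$record
  rec$atoms$resname[rec$atoms$resname == "HSP"] <- "HIS"  # route (b)
  sys <- to_system(rec, infer_bonds(rec, "distance"))
  led <- warning_ledger()
  rr <- repair_molecule(sys$molecules[[1]], demo_aa, led)
  rr <- resolve_modifications(rr$molecule, rr$reports, all_mods, led)
  expect_equal(rr$reports[["A|2|"]]$applied_modifications, "HIS-protonated")
  expect_length(ledger_blocking(led), 0L)
})

test_that("a phosphate on tyrosine resolves to the phospho modification", {
  rec <- make_structure("linear_peptide",
                        sequence = c("GLY", "PTR", "ALA"))$record
  rec$atoms$resname[rec$atoms$resname == "PTR"] <- "TYR"
  sys <- to_system(rec, infer_bonds(rec, "distance"))
  led <- warning_ledger()
  rr <- repair_molecule(sys$molecules[[1]], demo_aa, led)
  rr <- resolve_modifications(rr$molecule, rr$reports, all_mods, led)
  expect_equal(rr$reports[["A|2|"]]$applied_modifications, "TYR-phospho")
  # a clean residue resolves to the empty set
  expect_length(rr$reports[["A|1|"]]$applied_modifications, 0L)
})

test_that("protonation-state residue names resolve through the alias table", {
  rec <- make_structure("linear_peptide",
                        sequence = c("ALA", "HSP", "GLY"))$record
  sys <- to_system(rec, infer_bonds(rec, "distance"))
  rr <- repair_molecule(sys$molecules[[1]], demo_aa, warning_ledger())
  expect_equal(rr$reports[["A|2|"]]$applied_modifications, "HIS-protonated")
  expect_equal(unique(rr$molecule$atoms$resname[rr$molecule$atoms$resid == 2L]),
               "HIS")
})

test_that("termini are assigned at chain ends only", {
  ps <- peptide_system("linear_peptide", sequence = c("GLY", "ALA", "GLY"))
  mol <- assign_termini(ps$sys$molecules[[1]], demo_aa)
  expect_equal(mol$residue_mods[["A|1|"]], "N-ter")
  expect_equal(mol$residue_mods[["A|3|"]], "C-ter")
  expect_null(mol$residue_mods[["A|2|"]])

  cyc <- peptide_system("cyclic_peptide", n_res = 6)
  molc <- assign_termini(cyc$sys$molecules[[1]], demo_aa)
  expect_length(molc$residue_mods, 0L)

  single <- peptide_system("linear_peptide", sequence = "ALA")
  mols <- assign_termini(single$sys$molecules[[1]], demo_aa)
  expect_setequal(mols$residue_mods[["A|1|"]], c("N-ter", "C-ter"))
})

test_that("secondary-structure annotation propagates one letter per residue", {
  ps <- peptide_system("linear_peptide", sequence = c("GLY", "ALA", "GLY"))
  mol <- annotate_secondary_structure(ps$sys$molecules[[1]], "HHC", demo_aa)
  expect_equal(unique(mol$atoms$secstruct[mol$atoms$resid == 1L]), "H")
  expect_equal(unique(mol$atoms$secstruct[mol$atoms$resid == 3L]), "C")
  expect_error(annotate_secondary_structure(ps$sys$molecules[[1]], "HH"),
               "does not match residue count")
  # auto works on complete backbones, fails on missing backbone coordinates
  mol2 <- annotate_secondary_structure(ps$sys$molecules[[1]], "auto", demo_aa)
  expect_equal(unique(mol2$atoms$secstruct), "C")
  mol3 <- ps$sys$molecules[[1]]
  ca <- which(mol3$atoms$atom_name == "CA")[1]
  mol3$atoms$x[ca] <- mol3$atoms$y[ca] <- mol3$atoms$z[ca] <- NA_real_
  expect_error(annotate_secondary_structure(mol3, "auto", demo_aa),
               "cannot assign secondary structure")
})

test_that("repair is idempotent", {
  ps <- peptide_system("linear_peptide", n_res = 5,
                       corruption = "rename_atoms", seed = 9)
  rr1 <- repair_molecule(ps$sys$molecules[[1]], demo_aa, warning_ledger())
  rr2 <- repair_molecule(rr1$molecule, demo_aa, warning_ledger())
  expect_equal(rr2$molecule$atoms, rr1$molecule$atoms)
  expect_equal(nrow(rr2$molecule$edges), nrow(rr1$molecule$edges))
  for (rep2 in rr2$reports) expect_equal(nrow(rep2$renamed), 0L)
})

test_that("random renaming (elements preserved) is recovered exactly", {
  for (seed in 1:6) {
    ps <- peptide_system("linear_peptide", n_res = 6,
                         corruption = "rename_atoms", seed = seed)
    mol0 <- peptide_system("linear_peptide", n_res = 6, seed = seed)$sys$molecules[[1]]
    led <- warning_ledger()
    rr <- repair_molecule(ps$sys$molecules[[1]], demo_aa, led)
    expect_length(ledger_blocking(led), 0L)
    expect_equal(sort(paste(rr$molecule$atoms$resid,
                            rr$molecule$atoms$atom_name)),
                 sort(paste(mol0$atoms$resid, mol0$atoms$atom_name)))
  }
})

test_that("atom count after repair equals canonical count plus modification atoms", {
  rec <- make_structure("linear_peptide",
                        sequence = c("ALA", "HSP", "GLY"))$record
  rec$atoms$resname[rec$atoms$resname == "HSP"] <- "HIS"
  sys <- to_system(rec, infer_bonds(rec, "distance"))
  rr <- repair_molecule(sys$molecules[[1]], demo_aa, warning_ledger())
  rr <- resolve_modifications(rr$molecule, rr$reports, all_mods,
                              warning_ledger())
  is_h <- function(at) !is.na(at$element) & toupper(at$element) == "H"
  canonical <- sum(vapply(c("ALA", "HIS", "GLY"), function(b)
    sum(!is_h(demo_aa$blocks[[b]]$graph$atoms)), numeric(1)))
  n_mod_added <- 1L  # HD1 of the protonation modification (hydrogen)
  heavy_now <- sum(!is_h(rr$molecule$atoms))
  hydro_now <- sum(is_h(rr$molecule$atoms))
  expect_equal(heavy_now, canonical)
  expect_equal(hydro_now, 1L + n_mod_added)  # HE2 + HD1
})
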