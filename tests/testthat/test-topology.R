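demo_cg <- load_forcefield("demo-cg")

cg_backbone <- function(n, secstruct = NA_character_) {
  mol <- linear_cg_chain(n)
  mol$atoms$secstruct <- secstruct
  mol$forcefield <- "demo-cg"
  mol
}

test_that("backbone links add a bond per edge and an angle per bonded triple", {
  mol <- apply_links(cg_backbone(4), demo_cg$links)
  expect_length(mol$interactions$bonds, 3L)
  expect_length(mol$interactions$angles, 2L)
  # a link whose secstruct matcher finds nothing adds nothing
  coil <- apply_links(cg_backbone(4, secstruct = "C"), demo_cg$links)
  helix_params <- vapply(coil$interactions$angles, function(ia)
    ia$parameters[2], character(1))
  expect_true(all(helix_params == "127"))
  # on a helix the later (helical) link overrides the generic angle
  helix <- apply_links(cg_backbone(4, secstruct = "H"), demo_cg$links)
  expect_length(helix$interactions$angles, 2L)
  expect_true(all(vapply(helix$interactions$angles, function(ia)
    ia$parameters[2], character(1)) == "96"))
})

test_that("the disulfide link joins cysteine side-chain beads across chains", {
  at <- data.frame(
    atom_name = c("BB", "SC1", "BB", "SC1"),
    resname = "CYS", resid = c(1L, 1L, 5L, 5L),
    chain = c("A", "A", "B", "B"), particle_type = c("P5", "C5", "P5", "C5"),
    x = c(0, 0.3, 0.9, 0.6), y = 0, z = 0)
  mol <- molgraph(at, rbind(c(1, 2), c(3, 4), c(2, 4)))
  out <- apply_links(mol, demo_cg$links)
  ss <- Filter(function(ia) identical(ia$particles, c(2L, 4L)) ||
                 identical(ia$particles, c(4L, 2L)), out$interactions$bonds)
  expect_length(ss, 1L)
  expect_equal(ss[[1]]$parameters, c("1", "0.240", "5000"))
})

test_that("link application is independent of particle input order", {
  mol <- cg_backbone(5)
  out1 <- apply_links(mol, demo_cg$links)
  perm <- c(3L, 5L, 1L, 4L, 2L)   # relabel particles
  at2 <- mol$atoms[perm, ]
  e2 <- matrix(match(mol$edges, perm), ncol = 2)
  mol2 <- molgraph(at2, e2)
  out2 <- apply_links(mol2, demo_cg$links)
  count <- function(m) vapply(m$interactions, length, integer(1))
  expect_equal(count(out2), count(out1))
  # interactions correspond under the relabelling
  b1 <- lapply(out1$interactions$bonds, function(ia) sort(ia$particles))
  b2 <- lapply(out2$interactions$bonds, function(ia)
    sort(match(ia$particles, perm)))
  expect_setequal(b1, b2)
})

test_that("itp writing is deterministic and minimal molecules serialize", {
  at <- data.frame(atom_name = c("B1", "B2"), resname = "LIG", resid = 1L,
                   particle_type = c("P1", "P2"), charge = c(0, 0.5),
                   mass = c(72, 36))
  mol <- molgraph(at, rbind(c(1, 2)), interactions = list(
    bonds = list(bonded_interaction("bonds", c(1, 2), c("1", "0.33", "1250")))))
  txt <- write_itp(mol, "LIG")
  expect_true(any(grepl("\\[ moleculetype \\]", txt)))
  expect_equal(sum(grepl("^\\s+[0-9]+\\s+P", txt)), 2L)
  expect_identical(write_itp(mol, "LIG"), txt)
  # particles without a type refuse to serialize
  mol2 <- mol
  mol2$atoms$particle_type[2] <- NA_character_
  expect_error(write_itp(mol2, "LIG"), "B2")
})

test_that("itp read/write round-trips sections and parameters verbatim", {
  at <- data.frame(atom_name = c("B1", "B2", "B3", "V1"), resname = "LIG",
                   resid = 1L, particle_type = c("P1", "P2", "P3", "PV"),
                   charge = 0, mass = c(72, 45, 45, 0))
  mol <- molgraph(at, rbind(c(1, 2), c(2, 3)), interactions = list(
    bonds = list(bonded_interaction("bonds", c(1, 2), c("1", "0.33", "1250"))),
    constraints = list(bonded_interaction("constraints", c(2, 3),
                                          c("1", "0.27"))),
    angles = list(bonded_interaction("angles", c(1, 2, 3),
                                     c("2", "127", "20"))),
    exclusions = list(bonded_interaction("exclusions", c(1, 3))),
    virtual_sitesn = list(bonded_interaction("virtual_sitesn",
                                             c(4, 1, 2, 3), "2"))),
    name = "LIG", nrexcl = 1L)
  txt <- write_itp(mol)
  back <- read_itp(txt)
  expect_equal(back$name, "LIG")
  expect_equal(back$atoms$particle_type, at$particle_type)
  expect_equal(back$edges, mol$edges)
  for (kind in names(mol$interactions)) {
    expect_equal(lapply(back$interactions[[kind]], function(ia)
      list(ia$particles, ia$parameters)),
      lapply(mol$interactions[[kind]], function(ia)
        list(ia$particles, ia$parameters)),
      info = kind)
  }
  # second round trip is byte-identical
  expect_identical(write_itp(back), txt)
})

test_that("elastic-network bonds survive the itp round trip without becoming edges", {
  mol <- apply_links(linear_cg_chain(6), demo_cg$links)
  mol$forcefield <- "demo-cg"
  en <- generate_en(mol, en_params(upper_cutoff = 10), ff = demo_cg)
  mol2 <- en_apply(mol, en)
  txt <- write_itp(mol2, "PEP")
  expect_true(any(grepl("; elastic network", txt)))
  back <- read_itp(txt)
  en_bonds <- Filter(function(ia)
    identical(ia$meta$source, "elastic_network"), back$interactions$bonds)
  expect_length(en_bonds, length(en$interactions[[1]]))
  expect_equal(nrow(back$edges), nrow(mol$edges))
})

test_that("itp reading reports out-of-range indices and skipped includes", {
  txt <- c("[ moleculetype ]", "LIG 1", "[ atoms ]",
           "1 P1 1 LIG B1 1 0", "[ bonds ]", "1 7 1 0.3 100")
  expect_error(read_itp(txt), "out of range")
  txt2 <- c("#include \"other.itp\"", "[ moleculetype ]", "LIG 1",
            "[ atoms ]", "1 P1 1 LIG B1 1 0")
  mol <- read_itp(txt2)
  expect_match(attr(mol, "diagnostics"), "other.itp")
  expect_error(read_itp(c("[ bonds ]", "1 2")), "no \\[ atoms \\]")
})

test_that("remove_interactions and attribute edits of links are honoured", {
  lk <- ff_link(
    atoms = {
      a <- data.frame(id = 1:2, offset = c(0L, 1L), atom_name = "BB")
      a$resnames <- list("*", "*"); a$secstruct <- "*"
      a
    },
    edges = rbind(c(1L, 2L)),
    add_interactions = list(),
    remove_interactions = list(list(kind = "bonds", particles = 1:2)),
    edits = list(list(id = 1L, attr = "particle_type", value = "QX")))
  mol <- linear_cg_chain(3)
  mol <- apply_links(mol, demo_cg$links)
  n_before <- length(mol$interactions$bonds)
  out <- apply_links(mol, list(lk))
  expect_equal(length(out$interactions$bonds), n_before - 2L)
  expect_equal(out$atoms$particle_type[1:2], c("QX", "QX"))
})
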