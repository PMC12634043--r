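demo_cg <- load_forcefield("demo-cg")

test_that("the residue graph reflects bonded residue adjacency", {
  pent <- linear_cg_chain(5)
  rg <- residue_graph(pent)
  expect_equal(igraph::vcount(rg$graph), 5L)
  expect_equal(igraph::ecount(rg$graph), 4L)
  expect_equal(igraph::distances(rg$graph)[1, 5], 4)

  # cyclic peptide: a 6-cycle
  fx <- make_structure("cyclic_peptide", n_res = 6)
  r <- run_pipeline(fx$record)
  rgc <- residue_graph(r$cg_system$molecules[[1]])
  expect_equal(igraph::ecount(rgc$graph), 6L)
  expect_equal(max(igraph::distances(rgc$graph)), 3)

  # disulfide bridge makes the bridged residues graph-adjacent
  fx2 <- make_structure("two_chain_disulfide")
  r2 <- run_pipeline(fx2$record)
  m <- r2$cg_system$molecules[[1]]
  rg2 <- residue_graph(m)
  a3 <- which(rg2$res$chain == "A" & rg2$res$resid == 3)
  b2 <- which(rg2$res$chain == "B" & rg2$res$resid == 2)
  expect_equal(igraph::distances(rg2$graph)[a3, b2], 1)
})

test_that("bead selection defaults to the backbone bead and warns when empty", {
  fx <- make_structure("linear_peptide", n_res = 5)
  m <- run_pipeline(fx$record)$cg_system$molecules[[1]]
  sel <- select_beads(m, ff = demo_cg)
  expect_equal(sort(m$atoms$atom_name[sel]), rep("BB", 5))
  wider <- select_beads(m, c("BB", "SC1"))
  expect_true(all(sel %in% wider))
  expect_gt(length(wider), length(sel))
  led <- warning_ledger()
  expect_length(select_beads(m, "NOPE", ledger = led), 0L)
  expect_length(ledger_entries(led, "empty-selection"), 1L)
})

test_that("the residue minimum distance excludes close residues", {
  mol <- linear_cg_chain(12)
  en <- generate_en(mol, en_params(upper_cutoff = 10, lower_cutoff = 0),
                    ff = demo_cg)
  seps <- abs(en$pairs$resid_a - en$pairs$resid_b)
  expect_equal(min(seps), 3L)
  expect_equal(length(en$interactions[[1]]),
               sum(abs(outer(1:12, 1:12, "-")) >= 3) / 2)
  # no pair below the rmd, ever
  expect_true(all(en$pairs$graph_distance >= 3))
})

test_that("EN units restrict bonds to chains, molecules or regions", {
  fx <- make_structure("two_chain_disulfide", n_res = 5, n_res_b = 4)
  r <- run_pipeline(fx$record)
  m <- r$cg_system$molecules[[1]]
  big <- function(unit, regions = NULL)
    generate_en(m, en_params(upper_cutoff = 10, unit = unit,
                             regions = regions), ff = demo_cg)
  by_chain <- big("chain")
  inter_chain <- sum(by_chain$pairs$chain_a != by_chain$pairs$chain_b)
  expect_equal(inter_chain, 0L)
  by_mol <- big("molecule")
  expect_gt(sum(by_mol$pairs$chain_a != by_mol$pairs$chain_b), 0L)
  # chain subset of molecule subset of all
  key <- function(en) paste(en$pairs$chain_a, en$pairs$resid_a,
                            en$pairs$chain_b, en$pairs$resid_b)
  expect_true(all(key(by_chain) %in% key(by_mol)))
  by_all <- big("all")
  expect_true(all(key(by_mol) %in% key(by_all)))

  reg <- big("region", regions = list(c(1, 3)))
  expect_true(all(reg$pairs$resid_a >= 1 & reg$pairs$resid_a <= 3))
  expect_true(all(reg$pairs$resid_b >= 1 & reg$pairs$resid_b <= 3))
})

test_that("a region-limited EN keeps disordered tails free", {
  fx <- make_structure("idr_tail_protein", n_res = 16)
  core <- fx$manifest$core_range
  r <- run_pipeline(fx$record)
  m <- r$cg_system$molecules[[1]]
  en <- generate_en(m, en_params(upper_cutoff = 10, unit = "region",
                                 regions = list(core)), ff = demo_cg)
  expect_gt(nrow(en$pairs), 0L)
  expect_true(all(en$pairs$resid_a >= core[1] & en$pairs$resid_a <= core[2]))
  expect_true(all(en$pairs$resid_b >= core[1] & en$pairs$resid_b <= core[2]))
})

test_that("EN generation equals the O(n^2) triple-filter oracle", {
  set.seed(31)
  for (trial in 1:20) {
    n <- sample(5:40, 1)
    pos <- matrix(stats::runif(3 * n, 0, 2), ncol = 3)
    chain <- sample(c("A", "B"), n, replace = TRUE)
    atoms <- data.frame(atom_name = "BB", resname = "GLY",
                        resid = seq_len(n), chain = chain,
                        x = pos[, 1], y = pos[, 2], z = pos[, 3],
                        particle_type = "P5")
    atoms <- atoms[order(atoms$chain), ]
    atoms$resid <- stats::ave(seq_len(n), atoms$chain, FUN = seq_along)
    edges <- NULL
    for (ch in unique(atoms$chain)) {
      idx <- which(atoms$chain == ch)
      if (length(idx) > 1)
        edges <- rbind(edges, cbind(idx[-length(idx)], idx[-1]))
    }
    mol <- molgraph(atoms, edges)
    unit <- sample(c("molecule", "chain", "region"), 1)
    params <- en_params(upper_cutoff = stats::runif(1, 0.3, 1.5),
                        lower_cutoff = stats::runif(1, 0, 0.2),
                        rmd = sample(0:4, 1), unit = unit,
                        regions = if (unit == "region")
                          list(c(1, 3), c(5, 8)) else NULL)
    en <- generate_en(mol, params, ff = demo_cg)
    got <- if (is.null(en$pairs)) NULL else
      cbind(match(paste(en$pairs$chain_a, en$pairs$resid_a),
                  paste(atoms$chain, atoms$resid)),
            match(paste(en$pairs$chain_b, en$pairs$resid_b),
                  paste(atoms$chain, atoms$resid)))
    rg <- residue_graph(mol)
    res_dist <- igraph::distances(rg$graph)
    # per-particle residue distance (one bead per residue here)
    want <- brute_en_pairs(as.matrix(atoms[, c("x", "y", "z")]),
                           atoms$resid, atoms$chain, res_dist, params)
    norm <- function(m) {
      if (is.null(m)) return(matrix(integer(), ncol = 2))
      m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
      unname(m[order(m[, 1], m[, 2]), , drop = FALSE])
    }
    expect_equal(norm(got), norm(want))
  }
})

test_that("enlarging the cutoff or relaxing the rmd never removes bonds", {
  mol <- linear_cg_chain(10)
  key <- function(en) paste(en$pairs$resid_a, en$pairs$resid_b)
  small <- generate_en(mol, en_params(upper_cutoff = 1.0), ff = demo_cg)
  large <- generate_en(mol, en_params(upper_cutoff = 2.0), ff = demo_cg)
  expect_true(all(key(small) %in% key(large)))
  tight <- generate_en(mol, en_params(upper_cutoff = 2.0, rmd = 5), ff = demo_cg)
  expect_true(all(key(tight) %in% key(large)))
})

test_that("EN generation is pure post-processing", {
  fx <- make_structure("linear_peptide", n_res = 8)
  r <- run_pipeline(fx$record)
  m <- r$cg_system$molecules[[1]]
  en <- generate_en(m, en_params(upper_cutoff = 10), ff = demo_cg)
  m2 <- en_apply(m, en)
  expect_identical(m2$atoms, m$atoms)
  expect_identical(m2$edges, m$edges)
  # bonds carry provenance and harmonic type 6 with the measured length
  ia <- en$interactions[[1]][[1]]
  expect_equal(ia$meta$source, "elastic_network")
  expect_equal(ia$parameters[1], "6")
  d <- as.numeric(ia$parameters[2])
  p <- ia$particles
  expect_equal(d, round(sqrt(sum((m$atoms[p[1], c("x", "y", "z")] -
                                    m$atoms[p[2], c("x", "y", "z")])^2)), 5))
  # a bead without coordinates is skipped with a warning
  m3 <- m
  bb <- which(m3$atoms$atom_name == "BB")[1]
  m3$atoms$x[bb] <- m3$atoms$y[bb] <- m3$atoms$z[bb] <- NA_real_
  led <- warning_ledger()
  en3 <- generate_en(m3, en_params(upper_cutoff = 10), ff = demo_cg,
                     ledger = led)
  expect_length(ledger_entries(led, "missing-coordinates"), 1L)
  expect_false(any(en3$pairs$resid_a == m$atoms$resid[bb] |
                     en3$pairs$resid_b == m$atoms$resid[bb]))
})

test_that("parameter validation rejects inconsistent settings", {
  expect_error(en_params(upper_cutoff = 0.5, lower_cutoff = 0.7), "lower")
  expect_error(en_params(unit = "region"), "range")
  expect_error(en_params(regions = list(c(1, 5))), "region")
})
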