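## Deterministic generators for synthetic structures and corrupted variants.
## Geometry is idealized (standard bond lengths, planar placement) but
## realistic enough that distance-based bond inference reproduces the
## intended molecular graph exactly; the fixtures' claims are topological.
## All generator coordinates are built in Angstrom and converted to nm when
## the structure record is assembled.

# local residue templates: origin at N (or first backbone atom), chain axis
# +x, carbonyl O at +y, side chain towards -y.  Residue spacing 4.31 A.
.PEPTIDE_SPACING <- 4.31

peptide_template <- function(resname) {
  bb <- data.frame(atom_name = c("N", "CA", "C", "O"),
                   element = c("N", "C", "C", "O"),
                   x = c(0, 1.46, 2.98, 2.98), y = c(0, 0, 0, 1.23), z = 0,
                   stringsAsFactors = FALSE)
  side <- switch(resname,
    GLY = NULL,
    ALA = data.frame(atom_name = "CB", element = "C",
                     x = 1.46, y = -1.53, z = 0),
    CYS = data.frame(atom_name = c("CB", "SG"), element = c("C", "S"),
                     x = c(1.46, 1.46), y = c(-1.53, -3.34), z = 0),
    HIS = ,
    HSP = ,
    HISD = local({
      ring_r <- 1.37 / (2 * sin(pi / 5))
      cx <- 1.46; cy <- -3.03 - ring_r
      ang <- c(CG = 90, ND1 = 18, CE1 = -54, NE2 = -126, CD2 = 162) * pi / 180
      ring <- data.frame(
        atom_name = names(ang), element = c("C", "N", "C", "N", "C"),
        x = cx + ring_r * cos(ang), y = cy + ring_r * sin(ang), z = 0,
        stringsAsFactors = FALSE)
      hs <- NULL
      if (resname %in% c("HIS", "HSP")) {
        hs <- rbind(hs, data.frame(
          atom_name = "HE2", element = "H",
          x = cx + (ring_r + 1.01) * cos(ang["NE2"]),
          y = cy + (ring_r + 1.01) * sin(ang["NE2"]), z = 0))
      }
      if (resname %in% c("HISD", "HSP")) {
        hs <- rbind(hs, data.frame(
          atom_name = "HD1", element = "H",
          x = cx + (ring_r + 1.01) * cos(ang["ND1"]),
          y = cy + (ring_r + 1.01) * sin(ang["ND1"]), z = 0))
      }
      rbind(data.frame(atom_name = "CB", element = "C",
                       x = 1.46, y = -1.53, z = 0), ring, hs)
    }),
    TYR = ,
    PTR = local({
      ring_r <- 1.39
      cx <- 1.46; cy <- -3.03 - ring_r
      ang <- c(CG = 90, CD1 = 30, CE1 = -30, CZ = -90, CE2 = 210,
               CD2 = 150) * pi / 180
      ring <- data.frame(
        atom_name = names(ang), element = "C",
        x = cx + ring_r * cos(ang), y = cy + ring_r * sin(ang), z = 0,
        stringsAsFactors = FALSE)
      extra <- data.frame(atom_name = "OH", element = "O",
                          x = cx, y = cy - ring_r - 1.36, z = 0)
      if (resname == "PTR") {
        py <- cy - ring_r - 1.36 - 1.60
        extra <- rbind(extra, data.frame(
          atom_name = c("P", "O1P", "O2P", "O3P"),
          element = c("P", "O", "O", "O"),
          x = cx + c(0, 1.48, -1.48, 0),
          y = c(py, py, py, py - 1.48), z = 0))
      }
      rbind(data.frame(atom_name = "CB", element = "C",
                       x = 1.46, y = -1.53, z = 0), ring, extra)
    }),
    stop("no peptide template for residue '", resname, "'"))
  out <- rbind(bb, side)
  out$resname <- resname
  out
}

.PEO_SPACING <- 4.38
peo_template <- function() {
  data.frame(atom_name = c("C1", "C2", "O1"), element = c("C", "C", "O"),
             x = c(0, 1.52, 2.95), y = 0, z = 0, resname = "PEO",
             stringsAsFactors = FALSE)
}

.PE_SPACING <- 3.06
pe_template <- function(unit) {
  bb <- data.frame(atom_name = c("C1", "C2"), element = "C",
                   x = c(0, 1.53), y = 0, z = 0, stringsAsFactors = FALSE)
  if (unit == "PEB") {
    bb <- rbind(bb, data.frame(atom_name = c("CB1", "CB2"), element = "C",
                               x = 1.53, y = c(1.53, 3.06), z = 0))
  }
  bb$resname <- unit
  bb
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

default_sequence <- function(n) {
  rep(c("ALA", "GLY", "HIS", "ALA", "TYR", "GLY", "CYS", "ALA"),
      length.out = n)
}

assemble_chain <- function(sequence, chain, spacing = .PEPTIDE_SPACING,
                           origin = c(0, 0, 0), mirror_y = FALSE,
                           resid_start = 1L) {
  rows <- list()
  for (i in seq_along(sequence)) {
    tpl <- peptide_template(sequence[i])
    sgn <- if (mirror_y) -1 else 1
    rows[[i]] <- data.frame(
      atom_name = tpl$atom_name, resname = tpl$resname,
      resid = resid_start + i - 1L, chain = chain, element = tpl$element,
      x = origin[1] + (i - 1) * spacing + tpl$x,
      y = origin[2] + sgn * tpl$y, z = origin[3] + tpl$z,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# place a linear chain of local templates onto a circle (arc-length
# parameterization: local x = arc position, local y = radial offset)
wrap_circle <- function(atoms, spacing, n_units) {
  circumference <- spacing * n_units
  R <- circumference / (2 * pi)
  phi <- atoms$x / R
  r <- R + atoms$y
  atoms$x <- r * cos(phi)
  atoms$y <- r * sin(phi)
  atoms
}

#' Generate a synthetic structure and its ground-truth manifest
#'
#' Builds chemically consistent heavy-atom structures (peptides may carry
#' the His ring hydrogens) with idealized geometry whose interatomic
#' distances reproduce the intended bond graph under distance inference.
#' Optionally applies one corruption class; the manifest then records which
#' residues were corrupted, as ground truth for oracle tests.
#'
#' @param kind one of `"linear_peptide"`, `"cyclic_peptide"`,
#'   `"two_chain_disulfide"`, `"crown_ether"`, `"branched_polyethylene"`,
#'   `"idr_tail_protein"`.
#' @param n_res residue count (chain A for the dimer).
#' @param sequence residue-name vector overriding the default pattern.
#' @param n_res_b chain-B residue count (dimer only).
#' @param cys_positions positions of the bridged cysteines in chains A and B.
#' @param units repeat-unit names for `branched_polyethylene`.
#' @param corruption `NULL` or one of `"drop_atoms"`, `"drop_coordinates"`,
#'   `"rename_atoms"`, `"swap_elements"`, `"perturb_distances"`,
#'   `"add_atom"`.
#' @param n_corrupt number of residues to corrupt.
#' @param seed integer seed; identical (spec, seed) give identical output.
#' @return list with `record` (a [structure_record()]) and `manifest`.
#' @export
make_structure <- function(kind = c("linear_peptide", "cyclic_peptide",
                                    "two_chain_disulfide", "crown_ether",
                                    "branched_polyethylene",
                                    "idr_tail_protein"),
                           n_res = 6L, sequence = NULL, n_res_b = 4L,
                           cys_positions = c(3L, 2L),
                           units = c("PEL", "PEL", "PEB", "PEB", "PEB",
                                     "PEL", "PEL"),
                           corruption = NULL, n_corrupt = 1L, seed = 1L) {
  kind <- match.arg(kind)
  manifest <- list(kind = kind, seed = seed, expected_molecules = 1L,
                   disulfides = NULL, cyclic = FALSE,
                   corrupted = data.frame(chain = character(),
                                          resid = integer(),
                                          type = character()))
  if (kind == "linear_peptide") {
    seqn <- sequence %||% default_sequence(n_res)
    atoms <- assemble_chain(seqn, "A")
  } else if (kind == "idr_tail_protein") {
    n_res <- max(n_res, 12L)
    core <- seq(5L, n_res - 4L)
    seqn <- sequence %||% default_sequence(n_res)
    seqn[setdiff(seq_len(n_res), core)] <- "GLY"  # disordered tails
    atoms <- assemble_chain(seqn, "A")
    manifest$core_range <- range(core)
  } else if (kind == "cyclic_peptide") {
    if (n_res < 3L) stop("cyclic peptide needs at least 3 residues")
    seqn <- sequence %||% rep("GLY", n_res)
    atoms <- assemble_chain(seqn, "A")
    local_x <- atoms$x  # arc position; y already signed
    atoms <- wrap_circle(atoms, .PEPTIDE_SPACING, n_res)
    manifest$cyclic <- TRUE
  } else if (kind == "two_chain_disulfide") {
    sa <- sequence %||% rep("ALA", n_res); sa[cys_positions[1L]] <- "CYS"
    sb <- rep("ALA", n_res_b); sb[cys_positions[2L]] <- "CYS"
    a <- assemble_chain(sa, "A")
    b <- assemble_chain(sb, "B",
                        origin = c((cys_positions[1L] - cys_positions[2L]) *
                                     .PEPTIDE_SPACING, -8.73, 0),
                        mirror_y = TRUE)
    atoms <- rbind(a, b)
    manifest$disulfides <- data.frame(chain_a = "A",
                                      resid_a = cys_positions[1L],
                                      chain_b = "B",
                                      resid_b = cys_positions[2L])
  } else if (kind == "crown_ether") {
    if (n_res < 3L) stop("cyclic polyether needs at least 3 repeat units")
    rows <- lapply(seq_len(n_res), function(i) {
      tpl <- peo_template()
      data.frame(atom_name = tpl$atom_name, resname = tpl$resname,
                 resid = i, chain = "X", element = tpl$element,
                 x = (i - 1) * .PEO_SPACING + tpl$x, y = tpl$y, z = tpl$z,
                 stringsAsFactors = FALSE)
    })
    atoms <- wrap_circle(do.call(rbind, rows), .PEO_SPACING, n_res)
    manifest$cyclic <- TRUE
  } else { # branched_polyethylene
    rows <- lapply(seq_along(units), function(i) {
      tpl <- pe_template(units[i])
      data.frame(atom_name = tpl$atom_name, resname = tpl$resname,
                 resid = i, chain = "X", element = tpl$element,
                 x = (i - 1) * .PE_SPACING + tpl$x, y = tpl$y, z = tpl$z,
                 stringsAsFactors = FALSE)
    })
    atoms <- do.call(rbind, rows)
    manifest$n_units <- length(units)
  }
  atoms$x <- atoms$x / 10; atoms$y <- atoms$y / 10; atoms$z <- atoms$z / 10
  rownames(atoms) <- NULL
  manifest$residues <- unique(atoms[, c("chain", "resid", "resname")])
  rownames(manifest$residues) <- NULL
  rec <- structure_record(atoms)
  if (!is.null(corruption)) {
    res <- with_seed(seed, corrupt_record(rec, corruption, n_corrupt))
    rec <- res$record
    manifest$corrupted <- res$corrupted
  }
  list(record = rec, manifest = manifest)
}

# pick n residues (chain,resid) among the eligible set, deterministically
# under the caller's seed
pick_residues <- function(res, eligible, n) {
  idx <- which(eligible)
  if (!length(idx)) stop("no residue eligible for this corruption in fixture")
  idx[sample.int(length(idx), min(n, length(idx)))]
}

corrupt_record <- function(rec, corruption, n_corrupt) {
  at <- rec$atoms
  rkey <- paste(at$chain, at$resid, sep = "|")
  res <- unique(data.frame(chain = at$chain, resid = at$resid,
                           resname = at$resname, key = rkey,
                           stringsAsFactors = FALSE))
  corrupted <- NULL
  drop_idx <- integer()
  if (corruption == "drop_atoms") {
    sel <- pick_residues(res, res$resname %in%
                           c("ALA", "GLY", "CYS", "HIS", "HISD", "TYR"),
                         n_corrupt)
    for (r in sel) {
      drop_idx <- c(drop_idx, which(rkey == res$key[r] & at$atom_name == "O"))
    }
  } else if (corruption == "drop_coordinates") {
    # remove a whole side chain: every atom of the corresponding bead is
    # then missing from the input
    sel <- pick_residues(res, res$resname %in% c("CYS", "HIS", "HISD", "TYR"),
                         n_corrupt)
    for (r in sel) {
      drop_idx <- c(drop_idx, which(rkey == res$key[r] &
                                      !(at$atom_name %in% c("N", "CA", "C", "O"))))
    }
  } else if (corruption == "rename_atoms") {
    sel <- pick_residues(res, !(res$resname %in% c("TYR", "PTR")), n_corrupt)
    for (r in sel) {
      idx <- which(rkey == res$key[r])
      at$atom_name[idx] <- paste0("X", seq_along(idx))
    }
  } else if (corruption == "swap_elements") {
    sel <- pick_residues(res, rep(TRUE, nrow(res)), n_corrupt)
    for (r in sel) {
      idx <- which(rkey == res$key[r] & at$element == "N")[1L]
      if (is.na(idx)) idx <- which(rkey == res$key[r] & at$element == "O")[1L]
      at$element[idx] <- if (at$element[idx] == "N") "O" else "N"
    }
  } else if (corruption == "perturb_distances") {
    his <- res$resname %in% c("HIS", "HISD")
    sel <- pick_residues(res, if (any(his)) his else
      res$resname %in% c("ALA", "CYS"), n_corrupt)
    for (r in sel) {
      idx <- which(rkey == res$key[r])
      tgt <- idx[match("CE1", at$atom_name[idx])]
      if (!is.na(tgt)) {
        # push the ring atom outward far enough to break its ring bonds
        ctr <- c(mean(at$x[idx]), mean(at$y[idx]))
        v <- c(at$x[tgt], at$y[tgt]) - ctr
        v <- v / sqrt(sum(v^2))
        at$x[tgt] <- at$x[tgt] + 0.30 * v[1]
        at$y[tgt] <- at$y[tgt] + 0.30 * v[2]
      } else {
        tgt <- idx[match("CB", at$atom_name[idx])]
        at$x[tgt] <- at$x[tgt] + 0.22  # breaks CA-CB, grazes the carbonyl C
      }
    }
  } else if (corruption == "add_atom") {
    sel <- pick_residues(res, res$resname == "GLY", n_corrupt)
    extra <- NULL
    for (r in sel) {
      idx <- which(rkey == res$key[r])
      ca <- idx[match("CA", at$atom_name[idx])]
      row <- at[ca, , drop = FALSE]
      row$atom_name <- "CB"; row$element <- "C"
      row$y <- row$y - 0.153
      row$serial <- max(at$serial) + NROW(extra) + 1L
      extra <- rbind(extra, row)
    }
    at <- rbind(at, extra)
    at <- at[order(at$chain, at$resid, at$serial), , drop = FALSE]
  } else {
    stop("unknown corruption class: ", corruption)
  }
  if (exists("sel")) {
    corrupted <- data.frame(chain = res$chain[sel], resid = res$resid[sel],
                            type = corruption, stringsAsFactors = FALSE)
  }
  if (length(drop_idx)) at <- at[-drop_idx, , drop = FALSE]
  at$serial <- seq_len(nrow(at))
  rownames(at) <- NULL
  list(record = structure_record(at, rec$conect), corrupted = corrupted)
}
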