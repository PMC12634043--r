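## Resolution transformation: cover the repaired molecule with mapping
## fragments (largest residue scope first, so multi-residue mappings are
## not shadowed) and emit the target-resolution molecule with bead
## coordinates and intra-fragment interactions.

#' Cover a molecule with resolution mappings
#'
#' Greedy largest-scope-first placement: multi-residue mappings are placed
#' before single-residue ones; within a scope length, file order decides.
#' Each placement is validated by matching the mapping's source atoms (by
#' canonical name, the molecule having been repaired) onto consecutive
#' bonded residues whose names equal the mapping scope.  Residues with no
#' applicable mapping are excluded with a warning; heavy atoms not named by
#' any mapping (nor assigned by an applied modification) are reported as
#' uncovered, never silently dropped.
#'
#' @param mol repaired [molgraph()].
#' @param mappings list of [ff_mapping()].
#' @param ledger [warning_ledger()].
#' @param modifications named list of [ff_modification()]; atoms the
#'   molecule's applied modifications assign to beads count as covered.
#' @return list of class `mapping_cover`: `placements` (each with `mapping`,
#'   `residue_keys`, `atom_ids` named by "residx|atom_name"), and
#'   `uncovered_atoms`.
#' @export
build_cover <- function(mol, mappings, ledger = warning_ledger(),
                        modifications = list()) {
  res <- residue_table(mol)
  keys <- residue_keys(mol)
  ord <- order(-vapply(mappings, function(m) length(m$scope), integer(1)),
               seq_along(mappings))
  covered <- character()
  placements <- list()
  claimed <- integer()  # molecule atom ids claimed by a placement
  for (m in mappings[ord]) {
    L <- length(m$scope)
    for (start in seq_len(nrow(res))) {
      win <- start + seq_len(L) - 1L
      if (max(win) > nrow(res)) next
      if (any(res$key[win] %in% covered)) next
      if (!all(res$resname[win] == m$scope)) next
      if (L > 1L) {
        if (length(unique(res$chain[win])) != 1L) next
        if (any(diff(res$resid[win]) != 1L)) next
      }
      ids <- setNames(rep(NA_integer_, nrow(m$atoms)),
                      paste(m$atoms$residx, m$atoms$atom_name, sep = "|"))
      for (k in seq_len(nrow(m$atoms))) {
        ridx <- which(keys == res$key[win[m$atoms$residx[k]]])
        hit <- ridx[match(m$atoms$atom_name[k], mol$atoms$atom_name[ridx])]
        ids[k] <- hit
      }
      placements[[length(placements) + 1L]] <-
        list(mapping = m, residue_keys = res$key[win], atom_ids = ids,
             start = start)
      covered <- c(covered, res$key[win])
      claimed <- c(claimed, ids[!is.na(ids)])
    }
  }
  # greedy order decided the claims; emit beads in residue order
  placements <- placements[order(vapply(placements, `[[`, integer(1),
                                        "start"))]
  # atoms assigned to beads by applied modifications are covered too
  for (key in names(mol$residue_mods)) {
    ridx <- which(keys == key)
    for (mn in mol$residue_mods[[key]]) {
      mod <- modifications[[mn]]
      if (is.null(mod)) next
      for (asg in mod$atom_assign) {
        hit <- ridx[match(asg$atom, mol$atoms$atom_name[ridx])]
        claimed <- c(claimed, hit[!is.na(hit)])
      }
    }
  }
  uncovered <- setdiff(which(!is_hydrogen(mol$atoms)), claimed)
  uncovered <- uncovered[keys[uncovered] %in% covered]
  for (a in uncovered) {
    ledger_add(ledger, "unexpected-atoms",
               sprintf("atom '%s' is not covered by any mapping",
                       mol$atoms$atom_name[a]),
               list(chain = mol$atoms$chain[a], resid = mol$atoms$resid[a],
                    resname = mol$atoms$resname[a]))
  }
  left <- res$key[!(res$key %in% covered)]
  for (key in left) {
    r <- match(key, res$key)
    ledger_add(ledger, "unrecognized-residue",
               sprintf("no mapping applies to residue '%s'; residue excluded",
                       res$resname[r]),
               list(chain = res$chain[r], resid = res$resid[r],
                    resname = res$resname[r]))
  }
  structure(list(placements = placements, uncovered_atoms = uncovered,
                 residues = res),
            class = "mapping_cover")
}

bead_weights_for <- function(placement, mol, mods, weights_mode) {
  m <- placement$mapping
  beads <- m$beads
  per_bead <- setNames(vector("list", length(beads)), beads)
  add_w <- function(bead, atom_id, w) {
    per_bead[[bead]] <<- rbind(per_bead[[bead]],
                               data.frame(atom = atom_id, w = w))
  }
  for (k in seq_len(nrow(m$atoms))) {
    aid <- placement$atom_ids[k]
    if (is.na(aid)) next
    w <- m$atoms$weights[[k]]
    for (b in names(w)) add_w(b, aid, w[[b]])
  }
  # applied modifications extend the base mapping
  keys <- residue_keys(mol)
  for (key in placement$residue_keys) {
    for (mod in mods[[key]] %||% list()) {
      for (asg in mod$atom_assign) {
        ridx <- which(keys == key)
        aid <- ridx[match(asg$atom, mol$atoms$atom_name[ridx])]
        if (!is.na(aid) && asg$bead %in% beads) {
          add_w(asg$bead, aid, asg$weight)
        }
      }
    }
  }
  if (weights_mode != "file") {
    masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                P = 30.974)
    for (b in names(per_bead)) {
      tb <- per_bead[[b]]
      if (is.null(tb)) next
      pos <- tb$w > 0
      if (weights_mode == "uniform") tb$w[pos] <- 1
      if (weights_mode == "mass") {
        el <- toupper(mol$atoms$element[tb$atom[pos]])
        tb$w[pos] <- unname(masses[el])
        tb$w[pos][is.na(tb$w[pos])] <- 12
      }
      per_bead[[b]] <- tb
    }
  }
  per_bead
}

#' Transform a covered molecule to the target resolution
#'
#' One particle per target bead; the bead position is the weighted mean of
#' its source atoms' positions.  If only some source atoms have positions
#' the bead position is estimated from the available ones and a warning is
#' recorded; if none have, the bead is coordinate-free, with a warning.
#' Beads inherit residue attributes from the dominant source residue
#' (largest total weight, ties to the lowest resid); bead-to-bead edges are
#' created wherever a mapped source bond crosses beads; intra-fragment
#' interactions are copied from the target block; bead edits of applied
#' modifications (particle type, charge) are applied last.
#'
#' @param mol repaired source-resolution [molgraph()].
#' @param cover a `mapping_cover` from [build_cover()].
#' @param target_ff target-resolution [forcefield()].
#' @param ledger [warning_ledger()].
#' @param weights_mode `"file"` (mapping weights), `"mass"`, or `"uniform"`.
#' @return [molgraph()] at the target resolution.
#' @export
map_to_target <- function(mol, cover, target_ff, ledger = warning_ledger(),
                          weights_mode = c("file", "mass", "uniform")) {
  weights_mode <- match.arg(weights_mode)
  keys <- residue_keys(mol)
  # resolve modification objects from both force fields' libraries
  all_mods <- target_ff$modifications
  src_ff <- attr(mol, "source_ff")
  if (!is.null(src_ff)) all_mods <- c(all_mods, src_ff$modifications)
  mods_by_key <- lapply(mol$residue_mods, function(mns) {
    Filter(Negate(is.null), lapply(mns, function(mn) all_mods[[mn]]))
  })

  bead_rows <- list()
  bead_edges <- list()
  interactions <- list()
  citations <- mol$citations
  atom2bead <- list()  # per source atom: integer vector of bead ids
  for (i in seq_len(nrow(mol$atoms))) atom2bead[[i]] <- integer()
  n_beads <- 0L

  for (placement in cover$placements) {
    m <- placement$mapping
    tblock <- target_ff$blocks[[m$name]]
    if (is.null(tblock)) {
      ledger_add(ledger, "unrecognized-residue",
                 sprintf("mapping '%s' targets a block absent from force field '%s'",
                         m$name, target_ff$name))
      next
    }
    citations <- union(citations, tblock$citations)
    per_bead <- bead_weights_for(placement, mol, mods_by_key, weights_mode)
    tat <- tblock$graph$atoms
    for (bi in seq_len(nrow(tat))) {
      bname <- tat$atom_name[bi]
      tb <- per_bead[[bname]]
      pos <- c(NA_real_, NA_real_, NA_real_)
      dom_key <- placement$residue_keys[1L]
      n_src <- 0L
      if (!is.null(tb) && nrow(tb)) {
        wpos <- tb[tb$w > 0, , drop = FALSE]
        n_src <- nrow(wpos)
        have <- wpos[!is.na(mol$atoms$x[wpos$atom]), , drop = FALSE]
        if (nrow(have)) {
          W <- sum(have$w)
          pos <- c(sum(mol$atoms$x[have$atom] * have$w),
                   sum(mol$atoms$y[have$atom] * have$w),
                   sum(mol$atoms$z[have$atom] * have$w)) / W
        }
        rk <- keys[wpos$atom]
        totw <- tapply(wpos$w, rk, sum)
        best <- names(totw)[order(-totw, names(totw))][1L]
        dom_key <- best
        if (nrow(have) == 0L && n_src > 0L) {
          ledger_add(ledger, "missing-coordinates",
                     sprintf("all source atoms of bead %s are missing: bead is coordinate-free",
                             bname),
                     list(resid = sub("^[^|]*\\|", "", dom_key),
                          chain = sub("\\|.*$", "", dom_key), bead = bname))
        } else if (nrow(have) < n_src) {
          ledger_add(ledger, "missing-coordinates",
                     sprintf("bead %s position estimated from %d of %d source atoms",
                             bname, nrow(have), n_src),
                     list(resid = sub("^[^|]*\\|", "", dom_key),
                          chain = sub("\\|.*$", "", dom_key), bead = bname))
        }
      }
      src_row <- mol$atoms[match(dom_key, keys), , drop = FALSE]
      bead_rows[[length(bead_rows) + 1L]] <- data.frame(
        atom_name = bname, resname = src_row$resname,
        resid = src_row$resid, chain = src_row$chain,
        element = NA_character_,
        charge = tat$charge[bi], mass = tat$mass[bi],
        x = pos[1], y = pos[2], z = pos[3],
        particle_type = tat$particle_type[bi],
        secstruct = src_row$secstruct,
        stringsAsFactors = FALSE)
      if (!is.null(tb)) {
        for (a in tb$atom[tb$w > 0]) {
          atom2bead[[a]] <- union(atom2bead[[a]], n_beads + bi)
        }
      }
    }
    # intra-fragment interactions and edges from the target block
    for (kind in names(tblock$graph$interactions)) {
      for (ia in tblock$graph$interactions[[kind]]) {
        ia$particles <- n_beads + ia$particles
        interactions[[length(interactions) + 1L]] <- ia
      }
    }
    if (nrow(tblock$graph$edges)) {
      bead_edges[[length(bead_edges) + 1L]] <- n_beads + tblock$graph$edges
    }
    n_beads <- n_beads + nrow(tat)
  }
  if (!n_beads) stop("resolution transformation produced no particles")
  atoms <- do.call(rbind, bead_rows)
  # edges wherever a mapped source bond crosses bead boundaries
  for (e in seq_len(nrow(mol$edges))) {
    ba <- atom2bead[[mol$edges[e, 1L]]]
    bb <- atom2bead[[mol$edges[e, 2L]]]
    for (a in ba) for (b in bb) {
      if (a != b) bead_edges[[length(bead_edges) + 1L]] <- c(a, b)
    }
  }
  edges <- do.call(rbind, c(list(matrix(integer(), ncol = 2L)), bead_edges))
  grouped <- list()
  for (ia in interactions) grouped[[ia$kind]] <- c(grouped[[ia$kind]],
                                                   list(ia))
  out <- molgraph(atoms, edges, grouped, citations, target_ff$name,
                  mol$name, mol$nrexcl)
  out$residue_mods <- mol$residue_mods
  # bead edits (particle type / charge) from applied modifications
  out_keys <- residue_keys(out)
  for (key in names(mods_by_key)) {
    for (mod in mods_by_key[[key]]) {
      for (be in mod$bead_edits) {
        tgt <- which(out_keys == key & out$atoms$atom_name == be$bead)
        if (length(tgt)) {
          val <- if (be$attr %in% c("charge", "mass")) as.numeric(be$value) else be$value
          out$atoms[tgt, be$attr] <- val
        }
      }
    }
  }
  out
}

#' Identity mappings for a force field
#'
#' One mapping per block sending every particle to itself with weight 1 —
#' the same-resolution pathway: transforming with these reproduces the
#' input graph (plus the blocks' interactions), which is how all-atom
#' topologies are generated through the identical pipeline.
#'
#' @param ff a [forcefield()].
#' @return list of [ff_mapping()].
#' @export
identity_mappings <- function(ff) {
  lapply(unname(ff$blocks), function(b) {
    at <- b$graph$atoms
    atoms <- data.frame(residx = 1L, atom_name = at$atom_name,
                        stringsAsFactors = FALSE)
    atoms$weights <- lapply(at$atom_name, function(nm) setNames(1, nm))
    ff_mapping(b$name, b$name, at$atom_name, atoms, ff$name, ff$name)
  })
}

#' Construct virtual-site positions
#'
#' Virtual sites are massless particles whose position is built from their
#' constructing particles (here: the unweighted mean, GROMACS
#' `virtual_sitesn` style).  Sites depending on other sites are evaluated
#' in topological order; a site whose constructors lack coordinates becomes
#' coordinate-free with a warning.  Virtual sites are excluded from
#' elastic-network generation and mass accounting by carrying zero mass.
#'
#' @param mol a [molgraph()] with `virtual_sitesn` interactions.
#' @param ledger [warning_ledger()].
#' @return molecule with updated positions.
#' @export
construct_virtual_sites <- function(mol, ledger = warning_ledger()) {
  vs <- mol$interactions$virtual_sitesn
  if (!length(vs)) return(mol)
  sites <- vapply(vs, function(ia) ia$particles[1L], integer(1))
  remaining <- seq_along(vs)
  for (pass in seq_len(length(vs) + 1L)) {
    if (!length(remaining)) break
    progressed <- FALSE
    for (k in remaining) {
      cons <- vs[[k]]$particles[-1L]
      # wait until constructors that are themselves sites are resolved
      if (any(cons %in% sites[remaining] & cons != sites[k])) next
      s <- sites[k]
      if (anyNA(mol$atoms$x[cons])) {
        ledger_add(ledger, "missing-coordinates",
                   sprintf("virtual site %s has coordinate-free constructors",
                           mol$atoms$atom_name[s]),
                   list(resid = mol$atoms$resid[s], chain = mol$atoms$chain[s]))
        mol$atoms$x[s] <- mol$atoms$y[s] <- mol$atoms$z[s] <- NA_real_
      } else {
        mol$atoms$x[s] <- mean(mol$atoms$x[cons])
        mol$atoms$y[s] <- mean(mol$atoms$y[cons])
        mol$atoms$z[s] <- mean(mol$atoms$z[cons])
      }
      mol$atoms$mass[s] <- 0
      remaining <- setdiff(remaining, k)
      progressed <- TRUE
    }
    if (!progressed) stop("cyclic virtual-site dependency")
  }
  mol
}
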