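## Identify & repair: compare each residue to its canonical block, fix atom
## names, add missing atoms as coordinate-free nodes, flag extra atoms, and
## resolve them as modifications (protonation states, PTMs, termini).

residue_table <- function(mol) {
  keys <- residue_keys(mol)
  idx <- !duplicated(keys)
  data.frame(key = keys[idx], chain = mol$atoms$chain[idx],
             resid = mol$atoms$resid[idx], resname = mol$atoms$resname[idx],
             stringsAsFactors = FALSE)
}

is_hydrogen <- function(atoms) {
  el <- toupper(atoms$element)
  ifelse(is.na(el), grepl("^[0-9]*H", atoms$atom_name), el == "H")
}

# block graph with a modification's added atoms grafted on (used for
# route (a) aliases such as HSP = HIS + protonation)
apply_modification_to_block <- function(block, mod) {
  g <- block$graph
  added <- mod$atoms[mod$atoms$role == "added", , drop = FALSE]
  if (nrow(added)) {
    newrows <- data.frame(atom_name = added$atom_name,
                          resname = g$atoms$resname[1L],
                          resid = 1L, element = added$element,
                          stringsAsFactors = FALSE)
    atoms <- rbind(g$atoms[, c("atom_name", "resname", "resid", "element")],
                   newrows)
    all_names <- atoms$atom_name
    edges <- g$edges
    for (e in seq_len(nrow(mod$edges))) {
      a <- match(mod$edges[e, 1L], all_names)
      b <- match(mod$edges[e, 2L], all_names)
      if (!is.na(a) && !is.na(b)) edges <- rbind(edges, c(a, b))
    }
    g <- molgraph(atoms, edges, g$interactions, g$citations)
  }
  ff_block(block$name, g, block$nrexcl,
           union(block$citations, mod$citations))
}

#' Compare one residue against its canonical block
#'
#' Computes a maximum common induced-subgraph correspondence (fast path:
#' identical atom names and consistent connectivity), rewrites atom names
#' to the block's names, and reports missing and extra atoms.  Heavy atoms
#' and hydrogens are treated separately: structures without hydrogens are
#' valid inputs, so absent hydrogens in otherwise complete residues are
#' missing-but-unwarned unless `strict_h`.
#'
#' @param residue [molgraph()] of one residue (induced subgraph).
#' @param block [ff_block()] selected by residue name.
#' @param strict_h warn about absent hydrogens.
#' @return list with `correspondence` (block-atom name -> residue particle
#'   id), `missing` (block atom names), `extra` (residue particle ids),
#'   `renamed` (data.frame old/new), `new_names` (per residue particle).
#' @export
match_canonical <- function(residue, block, strict_h = FALSE) {
  bat <- block$graph$atoms
  rat <- residue$atoms
  bh <- !is_hydrogen(bat); rh <- !is_hydrogen(rat)
  bheavy <- which(bh); rheavy <- which(rh)
  corr <- rep(NA_integer_, nrow(bat))  # block idx -> residue idx

  heavy_block <- subset_molgraph(block$graph, bheavy)
  heavy_res <- subset_molgraph(residue, rheavy)
  fast <- FALSE
  if (length(bheavy) == length(rheavy) &&
      setequal(bat$atom_name[bheavy], rat$atom_name[rheavy]) &&
      !anyDuplicated(rat$atom_name[rheavy])) {
    m <- match(bat$atom_name[bheavy], rat$atom_name[rheavy])
    # elements and connectivity must agree, otherwise fall through to
    # graph matching
    bel <- toupper(bat$element[bheavy])
    rel <- toupper(rat$element[rheavy][m])
    el_ok <- all(is.na(bel) | is.na(rel) | bel == rel)
    eb <- matrix(m[heavy_block$edges], ncol = 2L)
    same <- el_ok &&
      identical(normalize_edges(eb, length(rheavy)), heavy_res$edges)
    if (same) {
      corr[bheavy] <- rheavy[m]
      fast <- TRUE
    }
  }
  if (!fast) {
    mcs <- max_common_subgraph(heavy_block, heavy_res)
    corr[bheavy] <- rheavy[mcs]
  }
  # hydrogens: assign residue H's to block H's bonded to the corresponding
  # heavy atom (name match preferred)
  radj <- adjacency_list(nrow(rat), residue$edges)
  badj <- adjacency_list(nrow(bat), block$graph$edges)
  used_bh <- rep(FALSE, nrow(bat))
  for (ri in which(!rh)) {
    heavy_nbr <- radj[[ri]][rh[radj[[ri]]]]
    cand <- integer()
    for (hn in heavy_nbr) {
      bidx <- which(corr == hn)
      if (length(bidx)) {
        cand <- c(cand, Filter(function(bj) !used_bh[bj] && !bh[bj] &&
                                 is.na(corr[bj]), badj[[bidx]]))
      }
    }
    if (length(cand)) {
      nm_hit <- cand[bat$atom_name[cand] == rat$atom_name[ri]]
      pick <- if (length(nm_hit)) nm_hit[1L] else cand[1L]
      corr[pick] <- ri
      used_bh[pick] <- TRUE
    }
  }
  matched <- which(!is.na(corr))
  missing <- bat$atom_name[setdiff(seq_len(nrow(bat)), matched)]
  extra <- setdiff(seq_len(nrow(rat)), corr[matched])
  new_names <- rat$atom_name
  new_names[corr[matched]] <- bat$atom_name[matched]
  renamed <- data.frame(old = rat$atom_name[corr[matched]],
                        new = bat$atom_name[matched],
                        stringsAsFactors = FALSE)
  renamed <- renamed[renamed$old != renamed$new, , drop = FALSE]
  list(correspondence = setNames(corr[matched], bat$atom_name[matched]),
       missing = missing,
       missing_heavy = missing[!is_hydrogen(
         bat[match(missing, bat$atom_name), , drop = FALSE])],
       extra = extra, renamed = renamed, new_names = new_names)
}

#' Repair a molecule against canonical residue definitions
#'
#' Stage-2 processing: every residue is compared against the block selected
#' by its residue name (through the force field's resname alias table, so
#' CHARMM/AMBER protonation-state names resolve to canonical block plus
#' pre-applied modification).  Atom names are rewritten, missing heavy
#' atoms are added as coordinate-free nodes (geometry is never rebuilt
#' here), and extra atoms are resolved against the modification library.
#'
#' @param mol [molgraph()] at the atomistic resolution.
#' @param ff source-resolution [forcefield()].
#' @param ledger [warning_ledger()].
#' @param strict_h warn about absent hydrogens.
#' @return list `molecule` (repaired), `reports` (per residue key).
#' @export
repair_molecule <- function(mol, ff, ledger = warning_ledger(),
                            strict_h = FALSE) {
  res <- residue_table(mol)
  keys <- residue_keys(mol)
  reports <- list()
  new_atoms <- mol$atoms
  added_rows <- list()
  added_edges <- list()
  for (r in seq_len(nrow(res))) {
    key <- res$key[r]
    ridx <- which(keys == key)
    rn <- res$resname[r]
    alias <- ff$aliases[[rn]]
    premods <- character()
    bname <- rn
    if (!is.null(alias)) {
      bname <- alias$block
      premods <- alias$mods
    }
    block <- ff$blocks[[bname]]
    if (is.null(block)) {
      ledger_add(ledger, "unrecognized-residue",
                 sprintf("residue name '%s' not in force field '%s'", rn, ff$name),
                 list(chain = res$chain[r], resid = res$resid[r], resname = rn))
      reports[[key]] <- list(chain = res$chain[r], resid = res$resid[r],
                             resname = rn, block = NA_character_,
                             correspondence = integer(), missing = character(),
                             extra = ridx, renamed = NULL,
                             applied_modifications = character())
      next
    }
    for (pm in premods) {
      block <- apply_modification_to_block(block, ff$modifications[[pm]])
    }
    mol$citations <- union(mol$citations, block$citations)
    residue <- subset_molgraph(mol, ridx)
    rep1 <- match_canonical(residue, block, strict_h = strict_h)
    orig <- attr(residue, "orig_index")
    # apply renames and canonical residue name
    new_atoms$atom_name[orig] <- rep1$new_names
    new_atoms$resname[ridx] <- bname
    for (i in seq_len(nrow(rep1$renamed))) {
      ledger_add(ledger, "general",
                 sprintf("atom '%s' renamed to '%s'", rep1$renamed$old[i],
                         rep1$renamed$new[i]),
                 list(chain = res$chain[r], resid = res$resid[r], resname = rn),
                 level = "info")
    }
    warn_missing <- if (strict_h) rep1$missing else rep1$missing_heavy
    if (length(warn_missing)) {
      ledger_add(ledger, "missing-atoms",
                 sprintf("missing atom(s): %s", paste(warn_missing, collapse = ", ")),
                 list(chain = res$chain[r], resid = res$resid[r], resname = rn))
    }
    # add missing heavy atoms as coordinate-free nodes
    bat <- block$graph$atoms
    # correspondence values are residue-local ids; translate to molecule ids
    name2mol <- setNames(orig[rep1$correspondence], names(rep1$correspondence))
    for (mn in rep1$missing_heavy) {
      bi <- match(mn, bat$atom_name)
      newrow <- new_atoms[ridx[1L], , drop = FALSE]
      newrow$atom_name <- mn
      newrow$element <- bat$element[bi]
      newrow$x <- newrow$y <- newrow$z <- NA_real_
      if (!is.null(newrow$serial)) newrow$serial <- NA_integer_
      added_rows[[length(added_rows) + 1L]] <- newrow
      name2mol[mn] <- nrow(new_atoms) + length(added_rows)
    }
    # edges of the block incident to newly added atoms
    for (e in seq_len(nrow(block$graph$edges))) {
      na_ <- bat$atom_name[block$graph$edges[e, ]]
      if (any(na_ %in% rep1$missing_heavy)) {
        a <- name2mol[na_[1L]]; b <- name2mol[na_[2L]]
        if (!is.na(a) && !is.na(b)) {
          added_edges[[length(added_edges) + 1L]] <- c(a, b)
        }
      }
    }
    reports[[key]] <- list(chain = res$chain[r], resid = res$resid[r],
                           resname = bname, block = bname,
                           correspondence = name2mol,
                           missing = rep1$missing_heavy,
                           extra = orig[rep1$extra],
                           renamed = rep1$renamed,
                           applied_modifications = premods)
  }
  if (length(added_rows)) {
    new_atoms <- rbind(new_atoms, do.call(rbind, added_rows))
  }
  edges <- rbind(mol$edges, do.call(rbind, added_edges))
  out <- molgraph(new_atoms, edges, mol$interactions, mol$citations,
                  mol$forcefield, mol$name, mol$nrexcl)
  out$residue_mods <- mol$residue_mods
  for (key in names(reports)) {
    pm <- reports[[key]]$applied_modifications
    if (length(pm)) {
      out$residue_mods[[key]] <- union(out$residue_mods[[key]], pm)
    }
  }
  list(molecule = out, reports = reports)
}

# can `mod`'s added atoms be embedded onto `extras` of this residue?
# returns list(assign = extra-particle-id -> added atom name) or NULL
embed_modification <- function(mol, mod, report, extras) {
  added <- mod$atoms[mod$atoms$role == "added", , drop = FALSE]
  if (!nrow(added) || length(extras) < nrow(added)) return(NULL)
  anchors <- mod$atoms$atom_name[mod$atoms$role == "anchor"]
  anchor_ids <- report$correspondence[anchors]
  if (anyNA(anchor_ids)) return(NULL)
  # build pattern: anchors + added, edges from the modification
  pat_names <- c(anchors, added$atom_name)
  pat_elem <- c(rep(NA_character_, length(anchors)), added$element)
  pedges <- NULL
  for (e in seq_len(nrow(mod$edges))) {
    a <- match(mod$edges[e, 1L], pat_names)
    b <- match(mod$edges[e, 2L], pat_names)
    if (!is.na(a) && !is.na(b)) pedges <- rbind(pedges, c(a, b))
  }
  pattern <- molgraph(data.frame(atom_name = pat_names, resname = "",
                                 resid = 1L, element = pat_elem,
                                 stringsAsFactors = FALSE), pedges)
  tgt_ids <- c(unname(anchor_ids), extras)
  target <- subset_molgraph(mol, tgt_ids)
  tmap <- attr(target, "index_map")
  n_anchor <- length(anchors)
  # anchor nodes must match exactly their molecule atom; added nodes match
  # extras by element
  tloc_anchor <- tmap[unname(anchor_ids)]
  target$atoms$.loc <- seq_len(nrow(target$atoms))
  nm <- function(p, t) {
    pidx <- match(p$atom_name, pat_names)
    if (pidx <= n_anchor) return(t$.loc == tloc_anchor[pidx])
    # added atom: must be an extra with matching element
    if (t$.loc %in% tloc_anchor) return(FALSE)
    identical(toupper(p$element), toupper(t$element))
  }
  ms <- subgraph_isomorphisms(pattern, target, node_match = nm,
                              max_matches = 1L)
  if (!length(ms)) return(NULL)
  m <- ms[[1L]]
  orig <- attr(target, "orig_index")
  assign <- setNames(added$atom_name, orig[m[(n_anchor + 1L):length(m)]])
  assign
}

#' Resolve extra atoms as force-field modifications
#'
#' Searches for a set of modifications whose added atoms exactly cover a
#' residue's extra atoms while their anchors match canonical atoms; the
#' minimal cover wins, ties broken by lexicographic modification name.
#' Matched extra atoms are renamed to the modification's atom names and the
#' modification recorded for the mapping stage.  Residues whose extras
#' cannot be explained are flagged, never silently passed on.
#'
#' @param mol repaired [molgraph()].
#' @param reports repair reports from [repair_molecule()].
#' @param modifications named list of [ff_modification()].
#' @param ledger [warning_ledger()].
#' @return list `molecule`, `reports` (with `applied_modifications` filled).
#' @export
resolve_modifications <- function(mol, reports, modifications,
                                  ledger = warning_ledger()) {
  for (key in names(reports)) {
    rep1 <- reports[[key]]
    extras <- rep1$extra
    if (!length(extras) || is.na(rep1$block)) next
    cands <- Filter(function(m) {
      ("*" %in% m$resnames || rep1$resname %in% m$resnames) &&
        any(m$atoms$role == "added")
    }, modifications)
    cands <- cands[order(vapply(cands, function(m) m$name, character(1)))]
    embeds <- lapply(cands, function(m) embed_modification(mol, m, rep1, extras))
    ok <- !vapply(embeds, is.null, logical(1))
    cands <- cands[ok]; embeds <- embeds[ok]
    chosen <- NULL
    if (length(cands)) {
      for (k in seq_len(min(length(cands), 3L))) {
        combos <- utils::combn(length(cands), k, simplify = FALSE)
        for (cmb in combos) {
          covered <- unlist(lapply(embeds[cmb], function(e)
            as.integer(names(e))))
          if (!anyDuplicated(covered) && setequal(covered, extras)) {
            chosen <- cmb
            break
          }
        }
        if (!is.null(chosen)) break
      }
    }
    if (is.null(chosen)) {
      ledger_add(ledger, "unexpected-atoms",
                 sprintf("atom(s) %s not explained by the canonical residue or any modification",
                         paste(mol$atoms$atom_name[extras], collapse = ", ")),
                 list(chain = rep1$chain, resid = rep1$resid,
                      resname = rep1$resname))
      next
    }
    for (ci in chosen) {
      mod <- cands[[ci]]
      emb <- embeds[[ci]]
      ids <- as.integer(names(emb))
      mol$atoms$atom_name[ids] <- unname(emb)
      for (ae in mod$attribute_edits) {
        tgt <- which(residue_keys(mol) == key &
                       mol$atoms$atom_name == ae$atom)
        if (length(tgt)) {
          val <- if (ae$attr %in% c("charge", "mass")) as.numeric(ae$value) else ae$value
          mol$atoms[tgt, ae$attr] <- val
        }
      }
      mol$residue_mods[[key]] <- union(mol$residue_mods[[key]], mod$name)
      mol$citations <- union(mol$citations, mod$citations)
      rep1$applied_modifications <- union(rep1$applied_modifications, mod$name)
      rep1$extra <- setdiff(rep1$extra, ids)
    }
    reports[[key]] <- rep1
  }
  list(molecule = mol, reports = reports)
}

#' Apply terminal modifications to chain ends
#'
#' Peptide residues (those whose block contains the force field's backbone
#' atoms) with a degree-deficient backbone terminus receive the force
#' field's default terminal modifications; cyclic molecules have no ends
#' and get none, and a single-residue molecule carries both.
#'
#' @param mol repaired [molgraph()].
#' @param ff source [forcefield()].
#' @param ledger [warning_ledger()].
#' @param nter,cter modification names overriding the force-field defaults.
#' @return the molecule with terminal modifications recorded.
#' @export
assign_termini <- function(mol, ff, ledger = warning_ledger(),
                           nter = NULL, cter = NULL) {
  bb <- ff$variables$backbone %||% c("N", "CA", "C")
  nter <- nter %||% (ff$variables$nter_mod %||% NA_character_)
  cter <- cter %||% (ff$variables$cter_mod %||% NA_character_)
  keys <- residue_keys(mol)
  res <- residue_table(mol)
  adj <- adjacency_list(nrow(mol$atoms), mol$edges)
  for (r in seq_len(nrow(res))) {
    block <- ff$blocks[[res$resname[r]]]
    if (is.null(block) || !all(bb %in% block$graph$atoms$atom_name)) next
    ridx <- which(keys == res$key[r])
    n_at <- ridx[match("N", mol$atoms$atom_name[ridx])]
    c_at <- ridx[match("C", mol$atoms$atom_name[ridx])]
    apply_term <- function(modname, what) {
      if (is.na(modname)) return()
      if (!modname %in% names(ff$modifications)) {
        ledger_add(ledger, "general",
                   sprintf("%s pattern matched but modification '%s' is not in the library",
                           what, modname),
                   list(chain = res$chain[r], resid = res$resid[r]))
        return()
      }
      mol$residue_mods[[res$key[r]]] <<-
        union(mol$residue_mods[[res$key[r]]], modname)
      mol$citations <<- union(mol$citations,
                              ff$modifications[[modname]]$citations)
    }
    if (!is.na(n_at)) {
      ext <- any(keys[adj[[n_at]]] != res$key[r] &
                   mol$atoms$atom_name[adj[[n_at]]] == "C")
      if (!ext) apply_term(nter, "N-terminus")
    }
    if (!is.na(c_at)) {
      ext <- any(keys[adj[[c_at]]] != res$key[r] &
                   mol$atoms$atom_name[adj[[c_at]]] == "N")
      if (!ext) apply_term(cter, "C-terminus")
    }
  }
  mol
}

#' Annotate per-residue secondary structure
#'
#' @param mol a [molgraph()].
#' @param ss one-letter-per-residue string, a file containing one
#'   (whitespace/line agnostic), or `"auto"`.  `"auto"` uses the trivial
#'   all-coil fallback but first verifies that backbone coordinates are
#'   complete, since a real assignment algorithm needs them: missing
#'   backbone positions are an error.
#' @param ff force field (for backbone atom names).
#' @param ledger [warning_ledger()].
#' @return molecule with `secstruct` set on every particle.
#' @export
annotate_secondary_structure <- function(mol, ss = "auto", ff = NULL,
                                         ledger = warning_ledger()) {
  res <- residue_table(mol)
  keys <- residue_keys(mol)
  if (length(ss) == 1L && file.exists(ss)) {
    ss <- paste(gsub("[ \t]", "", readLines(ss, warn = FALSE)), collapse = "")
  }
  if (identical(ss, "auto")) {
    bb <- if (!is.null(ff)) ff$variables$backbone %||% c("N", "CA", "C") else
      c("N", "CA", "C")
    bad <- mol$atoms$atom_name %in% bb & is.na(mol$atoms$x)
    if (any(bad)) {
      ledger_add(ledger, "ss-failure",
                 "missing backbone coordinates prevent secondary-structure assignment",
                 list(resid = mol$atoms$resid[which(bad)[1L]],
                      chain = mol$atoms$chain[which(bad)[1L]]))
      stop("cannot assign secondary structure: missing backbone coordinates")
    }
    ss <- strrep("C", nrow(res))
  }
  chars <- strsplit(ss, "")[[1L]]
  if (length(chars) != nrow(res)) {
    stop("secondary-structure length (", length(chars),
         ") does not match residue count (", nrow(res), ")")
  }
  mol$atoms$secstruct <- chars[match(keys, res$key)]
  mol
}
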