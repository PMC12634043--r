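## Elastic-network generation: weak harmonic bonds between (by default)
## backbone beads within a distance cutoff, generated after the resolution
## transformation as pure post-processing.  The residue minimum distance
## (RMD) is a graph distance on the residue graph, so residues joined by
## e.g. a disulfide bridge count as close and are excluded just like
## sequence neighbours.

#' Elastic-network parameters
#'
#' @param upper_cutoff upper distance cutoff in nm.
#' @param lower_cutoff lower distance cutoff in nm.
#' @param force_constant harmonic force constant in kJ mol^-1 nm^-2.
#' @param rmd residue minimum distance (graph distance in residues).  The
#'   default 3 keeps the network from competing with the bonds, angles and
#'   dihedrals between backbone beads and is part of the protein model:
#'   it should not normally be changed.
#' @param selection predicate over a particle row, or character vector of
#'   eligible bead names; `NULL` selects the force field's backbone bead.
#' @param unit scope within which bonds may form: `"molecule"` (default),
#'   `"chain"`, `"all"`, or `"region"`.
#' @param regions list/matrix of inclusive resid ranges (unit `"region"`);
#'   a pair spanning two different ranges gets no bond.
#' @return an `en_params` list.
#' @export
en_params <- function(upper_cutoff = 0.9, lower_cutoff = 0.0,
                      force_constant = 700, rmd = 3L, selection = NULL,
                      unit = c("molecule", "chain", "all", "region"),
                      regions = NULL) {
  unit <- match.arg(unit)
  stopifnot(lower_cutoff >= 0, upper_cutoff >= lower_cutoff,
            force_constant >= 0, rmd >= 0)
  if (unit == "region" && !length(regions)) {
    stop("unit = 'region' needs at least one resid range")
  }
  if (unit != "region" && length(regions)) {
    stop("regions are only meaningful with unit = 'region'")
  }
  structure(list(upper_cutoff = upper_cutoff, lower_cutoff = lower_cutoff,
                 force_constant = force_constant, rmd = as.integer(rmd),
                 selection = selection, unit = unit, regions = regions),
            class = "en_params")
}

#' Residue graph of a molecule
#'
#' One node per residue; an edge wherever two residues share at least one
#' inter-particle bond — including disulfide bridges, so the RMD rule
#' excludes bridge partners without special cases.
#'
#' @param mol a [molgraph()].
#' @return list with `res` (residue table) and `graph` (igraph).
#' @export
residue_graph <- function(mol) {
  res <- residue_table(mol)
  keys <- residue_keys(mol)
  ridx <- match(keys, res$key)
  e <- mol$edges
  re <- cbind(ridx[e[, 1L]], ridx[e[, 2L]])
  re <- re[re[, 1L] != re[, 2L], , drop = FALSE]
  g <- igraph::make_graph(as.integer(t(unique(re))), n = nrow(res),
                          directed = FALSE)
  list(res = res, graph = g)
}

#' Select elastic-network-eligible beads
#'
#' @param mol a [molgraph()].
#' @param predicate `function(particle_row) -> logical`, a character vector
#'   of bead names, or `NULL` for the default backbone-bead name.
#' @param ff force field providing the `bb_bead` variable for the default.
#' @param ledger [warning_ledger()].
#' @return integer vector of particle ids (empty selection is a warning).
#' @export
select_beads <- function(mol, predicate = NULL, ff = NULL,
                         ledger = warning_ledger()) {
  if (is.null(predicate)) {
    bb <- if (!is.null(ff)) ff$variables$bb_bead %||% "BB" else "BB"
    predicate <- bb
  }
  sel <- if (is.character(predicate)) {
    which(mol$atoms$atom_name %in% predicate)
  } else {
    which(vapply(seq_len(nrow(mol$atoms)), function(i)
      isTRUE(predicate(mol$atoms[i, , drop = FALSE])), logical(1)))
  }
  # virtual sites never take part in the elastic network
  vs <- vapply(mol$interactions$virtual_sitesn %||% list(),
               function(ia) ia$particles[1L], integer(1))
  sel <- setdiff(sel, vs)
  if (!length(sel)) {
    ledger_add(ledger, "empty-selection", "empty elastic-network selection")
  }
  sel
}

region_of <- function(resid, regions) {
  for (k in seq_along(regions)) {
    r <- regions[[k]]
    if (resid >= r[1L] && resid <= r[2L]) return(k)
  }
  NA_integer_
}

#' Generate an elastic network
#'
#' Emits a harmonic bond (GROMACS bond type 6, which adds no exclusions,
#' so the network is a pure bias) for every unordered pair of eligible
#' beads whose distance lies within the cutoffs, whose residue-graph
#' distance is at least the RMD, and which share an EN unit.  The bond
#' length is the measured distance (rounded to 1e-5 nm for byte-stable
#' output).  EN bonds never become graph edges: molecule partitioning and
#' graph distances are unchanged.
#'
#' @param x a [molgraph()] or `cg_system` (unit `"all"` spans molecules).
#' @param params an [en_params()].
#' @param ff force field (default bead selection).
#' @param ledger [warning_ledger()].
#' @return list with `interactions` (per molecule, to attach with
#'   [en_apply()]), `intermolecular` (bond list with global indices, only
#'   for unit `"all"`), and `pairs` (data.frame of the emitted pairs with
#'   molecule index, resids and distance).
#' @export
generate_en <- function(x, params = en_params(), ff = NULL,
                        ledger = warning_ledger()) {
  system <- as_system(x)
  nm <- length(system$molecules)
  beads <- list(); rg <- list()
  for (i in seq_len(nm)) {
    # a molecule without eligible beads (e.g. a ligand) is simply not
    # biased; only a system-wide empty selection is worth a warning
    beads[[i]] <- select_beads(system$molecules[[i]], params$selection, ff,
                               warning_ledger())
    rg[[i]] <- residue_graph(system$molecules[[i]])
  }
  if (sum(lengths(beads)) == 0L) {
    ledger_add(ledger, "empty-selection", "empty elastic-network selection")
  }
  # global tables
  tab <- do.call(rbind, lapply(seq_len(nm), function(i) {
    m <- system$molecules[[i]]
    b <- beads[[i]]
    if (!length(b)) return(NULL)
    data.frame(mol = i, id = b, chain = m$atoms$chain[b],
               resid = m$atoms$resid[b],
               rnode = match(residue_keys(m)[b], rg[[i]]$res$key),
               x = m$atoms$x[b], y = m$atoms$y[b], z = m$atoms$z[b],
               stringsAsFactors = FALSE)
  }))
  interactions <- rep(list(list()), nm)
  inter <- list()
  pairs_out <- NULL
  if (!is.null(tab)) {
    nopos <- is.na(tab$x)
    if (any(nopos)) {
      for (i in which(nopos)) {
        ledger_add(ledger, "missing-coordinates",
                   "eligible bead without position skipped by the elastic network",
                   list(chain = tab$chain[i], resid = tab$resid[i]))
      }
      tab <- tab[!nopos, , drop = FALSE]
    }
  }
  n <- NROW(tab)
  if (n >= 2L) {
    # residue-graph distances per molecule (graph distance in residues)
    rdist <- lapply(seq_len(nm), function(i)
      igraph::distances(rg[[i]]$graph))
    for (a in seq_len(n - 1L)) {
      for (b in seq((a + 1L), n)) {
        same_mol <- tab$mol[a] == tab$mol[b]
        if (params$unit != "all" && !same_mol) next
        if (params$unit == "chain" && tab$chain[a] != tab$chain[b]) next
        if (params$unit == "region") {
          ra <- region_of(tab$resid[a], params$regions)
          rb <- region_of(tab$resid[b], params$regions)
          if (is.na(ra) || is.na(rb) || ra != rb) next
        }
        d <- sqrt((tab$x[a] - tab$x[b])^2 + (tab$y[a] - tab$y[b])^2 +
                    (tab$z[a] - tab$z[b])^2)
        if (d < params$lower_cutoff || d > params$upper_cutoff) next
        gd <- if (same_mol) {
          rdist[[tab$mol[a]]][tab$rnode[a], tab$rnode[b]]
        } else Inf
        if (gd < params$rmd) next
        ia <- bonded_interaction("bonds", c(tab$id[a], tab$id[b]),
                          c("6", sprintf("%.5f", d),
                            format(params$force_constant)),
                          meta = list(source = "elastic_network"))
        if (same_mol) {
          i <- tab$mol[a]
          interactions[[i]] <- c(interactions[[i]], list(ia))
        } else {
          inter[[length(inter) + 1L]] <- ia
        }
        pairs_out <- rbind(pairs_out, data.frame(
          mol_a = tab$mol[a], mol_b = tab$mol[b],
          chain_a = tab$chain[a], chain_b = tab$chain[b],
          resid_a = tab$resid[a], resid_b = tab$resid[b],
          distance = d, graph_distance = as.numeric(gd)))
      }
    }
  }
  list(interactions = interactions, intermolecular = inter,
       pairs = pairs_out)
}

#' Attach generated elastic-network bonds to a system
#'
#' @param system `cg_system` or [molgraph()].
#' @param en result of [generate_en()].
#' @return the system with EN interactions added (edges untouched).
#' @export
en_apply <- function(system, en) {
  single <- !inherits(system, "cg_system")
  system <- as_system(system)
  for (i in seq_along(system$molecules)) {
    if (length(en$interactions[[i]])) {
      system$molecules[[i]] <- add_interactions(system$molecules[[i]],
                                                en$interactions[[i]])
    }
  }
  if (single) system$molecules[[1L]] else system
}
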