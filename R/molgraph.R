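#' @importFrom stats setNames
#' @importFrom utils head tail
NULL

# Columns every particle table carries.  atom_name, resname and resid are the
# only mandatory attributes; everything else may be NA ("absent").
.MG_COLS <- c("atom_name", "resname", "resid", "chain", "element", "charge",
              "mass", "x", "y", "z", "particle_type", "secstruct")

#' Construct a molecule graph
#'
#' A `molgraph` is the universal currency of the pipeline: an undirected
#' graph of particles (atoms or coarse-grained beads) whose edges are bonded
#' connectivity, plus a list of bonded interaction terms.  Interaction
#' parameters are carried verbatim and never interpreted numerically except
#' where an operation states so (elastic-network generation).
#'
#' @param atoms data.frame with at least `atom_name`, `resname`, `resid`.
#'   Optional columns: `chain`, `element`, `charge`, `mass`, `x`, `y`, `z`
#'   (positions in nm; `NA` means the position is absent), `particle_type`,
#'   `secstruct`.
#' @param edges two-column integer matrix of particle indices (1-based rows
#'   of `atoms`), or `NULL` for no edges.
#' @param interactions named list keyed by interaction kind (GROMACS itp
#'   section names: `bonds`, `angles`, `dihedrals`, `constraints`,
#'   `exclusions`, `pairs`, `virtual_sitesn`, `position_restraints`), each a
#'   list of interactions as returned by [bonded_interaction()].
#' @param citations character vector of citation keys attached to the
#'   parameters used in this molecule.
#' @param forcefield name of the force field the molecule belongs to.
#' @param name optional moleculetype name.
#' @param nrexcl number of bonded-neighbour exclusions for itp output.
#' @return an object of class `molgraph`.
#' @export
molgraph <- function(atoms, edges = NULL, interactions = list(),
                     citations = character(), forcefield = NA_character_,
                     name = NA_character_, nrexcl = NA_integer_) {
  stopifnot(is.data.frame(atoms))
  need <- c("atom_name", "resname", "resid")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) {
    stop("particle table lacks required attribute(s): ",
         paste(miss, collapse = ", "))
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  defaults <- list(chain = "", element = NA_character_, charge = NA_real_,
                   mass = NA_real_, x = NA_real_, y = NA_real_, z = NA_real_,
                   particle_type = NA_character_, secstruct = NA_character_)
  for (col in names(defaults)) {
    if (is.null(atoms[[col]])) {
      atoms[[col]] <- rep(defaults[[col]], length.out = nrow(atoms))
    }
  }
  atoms$resid <- as.integer(atoms$resid)
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  bad <- xor(rowSums(is.na(pos)) > 0L, rowSums(is.na(pos)) == 3L) |
    rowSums(is.nan(pos) | is.infinite(pos)) > 0L
  if (any(bad)) {
    stop("positions must be finite 3-vectors or wholly absent; offending ",
         "particle(s): ", paste(which(bad), collapse = ", "))
  }
  rownames(atoms) <- NULL
  edges <- normalize_edges(edges, nrow(atoms))
  mol <- structure(
    list(atoms = atoms[, unique(c(.MG_COLS, names(atoms))), drop = FALSE],
         edges = edges,
         interactions = interactions,
         citations = unique(citations),
         forcefield = forcefield,
         name = name,
         nrexcl = nrexcl,
         residue_mods = list()),
    class = "molgraph")
  validate_interactions(mol)
  mol
}

normalize_edges <- function(edges, n) {
  if (is.null(edges) || NROW(edges) == 0L) {
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("a", "b"))))
  }
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (any(edges < 1L | edges > n)) stop("edge references unknown particle")
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loop edge not allowed")
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
  edges <- unique(edges)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("a", "b"))
  edges
}

# Minimum particle counts per interaction kind (itp section names).
.KIND_MIN <- c(bonds = 2L, angles = 3L, dihedrals = 4L, constraints = 2L,
               exclusions = 2L, pairs = 2L, virtual_sitesn = 2L,
               position_restraints = 1L)
.KIND_EXACT <- c(bonds = 2L, angles = 3L, dihedrals = 4L, constraints = 2L,
                 pairs = 2L, position_restraints = 1L)

#' Build one bonded interaction term
#'
#' @param kind interaction kind (itp section name, e.g. `"bonds"`).
#' @param particles integer vector of particle ids, in force-field order.
#' @param parameters character vector of parameters, passed through verbatim.
#' @param meta named list of metadata (e.g. `source = "elastic_network"`).
#' @return a list of class `interaction`.
#' @export
bonded_interaction <- function(kind, particles, parameters = character(),
                        meta = list()) {
  structure(list(kind = kind, particles = as.integer(particles),
                 parameters = as.character(parameters), meta = meta),
            class = "interaction")
}

validate_interactions <- function(mol) {
  n <- nrow(mol$atoms)
  for (kind in names(mol$interactions)) {
    for (ia in mol$interactions[[kind]]) {
      if (any(ia$particles < 1L | ia$particles > n)) {
        stop("interaction of kind '", kind, "' references unknown particle")
      }
      if (!is.na(.KIND_EXACT[kind]) && length(ia$particles) != .KIND_EXACT[kind]) {
        stop("interaction of kind '", kind, "' needs ", .KIND_EXACT[kind],
             " particles, got ", length(ia$particles))
      }
      if (!is.na(.KIND_MIN[kind]) && length(ia$particles) < .KIND_MIN[kind]) {
        stop("interaction of kind '", kind, "' needs at least ",
             .KIND_MIN[kind], " particles")
      }
    }
  }
  invisible(mol)
}

#' Add interactions to a molecule
#'
#' Same-kind interactions over the same particle tuple (up to reversal)
#' replace the existing term, so re-applying a link is idempotent.
#'
#' @param mol a [molgraph()].
#' @param ias list of [bonded_interaction()] objects.
#' @return the updated molecule.
#' @export
add_interactions <- function(mol, ias) {
  for (ia in ias) {
    kind <- ia$kind
    existing <- mol$interactions[[kind]]
    key <- canonical_tuple(ia$particles)
    replaced <- FALSE
    if (!is.null(existing)) {
      for (i in seq_along(existing)) {
        if (identical(canonical_tuple(existing[[i]]$particles), key)) {
          existing[[i]] <- ia
          replaced <- TRUE
          break
        }
      }
    }
    if (!replaced) existing <- c(existing, list(ia))
    mol$interactions[[kind]] <- existing
  }
  validate_interactions(mol)
  mol
}

canonical_tuple <- function(p) {
  r <- rev(p)
  if (paste(r, collapse = ",") < paste(p, collapse = ",")) r else p
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph%s: %d particles, %d edges, %d residues>\n",
              if (is.na(x$name)) "" else paste0(" ", x$name),
              nrow(x$atoms), nrow(x$edges),
              length(unique(residue_keys(x)))))
  nia <- vapply(x$interactions, length, integer(1))
  if (length(nia)) {
    cat("  interactions:",
        paste(sprintf("%s=%d", names(nia), nia), collapse = ", "), "\n")
  }
  invisible(x)
}

# "chain|resid|icode" composite residue key, one per particle.
residue_keys <- function(mol) {
  at <- mol$atoms
  icode <- if (!is.null(at$icode)) at$icode else ""
  paste(at$chain, at$resid, icode, sep = "|")
}

adjacency_list <- function(n, edges) {
  adj <- rep(list(integer()), n)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1L]; b <- edges[i, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  lapply(adj, sort)
}

mg_igraph <- function(n, edges) {
  igraph::make_graph(edges = as.integer(t(edges)), n = n, directed = FALSE)
}

#' Partition a particle graph into molecules
#'
#' All particles connected by bonds form one molecule: two protein chains
#' joined by a disulfide bridge are a single molecule, while a cofactor that
#' only interacts non-bondedly is a separate one.  Components are returned
#' as separate molecules with particle ids renumbered contiguously; the
#' order-preserving old-to-new index map is kept in attribute `index_map`.
#'
#' @param mol a [molgraph()] (possibly disconnected).
#' @return list of connected `molgraph`s, ordered by their lowest original
#'   particle index.  Each carries attributes `orig_index` (new -> old) and
#'   `index_map` (old -> new, NA outside the component).
#' @export
connected_components <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 0L) return(list())
  comp <- igraph::components(mg_igraph(n, mol$edges))$membership
  first <- tapply(seq_len(n), comp, min)
  out <- list()
  for (cid in as.integer(names(sort(first)))) {
    keep <- which(comp == cid)
    out[[length(out) + 1L]] <- subset_molgraph(mol, keep)
  }
  out
}

#' Extract a particle subset as an induced subgraph
#'
#' Keeps the particles in `keep` (ascending original order) with the
#' induced edges and any interactions lying fully inside the subset.
#' Attribute `orig_index` maps new to old ids and `index_map` old to new.
#'
#' @param mol a [molgraph()].
#' @param keep integer vector of particle ids.
#' @return a [molgraph()].
#' @export
subset_molgraph <- function(mol, keep) {
  keep <- sort(unique(as.integer(keep)))
  map <- rep(NA_integer_, nrow(mol$atoms))
  map[keep] <- seq_along(keep)
  edges <- mol$edges
  if (nrow(edges)) {
    inside <- !is.na(map[edges[, 1L]]) & !is.na(map[edges[, 2L]])
    edges <- cbind(map[edges[inside, 1L]], map[edges[inside, 2L]])
  } else {
    edges <- NULL
  }
  ias <- list()
  for (kind in names(mol$interactions)) {
    sel <- Filter(function(ia) all(!is.na(map[ia$particles])),
                  mol$interactions[[kind]])
    if (length(sel)) {
      ias[[kind]] <- lapply(sel, function(ia) {
        ia$particles <- map[ia$particles]
        ia
      })
    }
  }
  sub <- molgraph(mol$atoms[keep, , drop = FALSE], edges, ias,
                  mol$citations, mol$forcefield, mol$name, mol$nrexcl)
  sub$residue_mods <- mol$residue_mods
  attr(sub, "orig_index") <- keep
  attr(sub, "index_map") <- map
  sub
}

#' Shortest-path graph distance between two particles
#'
#' @param mol a [molgraph()].
#' @param a,b particle ids.
#' @param via which edges count: `"edges"` (the molecule's bonded edge set,
#'   default) or a character vector of interaction kinds whose particle
#'   pairs/paths define edges (consecutive particles of each interaction).
#' @return non-negative integer path length, or `Inf` if disconnected under
#'   the chosen edge selector.
#' @export
graph_distance <- function(mol, a, b, via = "edges") {
  n <- nrow(mol$atoms)
  for (id in c(a, b)) {
    if (is.na(id) || id < 1L || id > n) {
      stop("unknown particle id: ", id)
    }
  }
  if (identical(via, "edges")) {
    edges <- mol$edges
  } else {
    pairs <- list()
    for (kind in via) {
      for (ia in mol$interactions[[kind]]) {
        p <- ia$particles
        if (length(p) >= 2L) {
          pairs[[length(pairs) + 1L]] <- cbind(head(p, -1L), tail(p, -1L))
        }
      }
    }
    edges <- normalize_edges(do.call(rbind, pairs), n)
  }
  d <- igraph::distances(mg_igraph(n, edges), v = a, to = b)[1L, 1L]
  if (is.infinite(d)) Inf else as.integer(d)
}
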