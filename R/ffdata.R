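## Force-field fragment data: Blocks, Links, Modifications, Mappings and the
## parsers/writers for the fragment dialect, backwards-style mappings and
## GROMACS .rtp files.  The dialect is line based and GROMACS-flavoured
## (bracketed directives, ';'/'#' comments, whitespace-separated fields) so
## the data files can be checked, made and modified by users.

# ---- tokenizing ------------------------------------------------------------

num_or_na <- function(x) {
  if (x %in% c("-", "*", "")) NA_real_ else as.numeric(x)
}

strip_comment <- function(line) {
  line <- sub("\r$", "", line)
  sub("[;#].*$", "", line)
}

tokenize_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  raw <- vapply(text, strip_comment, character(1), USE.NAMES = FALSE)
  keep <- which(nzchar(trimws(raw)))
  list(tokens = lapply(raw[keep], function(l) strsplit(trimws(l), "[ \t]+")[[1]]),
       lineno = keep)
}

is_directive <- function(tok) {
  length(tok) >= 1L && grepl("^\\[", tok[1L])
}

directive_name <- function(tok) {
  tolower(gsub("\\[|\\]", "", paste(tok, collapse = "")))
}

# interaction sections: how many leading tokens are particle references
.SECTION_ARITY <- c(bonds = 2L, angles = 3L, dihedrals = 4L, impropers = 4L,
                    constraints = 2L, pairs = 2L, position_restraints = 1L)
.INTERACTION_SECTIONS <- c(names(.SECTION_ARITY), "exclusions", "virtual_sitesn")

parse_interaction_line <- function(section, tok, resolve, lineno) {
  if (section == "exclusions") {
    particles <- vapply(tok, resolve, integer(1))
    return(bonded_interaction("exclusions", particles))
  }
  if (section == "virtual_sitesn") {
    if (length(tok) < 3L) stop("line ", lineno, ": virtual_sitesn needs site, function and constructors")
    particles <- vapply(tok[-2L], resolve, integer(1))
    return(bonded_interaction("virtual_sitesn", particles, parameters = tok[2L]))
  }
  arity <- .SECTION_ARITY[[section]]
  if (length(tok) < arity) {
    stop("line ", lineno, ": [", section, "] needs ", arity, " particles")
  }
  particles <- vapply(tok[seq_len(arity)], resolve, integer(1))
  kind <- if (section == "impropers") "dihedrals" else section
  ia <- bonded_interaction(kind, particles, parameters = tok[-seq_len(arity)])
  if (section == "impropers") ia$meta$improper <- TRUE
  ia
}

# ---- constructors ----------------------------------------------------------

#' Force-field block: the canonical graph of one residue / repeat unit
#'
#' @param name residue (monomeric-repeat-unit) name, unique per force field.
#' @param graph a [molgraph()] of the canonical particles; interactions
#'   attached to the graph are the intra-fragment terms.
#' @param nrexcl exclusion count for itp output.
#' @param citations citation keys.
#' @export
ff_block <- function(name, graph, nrexcl = NA_integer_, citations = character()) {
  structure(list(name = name, graph = graph, nrexcl = nrexcl,
                 citations = citations), class = "ff_block")
}

#' Force-field link: inter-residue interaction pattern
#'
#' Pattern nodes carry attribute matchers; `offset` is the residue offset
#' relative to the anchor residue (offset 0), or `NA` for "any residue"
#' (wildcard links are matched purely by graph edges, which is how e.g. a
#' disulfide bond between arbitrary residues is expressed).
#'
#' @param atoms data.frame with columns `id`, `offset`, `atom_name`,
#'   `resnames` (list column of name vectors, `"*"` = any), `secstruct`.
#' @param edges two-column matrix of pattern-node ids that must be bonded.
#' @param add_interactions interactions to create (particles are pattern ids).
#' @param remove_interactions list of `list(kind=, particles=ids)` patterns
#'   to delete.
#' @param edits list of `list(id=, attr=, value=)` node-attribute edits.
#' @param citations citation keys.
#' @export
ff_link <- function(atoms, edges = NULL, add_interactions = list(),
                    remove_interactions = list(), edits = list(),
                    citations = character()) {
  offs <- atoms$offset[!is.na(atoms$offset)]
  if (length(offs)) {
    rng <- range(offs)
    if (!setequal(offs, seq(rng[1], rng[2]))) {
      stop("link resid offsets must form a contiguous window, got {",
           paste(sort(unique(offs)), collapse = ","), "}")
    }
  }
  edges <- if (is.null(edges)) matrix(integer(), ncol = 2L) else
    matrix(as.integer(edges), ncol = 2L)
  for (ia in add_interactions) {
    if (!all(ia$particles %in% atoms$id)) {
      stop("link interaction references undeclared pattern node")
    }
  }
  structure(list(atoms = atoms, edges = edges,
                 add_interactions = add_interactions,
                 remove_interactions = remove_interactions,
                 edits = edits, citations = citations),
            class = "ff_link")
}

#' Force-field modification: a delta to a canonical residue
#'
#' Describes changes relative to the canonical block, e.g. a different
#' protonation state, a terminus, or a post-translational modification:
#' added particles, the anchor particles they attach to, attribute edits,
#' and edits to the bead assignment at the target resolution.
#'
#' @param name modification name.
#' @param resnames canonical residue names it applies to.
#' @param atoms data.frame with `atom_name`, `element`, `role`
#'   (`"anchor"`/`"added"`).
#' @param edges two-column character matrix of atom-name pairs.
#' @param attribute_edits list of `list(atom=, attr=, value=)`.
#' @param bead_edits list of `list(bead=, attr=, value=)` applied to target
#'   beads of the residue.
#' @param atom_assign list of `list(atom=, bead=, weight=)` extending the
#'   base mapping with the added atoms.
#' @param add_interactions interactions referencing modification atom names.
#' @param citations citation keys.
#' @export
ff_modification <- function(name, resnames, atoms,
                            edges = matrix(character(), ncol = 2L),
                            attribute_edits = list(), bead_edits = list(),
                            atom_assign = list(), add_interactions = list(),
                            citations = character()) {
  added <- atoms$atom_name[atoms$role == "added"]
  anchors <- atoms$atom_name[atoms$role == "anchor"]
  # every added node must reach an anchor through modification edges
  if (length(added)) {
    if (!length(anchors)) stop("modification '", name, "' has added atoms but no anchor")
    reach <- anchors
    repeat {
      nxt <- unique(c(reach,
                      edges[edges[, 1L] %in% reach, 2L],
                      edges[edges[, 2L] %in% reach, 1L]))
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    lost <- setdiff(added, reach)
    if (length(lost)) {
      stop("modification '", name, "' added atom(s) not connected to an anchor: ",
           paste(lost, collapse = ", "))
    }
  }
  structure(list(name = name, resnames = resnames, atoms = atoms,
                 edges = edges, attribute_edits = attribute_edits,
                 bead_edits = bead_edits, atom_assign = atom_assign,
                 add_interactions = add_interactions, citations = citations),
            class = "ff_modification")
}

#' Resolution mapping: one fragment at two resolutions
#'
#' @param name name of the target-resolution block the fragment maps onto.
#' @param scope residue names (possibly several, in sequence order) the
#'   mapping spans at the source resolution.
#' @param beads target bead names, in block order.
#' @param atoms data.frame with `residx` (1-based position in `scope`),
#'   `atom_name`, and `weights` (list column: named numeric, bead -> weight).
#' @param from_ff,to_ff names of the source/target force fields.
#' @export
ff_mapping <- function(name, scope, beads, atoms,
                       from_ff = NA_character_, to_ff = NA_character_) {
  for (w in atoms$weights) {
    if (any(w < 0) || any(!is.finite(w))) stop("mapping weights must be finite and >= 0")
    unknown <- setdiff(names(w), beads)
    if (length(unknown)) {
      stop("mapping '", name, "' names bead(s) absent from the target block: ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(list(name = name, scope = scope, beads = beads, atoms = atoms,
                 from_ff = from_ff, to_ff = to_ff), class = "ff_mapping")
}

#' Force field: collection of blocks, links, modifications and variables
#'
#' @param name force-field name.
#' @param blocks named list of [ff_block()].
#' @param links ordered list of [ff_link()] (file order = precedence).
#' @param modifications named list of [ff_modification()].
#' @param aliases named list: input resname -> `list(block=, mods=)`,
#'   covering e.g. CHARMM/AMBER protonation-state naming (HSP/HIP and the
#'   like) as data, not code.
#' @param variables named list of character vectors (e.g. `backbone`,
#'   `bb_bead`, `nter_mod`, `cter_mod`).
#' @export
forcefield <- function(name, blocks = list(), links = list(),
                       modifications = list(), aliases = list(),
                       variables = list()) {
  if (anyDuplicated(names(blocks))) stop("duplicate block name in force field")
  structure(list(name = name, blocks = blocks, links = links,
                 modifications = modifications, aliases = aliases,
                 variables = variables), class = "forcefield")
}

#' @export
print.forcefield <- function(x, ...) {
  cat(sprintf("<forcefield %s: %d blocks, %d links, %d modifications>\n",
              x$name, length(x$blocks), length(x$links),
              length(x$modifications)))
  invisible(x)
}

# ---- fragment-file parser --------------------------------------------------

#' Parse a fragment file (blocks, links, modifications)
#'
#' The dialect is documented in the package vignette.  Top-level directives
#' `[ block ]`, `[ link ]`, `[ modification ]`, `[ variables ]`, and
#' `[ aliases ]` open entries; within an entry, GROMACS-style sections
#' (`[ atoms ]`, `[ bonds ]`, ...) fill it in.  Unknown sections are skipped
#' with a diagnostic; duplicate block names and interactions referencing
#' undeclared atoms are errors.
#'
#' @param text character vector of lines (or one string with newlines).
#' @param name force-field name to attach.
#' @return a [forcefield()]; parser diagnostics (skipped sections) are in
#'   attribute `diagnostics`.
#' @export
parse_fragment_text <- function(text, name = "unnamed") {
  tk <- tokenize_lines(text)
  toks <- tk$tokens; linenos <- tk$lineno
  blocks <- list(); links <- list(); modifications <- list()
  aliases <- list(); variables <- list(); diagnostics <- character()

  i <- 1L
  n <- length(toks)
  ctx <- NULL      # current top-level entry ("block", "link", "modification",
                   # "variables", "aliases")
  section <- NULL  # current subsection within the entry
  cur <- NULL      # accumulator for the current entry

  flush_entry <- function() {
    if (is.null(ctx) || ctx %in% c("variables", "aliases")) return()
    if (ctx == "block") {
      if (is.null(cur$name)) stop("block without a name")
      if (cur$name %in% names(blocks)) stop("duplicate block name: ", cur$name)
      if (!nrow(cur$atoms)) stop("block '", cur$name, "' has no atoms")
      edges <- cur$edges
      for (ia in cur$interactions) {
        if (ia$kind %in% c("bonds", "constraints")) {
          edges <- rbind(edges, ia$particles)
        }
      }
      g <- molgraph(cur$atoms, edges, cur$interactions)
      blocks[[cur$name]] <<- ff_block(cur$name, g, cur$nrexcl, cur$citations)
    } else if (ctx == "link") {
      if (is.null(cur$atoms) || !nrow(cur$atoms)) stop("link without atoms")
      links[[length(links) + 1L]] <<-
        ff_link(cur$atoms, cur$edges_ids, cur$interactions,
                cur$remove, cur$edits, cur$citations)
    } else if (ctx == "modification") {
      if (is.null(cur$name)) stop("modification without a name")
      modifications[[cur$name]] <<-
        ff_modification(cur$name, cur$resnames, cur$atoms, cur$edges_names,
                        cur$attribute_edits, cur$bead_edits, cur$atom_assign,
                        cur$interactions, cur$citations)
    }
  }
  new_entry <- function(kind) {
    flush_entry()
    ctx <<- kind
    section <<- NULL
    cur <<- list(name = NULL, resnames = character(),
                 atoms = data.frame(), edges = NULL,
                 edges_ids = NULL,
                 edges_names = matrix(character(), ncol = 2L),
                 interactions = list(), remove = list(), edits = list(),
                 attribute_edits = list(), bead_edits = list(),
                 atom_assign = list(), citations = character(),
                 nrexcl = NA_integer_)
  }

  resolve_block_atom <- function(nm, lineno) {
    idx <- match(nm, cur$atoms$atom_name)
    if (is.na(idx)) {
      stop("line ", lineno, ": interaction references undeclared atom '", nm,
           "' in block '", cur$name %||% "?", "'")
    }
    idx
  }

  while (i <= n) {
    tok <- toks[[i]]; lineno <- linenos[i]
    if (is_directive(tok)) {
      d <- directive_name(tok)
      if (d %in% c("block", "link", "modification", "variables", "aliases",
                   "moleculetype")) {
        new_entry(if (d == "moleculetype") "block" else d)
      } else if (is.null(ctx)) {
        stop("line ", lineno, ": section [", d, "] outside any entry")
      } else if (d %in% c(.INTERACTION_SECTIONS, "atoms", "edges", "remove",
                          "edits", "bead-edits", "mapping")) {
        section <- d
      } else {
        diagnostics <- c(diagnostics,
                         sprintf("line %d: unknown directive [%s], section skipped",
                                 lineno, d))
        section <- ".skip"
      }
      i <- i + 1L
      next
    }
    if (is.null(ctx)) stop("line ", lineno, ": content outside any entry")
    if (identical(section, ".skip")) { i <- i + 1L; next }

    if (ctx == "variables") {
      variables[[tok[1L]]] <- tok[-1L]
    } else if (ctx == "aliases") {
      aliases[[tok[1L]]] <- list(block = tok[2L],
                                 mods = if (length(tok) > 2L) tok[-(1:2)] else character())
    } else if (is.null(section)) {
      # header lines of the entry: key value...
      key <- tolower(tok[1L])
      if (key == "name") cur$name <- tok[2L]
      else if (key %in% c("resname", "resnames")) {
        cur$resnames <- unlist(strsplit(tok[-1L], ",", fixed = TRUE))
      } else if (key == "citation") cur$citations <- c(cur$citations, tok[-1L])
      else if (key == "nrexcl") cur$nrexcl <- as.integer(tok[2L])
      else if (ctx == "block" && length(tok) >= 1L && is.null(cur$name)) {
        cur$name <- tok[1L]  # bare name line right after [ block ]
      } else stop("line ", lineno, ": unexpected entry header '", tok[1L], "'")
    } else if (section == "atoms") {
      if (ctx == "block") {
        if (length(tok) < 3L) stop("line ", lineno, ": block atom needs name element type")
        row <- data.frame(atom_name = tok[1L], resname = cur$name %||% "",
                          resid = 1L,
                          element = if (tok[2L] %in% c("-", "*")) NA_character_ else tok[2L],
                          particle_type = if (tok[3L] %in% c("-", "*")) NA_character_ else tok[3L],
                          charge = if (length(tok) >= 4L) num_or_na(tok[4L]) else NA_real_,
                          mass = if (length(tok) >= 5L) num_or_na(tok[5L]) else NA_real_,
                          stringsAsFactors = FALSE)
        cur$atoms <- rbind(cur$atoms, row)
      } else if (ctx == "link") {
        if (length(tok) < 3L) stop("line ", lineno, ": link atom needs id offset name")
        off <- if (tok[2L] == "?") NA_integer_ else as.integer(tok[2L])
        if (!tok[2L] == "?" && is.na(off)) stop("line ", lineno, ": bad offset '", tok[2L], "'")
        row <- data.frame(id = as.integer(tok[1L]), offset = off,
                          atom_name = tok[3L], stringsAsFactors = FALSE)
        row$resnames <- list(if (length(tok) >= 4L)
          unlist(strsplit(tok[4L], ",", fixed = TRUE)) else "*")
        row$secstruct <- if (length(tok) >= 5L) tok[5L] else "*"
        cur$atoms <- rbind(cur$atoms, row)
      } else { # modification
        if (length(tok) < 3L) stop("line ", lineno, ": modification atom needs name element role")
        if (!tok[3L] %in% c("anchor", "added")) {
          stop("line ", lineno, ": modification atom role must be anchor or added")
        }
        cur$atoms <- rbind(cur$atoms,
                           data.frame(atom_name = tok[1L],
                                      element = if (tok[2L] %in% c("-", "*")) NA_character_ else tok[2L],
                                      role = tok[3L], stringsAsFactors = FALSE))
      }
    } else if (section == "edges") {
      if (ctx == "link") {
        cur$edges_ids <- rbind(cur$edges_ids, as.integer(tok[1:2]))
      } else if (ctx == "modification") {
        cur$edges_names <- rbind(cur$edges_names, tok[1:2])
      } else {
        cur$edges <- rbind(cur$edges,
                           c(resolve_block_atom(tok[1L], lineno),
                             resolve_block_atom(tok[2L], lineno)))
      }
    } else if (section == "remove") {
      cur$remove[[length(cur$remove) + 1L]] <-
        list(kind = tok[1L], particles = as.integer(tok[-1L]))
    } else if (section == "edits") {
      if (ctx == "modification") {
        cur$attribute_edits[[length(cur$attribute_edits) + 1L]] <-
          list(atom = tok[1L], attr = tok[2L], value = tok[3L])
      } else {
        cur$edits[[length(cur$edits) + 1L]] <-
          list(id = as.integer(tok[1L]), attr = tok[2L], value = tok[3L])
      }
    } else if (section == "bead-edits") {
      cur$bead_edits[[length(cur$bead_edits) + 1L]] <-
        list(bead = tok[1L], attr = tok[2L], value = tok[3L])
    } else if (section == "mapping") {
      cur$atom_assign[[length(cur$atom_assign) + 1L]] <-
        list(atom = tok[1L], bead = tok[2L],
             weight = if (length(tok) >= 3L) as.numeric(tok[3L]) else 0)
    } else if (section %in% .INTERACTION_SECTIONS) {
      resolver <- if (ctx == "block") {
        function(nm) resolve_block_atom(nm, lineno)
      } else if (ctx == "link") {
        function(nm) {
          id <- as.integer(nm)
          if (is.na(id) || !(id %in% cur$atoms$id)) {
            stop("line ", lineno, ": link interaction references undeclared node '", nm, "'")
          }
          id
        }
      } else {
        function(nm) {
          idx <- match(nm, cur$atoms$atom_name)
          if (is.na(idx)) stop("line ", lineno,
                               ": modification interaction references undeclared atom '", nm, "'")
          idx
        }
      }
      ia <- parse_interaction_line(section, tok, resolver, lineno)
      cur$interactions[[length(cur$interactions) + 1L]] <- ia
    }
    i <- i + 1L
  }
  flush_entry()

  # block interactions were collected as a flat list; regroup by kind
  for (bn in names(blocks)) {
    g <- blocks[[bn]]$graph
    flat <- g$interactions
    if (length(flat) && is.null(names(flat))) {
      grouped <- list()
      for (ia in flat) grouped[[ia$kind]] <- c(grouped[[ia$kind]], list(ia))
      g$interactions <- grouped
      blocks[[bn]]$graph <- g
    }
  }
  ff <- forcefield(name, blocks, links, modifications, aliases, variables)
  attr(ff, "diagnostics") <- diagnostics
  ff
}

# Block entries accumulate interactions as a flat list during parsing; links
# keep them flat (applied in order).  parse_fragment_file reads a file.

#' @rdname parse_fragment_text
#' @param path file path.
#' @export
parse_fragment_file <- function(path, name = sub("\\.ff$", "", basename(path))) {
  parse_fragment_text(readLines(path, warn = FALSE), name = name)
}

# ---- mapping parser --------------------------------------------------------

#' Parse backwards-style mapping text
#'
#' Atom lines list a source atom and one or more target bead names; the
#' files carry no weights, so a shared atom's unit weight is split equally
#' across the listed beads.  Hydrogens (element H by name) default to zero
#' weight unless an explicit weight is given, because beads are defined on
#' heavy atoms.  A `[ scope ]` section declares multi-residue spans.
#'
#' @param text character vector of lines.
#' @return list of [ff_mapping()].
#' @export
parse_mapping_text <- function(text) {
  tk <- tokenize_lines(text)
  toks <- tk$tokens; linenos <- tk$lineno
  maps <- list()
  cur <- NULL; section <- NULL
  flush_map <- function() {
    if (is.null(cur)) return()
    atoms <- cur$atoms
    if (is.null(atoms) || !nrow(atoms)) stop("mapping '", cur$name, "' has no atoms")
    maps[[length(maps) + 1L]] <<-
      ff_mapping(cur$name, cur$scope %||% cur$name, cur$beads, atoms,
                 cur$from %||% NA_character_, cur$to %||% NA_character_)
  }
  for (i in seq_along(toks)) {
    tok <- toks[[i]]; lineno <- linenos[i]
    if (is_directive(tok)) {
      d <- directive_name(tok)
      if (d == "molecule") { flush_map(); cur <- list(); section <- "molecule" }
      else if (d %in% c("from", "to", "scope", "martini", "atoms")) section <- d
      else stop("line ", lineno, ": unknown mapping directive [", d, "]")
      next
    }
    if (is.null(cur)) stop("line ", lineno, ": content before [ molecule ]")
    if (section == "molecule") cur$name <- tok[1L]
    else if (section == "from") cur$from <- tok[1L]
    else if (section == "to") cur$to <- tok[1L]
    else if (section == "scope") cur$scope <- tok
    else if (section == "martini") cur$beads <- c(cur$beads, tok)
    else if (section == "atoms") {
      multi <- length(cur$scope %||% "x") > 1L
      # idx [residx] name bead... [weight]
      ptr <- 2L
      residx <- 1L
      if (multi) { residx <- as.integer(tok[2L]); ptr <- 3L }
      nm <- tok[ptr]
      rest <- tok[-seq_len(ptr)]
      wtot <- NA_real_
      if (length(rest) && !is.na(suppressWarnings(as.numeric(rest[length(rest)])))) {
        wtot <- as.numeric(rest[length(rest)])
        rest <- rest[-length(rest)]
      }
      beads <- rest
      if (is.na(wtot)) {
        wtot <- if (grepl("^[0-9]*H", nm)) 0 else 1
      }
      row <- data.frame(residx = residx, atom_name = nm, stringsAsFactors = FALSE)
      row$weights <- list(setNames(rep(wtot / max(length(beads), 1L),
                                       length(beads)), beads))
      cur$atoms <- rbind(cur$atoms, row)
    }
  }
  flush_map()
  maps
}

#' @rdname parse_mapping_text
#' @param path file path.
#' @export
parse_mapping_file <- function(path) parse_mapping_text(readLines(path, warn = FALSE))

# ---- rtp parser ------------------------------------------------------------

#' Parse a GROMACS .rtp residue-topology file
#'
#' Returns one block per residue section.  Bonds with `+`/`-` atom-name
#' prefixes are converted into inter-residue links with resid offsets
#' +1/-1; identical link signatures from different residues are merged by
#' taking the union of applicable residue names.
#'
#' @param text character vector of lines.
#' @param name force-field name for the result.
#' @return a [forcefield()] with blocks and links; `variables$bondedtypes`
#'   holds the `[bondedtypes]` row verbatim.
#' @export
parse_rtp_text <- function(text, name = "rtp") {
  tk <- tokenize_lines(text)
  toks <- tk$tokens; linenos <- tk$lineno
  bondedtypes <- character()
  blocks <- list()
  raw_links <- list()  # signature -> list(resnames, atoms(offset,name), section, params)
  resname <- NULL; section <- NULL
  atoms <- NULL; ias <- list()
  flush_res <- function() {
    if (is.null(resname)) return()
    if (is.null(atoms) || !nrow(atoms)) {
      stop("residue '", resname, "' lacks an [atoms] section")
    }
    grouped <- list()
    for (ia in ias) grouped[[ia$kind]] <- c(grouped[[ia$kind]], list(ia))
    edges <- NULL
    for (ia in grouped$bonds) edges <- rbind(edges, ia$particles)
    g <- molgraph(atoms, edges, grouped)
    blocks[[resname]] <<- ff_block(resname, g)
  }
  rtp_sections <- c(atoms = "atoms", bonds = "bonds", angles = "angles",
                    dihedrals = "dihedrals", impropers = "impropers",
                    exclusions = "exclusions")
  for (i in seq_along(toks)) {
    tok <- toks[[i]]; lineno <- linenos[i]
    if (is_directive(tok)) {
      d <- directive_name(tok)
      if (d == "bondedtypes") { section <- "bondedtypes" }
      else if (d %in% names(rtp_sections)) {
        if (is.null(resname)) stop("line ", lineno, ": [", d, "] before any residue")
        section <- d
      } else {
        flush_res()
        resname <- gsub("\\[|\\]", "", paste(tok, collapse = ""))
        atoms <- NULL; ias <- list(); section <- NULL
      }
      next
    }
    if (identical(section, "bondedtypes")) { bondedtypes <- tok; next }
    if (is.null(resname) || is.null(section)) next
    if (section == "atoms") {
      row <- data.frame(atom_name = tok[1L], resname = resname, resid = 1L,
                        element = element_from_name(tok[1L]),
                        particle_type = tok[2L],
                        charge = if (length(tok) >= 3L) as.numeric(tok[3L]) else NA_real_,
                        stringsAsFactors = FALSE)
      atoms <- rbind(atoms, row)
    } else {
      arity <- if (section %in% c("bonds", "exclusions")) 2L else
        if (section == "angles") 3L else 4L
      refs <- tok[seq_len(arity)]
      params <- tok[-seq_len(arity)]
      offs <- vapply(refs, function(r) {
        if (startsWith(r, "-")) -1L else if (startsWith(r, "+")) 1L else 0L
      }, integer(1))
      names_clean <- sub("^[+-]", "", refs)
      if (any(offs != 0L)) {
        sig <- paste(section, paste(offs, names_clean, collapse = " "),
                     paste(params, collapse = " "), sep = "|")
        if (is.null(raw_links[[sig]])) {
          raw_links[[sig]] <- list(resnames = character(), offsets = offs,
                                   names = names_clean, section = section,
                                   params = params)
        }
        raw_links[[sig]]$resnames <- union(raw_links[[sig]]$resnames, resname)
      } else {
        idx <- match(names_clean, atoms$atom_name)
        if (anyNA(idx)) {
          stop("line ", lineno, ": interaction references undeclared atom '",
               names_clean[which(is.na(idx))[1L]], "' in residue '", resname, "'")
        }
        kind <- if (section == "impropers") "dihedrals" else section
        ia <- bonded_interaction(kind, idx, params)
        if (section == "impropers") ia$meta$improper <- TRUE
        ias[[length(ias) + 1L]] <- ia
      }
    }
  }
  flush_res()
  links <- lapply(raw_links, function(rl) {
    at <- data.frame(id = seq_along(rl$names), offset = rl$offsets,
                     atom_name = rl$names, stringsAsFactors = FALSE)
    at$resnames <- lapply(seq_along(rl$names), function(k) {
      if (rl$offsets[k] == 0L) rl$resnames else "*"
    })
    at$secstruct <- "*"
    kind <- if (rl$section == "impropers") "dihedrals" else rl$section
    ia <- bonded_interaction(kind, at$id, rl$params)
    if (rl$section == "impropers") ia$meta$improper <- TRUE
    edges <- if (rl$section == "bonds") matrix(at$id[1:2], ncol = 2L) else NULL
    ff_link(at, edges, list(ia))
  })
  names(links) <- NULL
  forcefield(name, blocks, links,
             variables = list(bondedtypes = bondedtypes))
}

#' @rdname parse_rtp_text
#' @param path file path.
#' @export
parse_rtp_file <- function(path, name = sub("\\.rtp$", "", basename(path))) {
  parse_rtp_text(readLines(path, warn = FALSE), name = name)
}

# ---- validation ------------------------------------------------------------

#' Cross-check a force field against a mapping set
#'
#' Diagnostics only, never mutates: reports blocks with no mapping,
#' mappings naming unknown blocks, and links whose residue-name matchers
#' match no block.
#'
#' @param ff a [forcefield()] (target resolution).
#' @param mappings list of [ff_mapping()].
#' @return character vector of diagnostics (empty when consistent).
#' @export
validate_forcefield <- function(ff, mappings) {
  diags <- character()
  mapped <- vapply(mappings, function(m) m$name, character(1))
  for (bn in names(ff$blocks)) {
    if (!(bn %in% mapped)) diags <- c(diags, sprintf("block '%s' has no mapping", bn))
  }
  for (m in mappings) {
    if (!(m$name %in% names(ff$blocks))) {
      diags <- c(diags, sprintf("mapping '%s' targets unknown block", m$name))
    }
  }
  for (k in seq_along(ff$links)) {
    rn <- unique(unlist(ff$links[[k]]$atoms$resnames))
    rn <- setdiff(rn, "*")
    if (length(rn) && !any(rn %in% names(ff$blocks))) {
      diags <- c(diags, sprintf("link %d resnames (%s) match no block", k,
                                paste(rn, collapse = ",")))
    }
  }
  diags
}

# ---- serializers (round-trip support) --------------------------------------

fmt_num <- function(x) {
  ifelse(is.na(x), "-", vapply(x, function(v) format(v, digits = 12), character(1)))
}

serialize_interactions <- function(ias_by_kind_or_flat, atom_names = NULL,
                                   id_labels = NULL) {
  out <- character()
  flat <- ias_by_kind_or_flat
  if (!is.null(names(flat))) flat <- unlist(unname(flat), recursive = FALSE)
  bykind <- split(flat, vapply(flat, function(ia) {
    if (isTRUE(ia$meta$improper)) "impropers" else ia$kind
  }, character(1)))
  for (sect in intersect(c("bonds", "angles", "dihedrals", "impropers",
                           "constraints", "pairs", "exclusions",
                           "virtual_sitesn", "position_restraints"),
                         names(bykind))) {
    out <- c(out, sprintf("[ %s ]", sect))
    for (ia in bykind[[sect]]) {
      refs <- if (!is.null(atom_names)) atom_names[ia$particles] else
        if (!is.null(id_labels)) id_labels[as.character(ia$particles)] else
          as.character(ia$particles)
      if (ia$kind == "virtual_sitesn") {
        out <- c(out, paste(c(refs[1L], ia$parameters, refs[-1L]), collapse = " "))
      } else {
        out <- c(out, paste(c(refs, ia$parameters), collapse = " "))
      }
    }
  }
  out
}

#' Serialize a force field to the fragment dialect
#' @param ff a [forcefield()].
#' @return character vector of lines re-readable by [parse_fragment_text()].
#' @export
write_fragment_text <- function(ff) {
  out <- character()
  if (length(ff$variables)) {
    out <- c(out, "[ variables ]")
    for (k in names(ff$variables)) {
      out <- c(out, paste(c(k, ff$variables[[k]]), collapse = " "))
    }
    out <- c(out, "")
  }
  if (length(ff$aliases)) {
    out <- c(out, "[ aliases ]")
    for (k in names(ff$aliases)) {
      al <- ff$aliases[[k]]
      out <- c(out, paste(c(k, al$block, al$mods), collapse = " "))
    }
    out <- c(out, "")
  }
  for (b in ff$blocks) {
    out <- c(out, "[ block ]", paste("name", b$name))
    if (!is.na(b$nrexcl)) out <- c(out, paste("nrexcl", b$nrexcl))
    for (ct in b$citations) out <- c(out, paste("citation", ct))
    out <- c(out, "[ atoms ]")
    at <- b$graph$atoms
    for (i in seq_len(nrow(at))) {
      out <- c(out, paste(c(at$atom_name[i],
                            ifelse(is.na(at$element[i]), "-", at$element[i]),
                            ifelse(is.na(at$particle_type[i]), "-", at$particle_type[i]),
                            fmt_num(at$charge[i]), fmt_num(at$mass[i])),
                          collapse = " "))
    }
    # edges not expressed by a bond interaction
    bonded <- unique(do.call(rbind, c(list(matrix(integer(), ncol = 2)),
      lapply(b$graph$interactions$bonds, function(ia) sort(ia$particles)))))
    extra <- b$graph$edges
    if (nrow(extra)) {
      keep <- !apply(extra, 1L, function(e)
        any(apply(bonded, 1L, function(be) all(be == e))))
      extra <- extra[keep, , drop = FALSE]
    }
    if (nrow(extra)) {
      out <- c(out, "[ edges ]")
      for (i in seq_len(nrow(extra))) {
        out <- c(out, paste(at$atom_name[extra[i, ]], collapse = " "))
      }
    }
    out <- c(out, serialize_interactions(b$graph$interactions, at$atom_name), "")
  }
  for (lk in ff$links) {
    out <- c(out, "[ link ]")
    for (ct in lk$citations) out <- c(out, paste("citation", ct))
    out <- c(out, "[ atoms ]")
    for (i in seq_len(nrow(lk$atoms))) {
      a <- lk$atoms[i, ]
      out <- c(out, paste(c(a$id,
                            if (is.na(a$offset)) "?" else
                              sprintf("%+d", a$offset),
                            a$atom_name,
                            paste(a$resnames[[1]], collapse = ","),
                            a$secstruct), collapse = " "))
    }
    if (NROW(lk$edges)) {
      out <- c(out, "[ edges ]")
      for (i in seq_len(nrow(lk$edges))) {
        out <- c(out, paste(lk$edges[i, ], collapse = " "))
      }
    }
    out <- c(out, serialize_interactions(lk$add_interactions))
    if (length(lk$remove_interactions)) {
      out <- c(out, "[ remove ]")
      for (rm in lk$remove_interactions) {
        out <- c(out, paste(c(rm$kind, rm$particles), collapse = " "))
      }
    }
    if (length(lk$edits)) {
      out <- c(out, "[ edits ]")
      for (e in lk$edits) out <- c(out, paste(e$id, e$attr, e$value))
    }
    out <- c(out, "")
  }
  for (m in ff$modifications) {
    out <- c(out, "[ modification ]", paste("name", m$name),
             paste("resname", paste(m$resnames, collapse = ",")))
    for (ct in m$citations) out <- c(out, paste("citation", ct))
    out <- c(out, "[ atoms ]")
    for (i in seq_len(nrow(m$atoms))) {
      out <- c(out, paste(m$atoms$atom_name[i],
                          ifelse(is.na(m$atoms$element[i]), "-", m$atoms$element[i]),
                          m$atoms$role[i]))
    }
    if (nrow(m$edges)) {
      out <- c(out, "[ edges ]")
      for (i in seq_len(nrow(m$edges))) out <- c(out, paste(m$edges[i, ], collapse = " "))
    }
    out <- c(out, serialize_interactions(m$add_interactions, m$atoms$atom_name))
    if (length(m$attribute_edits)) {
      out <- c(out, "[ edits ]")
      for (e in m$attribute_edits) out <- c(out, paste(e$atom, e$attr, e$value))
    }
    if (length(m$bead_edits)) {
      out <- c(out, "[ bead-edits ]")
      for (e in m$bead_edits) out <- c(out, paste(e$bead, e$attr, e$value))
    }
    if (length(m$atom_assign)) {
      out <- c(out, "[ mapping ]")
      for (e in m$atom_assign) {
        out <- c(out, paste(e$atom, e$bead, format(e$weight, digits = 12)))
      }
    }
    out <- c(out, "")
  }
  out
}

#' Serialize mappings to the backwards-style dialect
#' @param mappings list of [ff_mapping()].
#' @return character vector of lines re-readable by [parse_mapping_text()].
#' @export
write_mapping_text <- function(mappings) {
  out <- character()
  for (m in mappings) {
    out <- c(out, "[ molecule ]", m$name)
    if (!is.na(m$from_ff)) out <- c(out, "[ from ]", m$from_ff)
    if (!is.na(m$to_ff)) out <- c(out, "[ to ]", m$to_ff)
    if (!identical(m$scope, m$name)) {
      out <- c(out, "[ scope ]", paste(m$scope, collapse = " "))
    }
    out <- c(out, "[ martini ]", paste(m$beads, collapse = " "), "[ atoms ]")
    multi <- length(m$scope) > 1L
    for (i in seq_len(nrow(m$atoms))) {
      w <- m$atoms$weights[[i]]
      wtot <- sum(w)
      default <- if (grepl("^[0-9]*H", m$atoms$atom_name[i])) 0 else 1
      wtok <- if (isTRUE(all.equal(wtot, default))) character() else
        format(wtot, digits = 12)
      out <- c(out, paste(c(i, if (multi) m$atoms$residx[i],
                            m$atoms$atom_name[i], names(w), wtok),
                          collapse = " "))
    }
    out <- c(out, "")
  }
  out
}

# ---- bundled demonstration force field -------------------------------------

#' Load a bundled or on-disk force field
#'
#' `"demo-aa"` and `"demo-cg"` resolve to the demonstration force field
#' shipped with the package (a reduced amino-acid set with His tautomers, a
#' protonated-His and phospho-Tyr modification, terminal modifications, a
#' PEO repeat unit, and linear/branched polyethylene units).  Anything else
#' is treated as a path to a fragment file.
#'
#' @param name force-field name or path.
#' @return a [forcefield()].
#' @export
load_forcefield <- function(name) {
  if (inherits(name, "forcefield")) return(name)
  path <- if (file.exists(name)) name else
    system.file("extdata", "demo", paste0(name, ".ff"), package = "cgweaver")
  if (!nzchar(path) || !file.exists(path)) stop("force field not found: ", name)
  parse_fragment_file(path, name = sub("\\.ff$", "", basename(path)))
}

#' Load the bundled demonstration mappings (or a mapping file)
#' @param path mapping file path, or `NULL` for the bundled set.
#' @return list of [ff_mapping()].
#' @export
load_mappings <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "demo", "demo.map", package = "cgweaver")
  }
  if (!file.exists(path)) stop("mapping file not found: ", path)
  parse_mapping_file(path)
}

element_from_name <- function(nm) {
  core <- sub("^[0-9]+", "", nm)
  first <- toupper(substr(core, 1L, 1L))
  if (first %in% c("C", "N", "O", "S", "P", "H", "F", "K", "B", "I")) first
  else NA_character_
}
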