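## Create-topology stage: add inter-residue interactions by link matching,
## and read/write GROMACS topology files.

link_node_matcher <- function(lk) {
  function(p, t) {
    k <- match(p$atom_name, paste0(".", lk$atoms$id))
    a <- lk$atoms[k, ]
    if (t$atom_name != a$atom_name) return(FALSE)
    rns <- a$resnames[[1L]]
    if (!("*" %in% rns) && !(t$resname %in% rns)) return(FALSE)
    if (a$secstruct != "*" &&
        (is.na(t$secstruct) || t$secstruct != a$secstruct)) return(FALSE)
    TRUE
  }
}

# enumerate occurrences of a link pattern; returns list of integer vectors
# (link atom id -> molecule particle id)
match_link <- function(mol, lk) {
  at <- lk$atoms
  keys <- residue_keys(mol)
  res <- residue_table(mol)
  out <- list()
  if (anyNA(at$offset)) {
    # wildcard link: pure graph matching on pattern edges + matchers
    pat_atoms <- data.frame(atom_name = paste0(".", at$id), resname = "",
                            resid = seq_len(nrow(at)),
                            stringsAsFactors = FALSE)
    pattern <- molgraph(pat_atoms, matrix(match(lk$edges, at$id), ncol = 2L))
    ms <- subgraph_isomorphisms(pattern, mol, node_match = link_node_matcher(lk))
    seen <- character()
    for (m in ms) {
      key <- paste(sort(m), collapse = ",")
      if (key %in% seen) next  # symmetric matches collapse to one occurrence
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- setNames(m, at$id)
    }
    return(out)
  }
  # offset link: anchor on each residue, then place nodes at resid offsets
  for (r in seq_len(nrow(res))) {
    ids <- setNames(rep(NA_integer_, nrow(at)), at$id)
    ok <- TRUE
    for (k in seq_len(nrow(at))) {
      tkey_resid <- res$resid[r] + at$offset[k]
      tr <- which(res$chain == res$chain[r] & res$resid == tkey_resid)
      if (length(tr) != 1L) { ok <- FALSE; break }
      rns <- at$resnames[[k]]
      if (!("*" %in% rns) && !(res$resname[tr] %in% rns)) { ok <- FALSE; break }
      ridx <- which(keys == res$key[tr])
      hit <- ridx[match(at$atom_name[k], mol$atoms$atom_name[ridx])]
      if (is.na(hit)) { ok <- FALSE; break }
      if (at$secstruct[k] != "*" &&
          (is.na(mol$atoms$secstruct[hit]) ||
           mol$atoms$secstruct[hit] != at$secstruct[k])) { ok <- FALSE; break }
      ids[k] <- hit
    }
    if (!ok) next
    # pattern edges must exist in the molecule
    for (e in seq_len(nrow(lk$edges))) {
      a <- ids[as.character(lk$edges[e, 1L])]
      b <- ids[as.character(lk$edges[e, 2L])]
      pair <- c(min(a, b), max(a, b))
      if (!any(mol$edges[, 1L] == pair[1L] & mol$edges[, 2L] == pair[2L])) {
        ok <- FALSE
        break
      }
    }
    if (ok) out[[length(out) + 1L]] <- ids
  }
  out
}

#' Apply inter-residue links to a molecule
#'
#' For each link (in file order, which is also precedence: a later link's
#' interaction over the same particle tuple replaces an earlier one), every
#' occurrence of its pattern adds the link's interactions, removes matching
#' ones, and applies attribute edits.  Zero matches is normal.
#'
#' @param mol target-resolution [molgraph()] with intra-fragment
#'   interactions.
#' @param links ordered list of [ff_link()].
#' @param ledger [warning_ledger()].
#' @return molecule with inter-residue interactions added.
#' @export
apply_links <- function(mol, links, ledger = warning_ledger()) {
  for (lk in links) {
    occurrences <- match_link(mol, lk)
    for (ids in occurrences) {
      idmap <- setNames(unname(ids), as.character(lk$atoms$id))
      for (rm in lk$remove_interactions) {
        tgt <- canonical_tuple(unname(idmap[as.character(rm$particles)]))
        kept <- Filter(function(ia)
          !identical(canonical_tuple(ia$particles), tgt),
          mol$interactions[[rm$kind]])
        mol$interactions[[rm$kind]] <- kept
      }
      adds <- lapply(lk$add_interactions, function(ia) {
        ia$particles <- unname(idmap[as.character(ia$particles)])
        ia
      })
      mol <- add_interactions(mol, adds)
      for (ed in lk$edits) {
        tgt <- idmap[as.character(ed$id)]
        val <- if (ed$attr %in% c("charge", "mass")) as.numeric(ed$value) else ed$value
        mol$atoms[tgt, ed$attr] <- val
      }
      mol$citations <- union(mol$citations, lk$citations)
    }
  }
  mol
}

# canonical GROMACS itp section order
.ITP_ORDER <- c("bonds", "pairs", "constraints", "exclusions", "angles",
                "dihedrals", "virtual_sitesn", "position_restraints")

format_meta <- function(meta) {
  meta <- meta[names(meta) != "improper"]
  if (!length(meta)) return("")
  paste0(" ; ", paste(sprintf("%s=%s", names(meta),
                              vapply(meta, format, character(1))),
                      collapse = " "))
}

#' Write a molecule as GROMACS itp text
#'
#' Deterministic output: identical molecules give byte-identical text.
#' Elastic-network bonds are written in their own commented sub-block with
#' their provenance metadata; citation keys accumulated on the molecule are
#' emitted as header comments.
#'
#' @param mol [molgraph()]; every particle needs a `particle_type`.
#' @param name moleculetype name.
#' @param nrexcl exclusion count (default: molecule's, else 1).
#' @return character vector of itp lines.
#' @export
write_itp <- function(mol, name = NULL, nrexcl = NULL) {
  at <- mol$atoms
  untyped <- which(is.na(at$particle_type))
  if (length(untyped)) {
    stop("particle(s) lacking a type: ",
         paste(at$atom_name[untyped], collapse = ", "))
  }
  name <- name %||% (if (!is.na(mol$name)) mol$name else "molecule")
  nrexcl <- nrexcl %||% (if (!is.na(mol$nrexcl)) mol$nrexcl else 1L)
  out <- character()
  if (length(mol$citations)) {
    out <- c(out, paste("; citations:",
                        paste(sort(mol$citations), collapse = ", ")))
  }
  out <- c(out, "[ moleculetype ]", sprintf("%s %d", name, nrexcl), "",
           "[ atoms ]")
  for (i in seq_len(nrow(at))) {
    out <- c(out, sprintf("%5d %10s %5d %7s %7s %5d %10s%s",
                          i, at$particle_type[i], at$resid[i],
                          at$resname[i], at$atom_name[i], i,
                          format(ifelse(is.na(at$charge[i]), 0, at$charge[i])),
                          ifelse(is.na(at$mass[i]), "",
                                 paste0(" ", format(at$mass[i])))))
  }
  for (sect in .ITP_ORDER) {
    ias <- mol$interactions[[sect]]
    if (!length(ias)) next
    is_en <- vapply(ias, function(ia)
      identical(ia$meta$source, "elastic_network"), logical(1))
    emit <- function(subset) {
      vapply(subset, function(ia) {
        p <- ia$particles
        if (ia$kind == "virtual_sitesn") {
          body <- paste(c(p[1L], ia$parameters, p[-1L]), collapse = " ")
        } else {
          body <- paste(c(p, ia$parameters), collapse = " ")
        }
        paste0(body, format_meta(ia$meta))
      }, character(1))
    }
    out <- c(out, "", sprintf("[ %s ]", sect), emit(ias[!is_en]))
    if (any(is_en)) {
      out <- c(out, "; elastic network", emit(ias[is_en]))
    }
  }
  out
}

#' Read GROMACS itp text into a molecule graph
#'
#' Nodes come from `[ atoms ]`, edges from `[ bonds ]` and
#' `[ constraints ]` (elastic-network bonds, recognizable by their
#' `source=elastic_network` comment metadata, add interactions but no
#' edges), and every section is stored as interactions with verbatim
#' parameters.  `#include` lines are not followed; they are recorded as a
#' diagnostic.
#'
#' @param text character vector of itp lines (or a file path).
#' @return a [molgraph()]; skipped includes in attribute `diagnostics`.
#' @export
read_itp <- function(text) {
  if (length(text) == 1L && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  text <- sub("\r$", "", text)
  diagnostics <- character()
  name <- NA_character_; nrexcl <- NA_integer_
  atoms <- NULL
  ias <- list()
  edges <- NULL
  section <- NULL
  citations <- character()
  for (i in seq_along(text)) {
    line <- text[i]
    if (grepl("^#include", line)) {
      diagnostics <- c(diagnostics, paste("include not followed:", line))
      next
    }
    if (grepl("^; citations: ", line)) {
      citations <- strsplit(sub("^; citations: ", "", line), ", ",
                            fixed = TRUE)[[1]]
      next
    }
    meta <- list()
    cm <- regmatches(line, regexpr(";.*$", line))
    if (length(cm)) {
      for (kv in regmatches(cm, gregexpr("[A-Za-z_]+=[^ ]+", cm))[[1]]) {
        parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
        meta[[parts[1L]]] <- parts[2L]
      }
    }
    bare <- strip_comment(line)
    if (!nzchar(trimws(bare))) next
    tok <- strsplit(trimws(bare), "[ \t]+")[[1]]
    if (is_directive(tok)) {
      section <- directive_name(tok)
      next
    }
    if (is.null(section)) next
    if (section == "moleculetype") {
      name <- tok[1L]; nrexcl <- as.integer(tok[2L])
    } else if (section == "atoms") {
      atoms <- rbind(atoms, data.frame(
        atom_name = tok[5L], resname = tok[4L], resid = as.integer(tok[3L]),
        chain = "", particle_type = tok[2L],
        charge = if (length(tok) >= 7L) as.numeric(tok[7L]) else NA_real_,
        mass = if (length(tok) >= 8L) as.numeric(tok[8L]) else NA_real_,
        stringsAsFactors = FALSE))
    } else if (section %in% c(.ITP_ORDER)) {
      if (is.null(atoms)) stop("itp input has no [ atoms ] section before [",
                               section, "]")
      nmax <- nrow(atoms)
      resolve <- function(s) {
        v <- as.integer(s)
        if (is.na(v) || v < 1L || v > nmax) {
          stop("itp [", section, "] line ", i,
               ": particle index out of range: ", s)
        }
        v
      }
      ia <- parse_interaction_line(
        if (section %in% names(.SECTION_ARITY) ||
            section %in% c("exclusions", "virtual_sitesn")) section else section,
        tok, resolve, i)
      ia$meta <- meta
      ias[[length(ias) + 1L]] <- ia
      if (ia$kind %in% c("bonds", "constraints") &&
          !identical(meta$source, "elastic_network")) {
        edges <- rbind(edges, ia$particles)
      }
    }
  }
  if (is.null(atoms)) stop("itp input has no [ atoms ] section")
  grouped <- list()
  for (ia in ias) grouped[[ia$kind]] <- c(grouped[[ia$kind]], list(ia))
  mol <- molgraph(atoms, edges, grouped, citations = citations,
                  name = name, nrexcl = nrexcl)
  attr(mol, "diagnostics") <- diagnostics
  mol
}

#' Write a .top skeleton for a system
#'
#' Includes the given itp files and fills the `[ system ]` and
#' `[ molecules ]` directives; cross-molecule elastic-network bonds, which
#' cannot live in an itp, go under `[ intermolecular_interactions ]`.
#'
#' @param path output file.
#' @param itp_files character vector of itp file names to include.
#' @param mol_names moleculetype names, one per molecule.
#' @param counts molecule counts (default 1 each).
#' @param title system title.
#' @param intermolecular optional list of [bonded_interaction()] with global
#'   particle indices.
#' @export
write_top <- function(path, itp_files, mol_names, counts = NULL,
                      title = "cgweaver system", intermolecular = NULL) {
  counts <- counts %||% rep(1L, length(mol_names))
  out <- c(sprintf("#include \"%s\"", itp_files), "", "[ system ]", title,
           "", "[ molecules ]",
           sprintf("%s %d", mol_names, counts))
  if (length(intermolecular)) {
    out <- c(out, "", "[ intermolecular_interactions ]", "[ bonds ]",
             vapply(intermolecular, function(ia)
               paste0(paste(c(ia$particles, ia$parameters), collapse = " "),
                      format_meta(ia$meta)), character(1)))
  }
  writeLines(out, path)
  invisible(path)
}
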