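## Reading/writing atomistic structures (PDB, GRO), bond inference by three
## strategies, and partitioning into molecules.  All positions are held in
## nm internally; PDB files are Angstrom and converted at parse time.

# Cordero covalent radii (nm) for the elements the pipeline meets.
.COVALENT_RADII <- c(H = 0.031, C = 0.076, N = 0.071, O = 0.066, S = 0.105,
                     P = 0.107, F = 0.057, CL = 0.102, BR = 0.120, I = 0.139,
                     NA. = 0.166, K = 0.203, MG = 0.141, CA. = 0.176,
                     ZN = 0.122, FE = 0.132)

covalent_radius <- function(element) {
  r <- .COVALENT_RADII[toupper(element)]
  r[is.na(r)] <- 0.076  # unknown elements behave like carbon
  unname(r)
}

#' Construct a structure record
#'
#' The parsed form of one model of a structure file: a particle table plus
#' symmetrized CONECT pairs.  Positions are in nm.
#'
#' @param atoms data.frame with `serial`, `atom_name`, `resname`, `resid`,
#'   `chain`, and optionally `icode`, `altloc`, `occupancy`, `element`,
#'   `x`, `y`, `z` (nm), `hetatm`.
#' @param conect two-column matrix of serial pairs (deduplicated,
#'   symmetrized).
#' @param model_index which MODEL the record came from.
#' @export
structure_record <- function(atoms, conect = NULL, model_index = 1L) {
  stopifnot(is.data.frame(atoms))
  for (col in c("icode", "altloc")) if (is.null(atoms[[col]])) atoms[[col]] <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$element)) {
    atoms$element <- vapply(atoms$atom_name, element_from_name, character(1))
  }
  if (is.null(atoms$hetatm)) atoms$hetatm <- FALSE
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (anyDuplicated(atoms$serial)) stop("duplicate atom serials in model")
  if (!is.null(conect) && NROW(conect)) {
    conect <- matrix(as.integer(conect), ncol = 2L)
    conect <- unique(cbind(pmin(conect[, 1L], conect[, 2L]),
                           pmax(conect[, 1L], conect[, 2L])))
    conect <- conect[order(conect[, 1L], conect[, 2L]), , drop = FALSE]
  } else {
    conect <- matrix(integer(), ncol = 2L)
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, conect = conect, model_index = model_index),
            class = "structure_record")
}

#' @export
print.structure_record <- function(x, ...) {
  cat(sprintf("<structure: %d atoms, %d CONECT pairs, %d chains>\n",
              nrow(x$atoms), nrow(x$conect), length(unique(x$atoms$chain))))
  invisible(x)
}

#' Read a PDB file
#'
#' ATOM/HETATM records are parsed by fixed columns; only the first MODEL is
#' used; alternate locations are resolved by keeping the highest occupancy
#' (ties: alphabetically first altloc); CONECT pairs are deduplicated and
#' symmetrized.  Coordinates are converted from Angstrom to nm.
#'
#' @param path file path, or a character vector of PDB lines.
#' @return a [structure_record()].
#' @export
read_pdb <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else path
  lines <- sub("\r$", "", lines)
  # first model only
  mstart <- grep("^MODEL", lines)
  if (length(mstart) >= 1L) {
    mend <- grep("^ENDMDL", lines)
    end <- if (length(mend)) mend[1L] else length(lines)
    atom_zone <- seq(mstart[1L], end)
  } else {
    atom_zone <- seq_along(lines)
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  sel <- which(is_atom & seq_along(lines) %in% atom_zone)
  if (!length(sel)) stop("no atoms found in PDB input")
  f <- function(l, a, b) substr(l, a, b)
  recs <- lines[sel]
  coords <- cbind(suppressWarnings(as.numeric(f(recs, 31, 38))),
                  suppressWarnings(as.numeric(f(recs, 39, 46))),
                  suppressWarnings(as.numeric(f(recs, 47, 54))))
  bad <- which(rowSums(is.na(coords)) > 0L)
  if (length(bad)) {
    stop("unparseable coordinate field at line ", sel[bad[1L]])
  }
  occ <- suppressWarnings(as.numeric(f(recs, 55, 60)))
  occ[is.na(occ)] <- 1
  elem <- trimws(f(recs, 77, 78))
  nm <- trimws(f(recs, 13, 16))
  elem <- ifelse(nzchar(elem), elem,
                 vapply(nm, element_from_name, character(1)))
  atoms <- data.frame(
    serial = as.integer(f(recs, 7, 11)),
    atom_name = nm,
    altloc = trimws(f(recs, 17, 17)),
    resname = trimws(f(recs, 18, 20)),
    chain = trimws(f(recs, 22, 22)),
    resid = as.integer(f(recs, 23, 26)),
    icode = trimws(f(recs, 27, 27)),
    x = coords[, 1L] / 10, y = coords[, 2L] / 10, z = coords[, 3L] / 10,
    occupancy = occ,
    element = elem,
    hetatm = startsWith(recs, "HETATM"),
    stringsAsFactors = FALSE)
  # altloc resolution: per (chain,resid,icode,name) keep highest occupancy,
  # ties alphabetically first altloc
  key <- paste(atoms$chain, atoms$resid, atoms$icode, atoms$atom_name, sep = "|")
  if (anyDuplicated(key)) {
    ord <- order(key, -atoms$occupancy, atoms$altloc)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resid, atoms$icode,
                                     atoms$atom_name, sep = "|")), , drop = FALSE]
    atoms <- atoms[order(match(atoms$serial, atoms$serial)), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  conect <- NULL
  for (l in lines[startsWith(lines, "CONECT")] ) {
    toks <- suppressWarnings(as.integer(strsplit(trimws(substr(l, 7, 70)),
                                                 "[ \t]+")[[1]]))
    toks <- toks[!is.na(toks)]
    if (length(toks) >= 2L) {
      conect <- rbind(conect, cbind(toks[1L], toks[-1L]))
    }
  }
  structure_record(atoms, conect)
}

#' Read a GRO file
#' @param path file path or character vector of lines.
#' @return a [structure_record()] (positions already in nm).
#' @export
read_gro <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else path
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3L) stop("truncated GRO input")
  n <- as.integer(trimws(lines[2L]))
  if (is.na(n) || n < 1L) stop("no atoms found in GRO input")
  recs <- lines[3:(2 + n)]
  f <- function(a, b) substr(recs, a, b)
  atoms <- data.frame(
    serial = seq_len(n),
    atom_name = trimws(f(11, 15)),
    resname = trimws(f(6, 10)),
    chain = "",
    resid = as.integer(f(1, 5)),
    x = as.numeric(f(21, 28)), y = as.numeric(f(29, 36)),
    z = as.numeric(f(37, 44)),
    stringsAsFactors = FALSE)
  rec <- structure_record(atoms)
  attr(rec, "box") <- as.numeric(strsplit(trimws(lines[3 + n]), "[ \t]+")[[1]])
  rec
}

#' Infer bonds between atoms
#'
#' Three strategies: `distance` draws an edge when the interatomic distance
#' is at most `scale` times the sum of the covalent radii (hydrogens capped
#' at one bond, to their closest heavy atom); `names` copies intra-residue
#' bonds from the force-field block matching the residue name and adds
#' inter-residue bonds from finite-offset link patterns; `conect` uses the
#' file's CONECT pairs only; `auto` picks conect if pairs are present, else
#' distance when all positions are known, else names.
#'
#' @param record a [structure_record()].
#' @param strategy `"auto"`, `"distance"`, `"names"`, or `"conect"`.
#' @param ff a [forcefield()] (required for `names`).
#' @param scale tolerance factor on the covalent-radius sum.
#' @param ledger optional [warning_ledger()] for diagnostics.
#' @return two-column integer matrix of atom indices (1-based rows).
#' @export
infer_bonds <- function(record, strategy = "auto", ff = NULL, scale = 1.2,
                        ledger = NULL) {
  at <- record$atoms
  n <- nrow(at)
  strategy <- match.arg(strategy, c("auto", "distance", "names", "conect"))
  if (strategy == "auto") {
    strategy <- if (nrow(record$conect)) "conect"
    else if (!anyNA(at$x)) "distance"
    else "names"
  }
  if (strategy == "conect") {
    idx <- match(record$conect, at$serial)
    pairs <- matrix(idx, ncol = 2L)
    pairs <- pairs[rowSums(is.na(pairs)) == 0L, , drop = FALSE]
    return(normalize_edges(pairs, n))
  }
  if (strategy == "distance") {
    missing <- which(is.na(at$x) | is.na(at$y) | is.na(at$z))
    if (length(missing)) {
      stop("distance bond inference needs positions for all particles; ",
           "missing for: ", paste(at$atom_name[missing], collapse = ", "))
    }
    pos <- as.matrix(at[, c("x", "y", "z")])
    rad <- covalent_radius(at$element)
    d <- as.matrix(stats::dist(pos))
    cutoff <- scale * outer(rad, rad, `+`)
    hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
    pairs <- hit
    # hydrogens: keep only the single bond to the closest heavy atom
    hydro <- which(toupper(at$element) == "H")
    if (length(hydro) && nrow(pairs)) {
      keep <- rep(TRUE, nrow(pairs))
      for (h in hydro) {
        inv <- which(pairs[, 1L] == h | pairs[, 2L] == h)
        if (length(inv) > 1L) {
          partners <- ifelse(pairs[inv, 1L] == h, pairs[inv, 2L], pairs[inv, 1L])
          dd <- d[cbind(rep(h, length(partners)), partners)]
          heavy <- toupper(at$element[partners]) != "H"
          ord <- order(!heavy, dd)
          keep[inv[-ord[1L]]] <- FALSE
        }
      }
      pairs <- pairs[keep, , drop = FALSE]
    }
    return(normalize_edges(pairs, n))
  }
  # names strategy
  if (is.null(ff)) stop("names bond inference needs a force field")
  pairs <- NULL
  rkey <- paste(at$chain, at$resid, at$icode, sep = "|")
  resinfo <- !duplicated(rkey)
  res <- data.frame(key = rkey[resinfo], chain = at$chain[resinfo],
                    resid = at$resid[resinfo], resname = at$resname[resinfo],
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(res))) {
    rn <- res$resname[r]
    alias <- ff$aliases[[rn]]
    bname <- if (!is.null(alias)) alias$block else rn
    block <- ff$blocks[[bname]]
    ridx <- which(rkey == res$key[r])
    if (is.null(block)) {
      if (!is.null(ledger)) {
        ledger_add(ledger, "unrecognized-residue",
                   sprintf("no block '%s' for name-based bond inference", rn),
                   list(chain = res$chain[r], resid = res$resid[r],
                        resname = rn))
      }
      next
    }
    bat <- block$graph$atoms$atom_name
    for (e in seq_len(nrow(block$graph$edges))) {
      a <- ridx[match(bat[block$graph$edges[e, 1L]], at$atom_name[ridx])]
      b <- ridx[match(bat[block$graph$edges[e, 2L]], at$atom_name[ridx])]
      if (!is.na(a) && !is.na(b)) pairs <- rbind(pairs, c(a, b))
    }
  }
  # inter-residue bonds from finite-offset links
  for (lk in ff$links) {
    offs <- lk$atoms$offset
    if (anyNA(offs)) next  # wildcard links need geometry
    for (r in seq_len(nrow(res))) {
      ok <- TRUE
      idx <- integer(nrow(lk$atoms))
      for (k in seq_len(nrow(lk$atoms))) {
        tkey <- paste(res$chain[r], res$resid[r] + offs[k], "", sep = "|")
        tr <- match(tkey, res$key)
        if (is.na(tr)) { ok <- FALSE; break }
        rns <- lk$atoms$resnames[[k]]
        if (!("*" %in% rns) && !(res$resname[tr] %in% rns)) { ok <- FALSE; break }
        ridx <- which(rkey == tkey)
        a <- ridx[match(lk$atoms$atom_name[k], at$atom_name[ridx])]
        if (is.na(a)) { ok <- FALSE; break }
        idx[k] <- a
      }
      if (!ok) next
      for (ia in lk$add_interactions) {
        if (ia$kind == "bonds") {
          pairs <- rbind(pairs, idx[match(ia$particles, lk$atoms$id)])
        }
      }
    }
  }
  normalize_edges(pairs, n)
}

#' Build a system of molecules from a structure record and bond list
#'
#' Applies [connected_components()]; particles keep their chain attribute
#' and the molecule order is deterministic: by lowest original serial.
#'
#' @param record a [structure_record()].
#' @param edges edge matrix from [infer_bonds()].
#' @param ff optional [forcefield()] whose name tags the system.
#' @return a list of class `cg_system` with elements `molecules` (list of
#'   [molgraph()]) and `forcefield`.
#' @export
to_system <- function(record, edges, ff = NULL) {
  at <- record$atoms
  cols <- c("atom_name", "resname", "resid", "chain", "element",
            "x", "y", "z", "icode")
  mol <- molgraph(at[, cols, drop = FALSE], edges,
                  forcefield = if (!is.null(ff)) ff$name else NA_character_)
  mol$atoms$serial <- at$serial
  mols <- connected_components(mol)
  first_serial <- vapply(mols, function(m) min(m$atoms$serial), numeric(1))
  mols <- mols[order(first_serial)]
  structure(list(molecules = mols,
                 forcefield = if (!is.null(ff)) ff$name else NA_character_),
            class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf("<system: %d molecule(s)>\n", length(x$molecules)))
  for (m in x$molecules) print(m)
  invisible(x)
}

as_system <- function(x) {
  if (inherits(x, "cg_system")) x
  else structure(list(molecules = list(x), forcefield = x$forcefield),
                 class = "cg_system")
}

#' Write a system (or molecule) as a GRO file
#'
#' Positions are written in nm with 3 decimals.  Particles lacking a
#' position are written at the (0,0,0) sentinel and a warning is recorded,
#' never silently; this requires `allow_missing = TRUE`.
#'
#' @param system a `cg_system` or [molgraph()].
#' @param path output file path.
#' @param title title line.
#' @param allow_missing permit coordinate-free particles.
#' @param ledger optional [warning_ledger()].
#' @export
write_gro <- function(system, path, title = "generated by cgweaver",
                      allow_missing = FALSE, ledger = NULL) {
  system <- as_system(system)
  at <- do.call(rbind, lapply(system$molecules, function(m)
    m$atoms[, c("atom_name", "resname", "resid", "chain", "x", "y", "z")]))
  miss <- which(is.na(at$x))
  if (length(miss)) {
    if (!allow_missing) {
      stop("cannot write GRO: ", length(miss), " particle(s) lack positions")
    }
    if (!is.null(ledger)) {
      for (i in miss) {
        ledger_add(ledger, "missing-coordinates",
                   sprintf("particle %s written at the (0,0,0) sentinel",
                           at$atom_name[i]),
                   list(chain = at$chain[i], resid = at$resid[i],
                        resname = at$resname[i]))
      }
    }
    at$x[miss] <- at$y[miss] <- at$z[miss] <- 0
  }
  n <- nrow(at)
  lines <- c(title, sprintf("%5d", n))
  serial <- seq_len(n)
  lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                            at$resid %% 100000L, substr(at$resname, 1, 5),
                            substr(at$atom_name, 1, 5), serial %% 100000L,
                            at$x, at$y, at$z))
  span <- apply(at[, c("x", "y", "z")], 2L, function(v) diff(range(v)))
  box <- pmax(span + 1, 1)
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Write a system (or molecule) as a PDB file
#'
#' @inheritParams write_gro
#' @param conect write CONECT records for all edges.
#' @export
write_pdb <- function(system, path, allow_missing = FALSE, ledger = NULL,
                      conect = TRUE) {
  system <- as_system(system)
  lines <- character()
  serial <- 0L
  conect_lines <- character()
  for (m in system$molecules) {
    at <- m$atoms
    offset <- serial
    for (i in seq_len(nrow(at))) {
      serial <- serial + 1L
      xyz <- c(at$x[i], at$y[i], at$z[i]) * 10
      if (anyNA(xyz)) {
        if (!allow_missing) stop("cannot write PDB: particle lacks position")
        if (!is.null(ledger)) {
          ledger_add(ledger, "missing-coordinates",
                     sprintf("particle %s written at the (0,0,0) sentinel",
                             at$atom_name[i]),
                     list(chain = at$chain[i], resid = at$resid[i],
                          resname = at$resname[i]))
        }
        xyz <- c(0, 0, 0)
      }
      nm <- at$atom_name[i]
      nmfmt <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else substr(nm, 1, 4)
      el <- if (is.na(at$element[i])) "" else at$element[i]
      lines <- c(lines, sprintf(
        "ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, nmfmt, "", substr(at$resname[i], 1, 3),
        substr(at$chain[i], 1, 1), at$resid[i] %% 10000L,
        substr(if (is.null(at$icode)) "" else at$icode[i], 1, 1),
        xyz[1], xyz[2], xyz[3], 1, 0, el))
    }
    if (conect && nrow(m$edges)) {
      for (e in seq_len(nrow(m$edges))) {
        conect_lines <- c(conect_lines,
                          sprintf("CONECT%5d%5d", offset + m$edges[e, 1L],
                                  offset + m$edges[e, 2L]))
      }
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, conect_lines, "END"), path)
  invisible(path)
}
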