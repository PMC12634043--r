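## Stage 1-6 orchestration: read -> partition -> repair/identify -> map ->
## link -> post-process (elastic network) -> write, with a typed warning
## ledger and deterministic exit behaviour.  On unignored warnings nothing
## is written and the run reports exit status 1; hard stage errors give 2.

#' Run the topology-generation pipeline
#'
#' @param input structure file path (`.pdb`/`.gro`) or a
#'   [structure_record()].
#' @param source_ff source-resolution force field (name, path, or object).
#' @param target_ff target-resolution force field; defaults to the bundled
#'   CG demonstration force field.  Pass the source force field together
#'   with `mappings = "identity"` for same-resolution (all-atom) output.
#' @param mappings list of [ff_mapping()], a mapping file path,
#'   `"identity"`, or `NULL` for the bundled set.
#' @param bonds_from bond-inference strategy (see [infer_bonds()]).
#' @param bond_scale tolerance factor for distance inference.
#' @param ss secondary structure: string, file, `"auto"`, or `NULL` to skip.
#' @param nter,cter terminal modification names overriding the defaults.
#' @param strict_h warn about absent hydrogens.
#' @param elastic generate an elastic network.
#' @param en [en_params()] for the elastic network.
#' @param map_weights `"file"`, `"mass"`, or `"uniform"`.
#' @param ignore warning categories to ignore (see `LEDGER_CATEGORIES`).
#' @param maxwarn tolerated number of unignored warnings.
#' @param name moleculetype base name.
#' @param out_prefix path prefix for outputs (`<prefix>_<i>.itp`,
#'   `<prefix>.gro`, `<prefix>.top`), or `NULL` to skip writing.
#' @return object of class `cgweaver_result` with `exit_code` (0 = success,
#'   1 = warnings blocked output, 2 = hard error), `system` (source
#'   resolution), `cg_system`, `ledger`, `reports`, `citations`, `outputs`.
#' @export
run_pipeline <- function(input, source_ff = "demo-aa", target_ff = "demo-cg",
                         mappings = NULL, bonds_from = "auto",
                         bond_scale = 1.2, ss = NULL, nter = NULL,
                         cter = NULL, strict_h = FALSE, elastic = FALSE,
                         en = en_params(), map_weights = "file",
                         ignore = character(), maxwarn = 0L,
                         name = "molecule", out_prefix = NULL) {
  ledger <- warning_ledger(ignored = ignore, max_warnings = maxwarn)
  result <- list(exit_code = 2L, system = NULL, cg_system = NULL,
                 ledger = ledger, reports = list(), citations = character(),
                 outputs = character(), error = NULL)
  class(result) <- "cgweaver_result"
  stage <- "setup"
  tryCatch({
    src <- load_forcefield(source_ff)
    tgt <- load_forcefield(target_ff)
    maps <- if (identical(mappings, "identity")) {
      tgt <- src
      identity_mappings(src)
    } else if (is.null(mappings)) {
      load_mappings()
    } else if (is.character(mappings)) {
      load_mappings(mappings)
    } else mappings
    all_mods <- c(src$modifications, tgt$modifications)

    stage <- "read input"
    record <- if (inherits(input, "structure_record")) input
    else if (grepl("\\.gro$", input)) read_gro(input)
    else read_pdb(input)

    stage <- "bond inference"
    edges <- infer_bonds(record, bonds_from, ff = src, scale = bond_scale,
                         ledger = ledger)
    system <- to_system(record, edges, src)

    stage <- "identify and repair"
    reports <- list()
    for (i in seq_along(system$molecules)) {
      rr <- repair_molecule(system$molecules[[i]], src, ledger,
                            strict_h = strict_h)
      rr <- resolve_modifications(rr$molecule, rr$reports, all_mods, ledger)
      mol <- assign_termini(rr$molecule, src, ledger, nter = nter,
                            cter = cter)
      if (!is.null(ss)) {
        mol <- annotate_secondary_structure(mol, ss, src, ledger)
      }
      system$molecules[[i]] <- mol
      reports[[i]] <- rr$reports
    }
    result$system <- system
    result$reports <- reports

    stage <- "resolution transformation"
    cg_mols <- list()
    for (i in seq_along(system$molecules)) {
      mol <- system$molecules[[i]]
      attr(mol, "source_ff") <- src
      cover <- build_cover(mol, maps, ledger, modifications = all_mods)
      if (!length(cover$placements)) next
      cg <- map_to_target(mol, cover, tgt, ledger, weights_mode = map_weights)
      cg <- construct_virtual_sites(cg, ledger)
      cg_mols[[length(cg_mols) + 1L]] <- cg
    }
    if (!length(cg_mols)) stop("no molecule could be transformed")
    cg_system <- structure(list(molecules = cg_mols, forcefield = tgt$name),
                           class = "cg_system")

    stage <- "create topology"
    for (i in seq_along(cg_system$molecules)) {
      cg_system$molecules[[i]] <-
        apply_links(cg_system$molecules[[i]], tgt$links, ledger)
    }

    stage <- "post-processing"
    en_result <- NULL
    if (elastic) {
      en_result <- generate_en(cg_system, en, ff = tgt, ledger = ledger)
      cg_system <- en_apply(cg_system, en_result)
    }
    result$cg_system <- cg_system
    result$en <- en_result
    result$citations <- sort(unique(unlist(
      lapply(cg_system$molecules, function(m) m$citations))))

    stage <- "write output"
    if (ledger_passes(ledger)) {
      result$exit_code <- 0L
      if (!is.null(out_prefix)) {
        itps <- character()
        mol_names <- character()
        for (i in seq_along(cg_system$molecules)) {
          mol_names[i] <- if (length(cg_system$molecules) == 1L) name else
            sprintf("%s_%d", name, i)
          itps[i] <- sprintf("%s_%d.itp", out_prefix, i)
          writeLines(write_itp(cg_system$molecules[[i]], mol_names[i]),
                     itps[i])
        }
        gro <- paste0(out_prefix, ".gro")
        write_gro(cg_system, gro, allow_missing = TRUE, ledger = ledger)
        top <- paste0(out_prefix, ".top")
        write_top(top, basename(itps), mol_names,
                  intermolecular = en_result$intermolecular)
        result$outputs <- c(itps, gro, top)
      }
    } else {
      result$exit_code <- 1L
    }
    result
  }, error = function(e) {
    result$error <- sprintf("stage '%s': %s", stage, conditionMessage(e))
    result$exit_code <- 2L
    result
  })
}

#' @export
print.cgweaver_result <- function(x, ...) {
  status <- c("0 (success)", "1 (warnings blocked output)",
              "2 (hard error)")[x$exit_code + 1L]
  cat("cgweaver pipeline result - exit", status, "\n")
  if (!is.null(x$error)) cat("  error:", x$error, "\n")
  print(x$ledger)
  if (length(x$citations)) {
    cat("Please cite the parameter sets used:\n")
    cat(paste0("  - ", x$citations, collapse = "\n"), "\n")
  }
  if (length(x$outputs)) {
    cat("written:", paste(x$outputs, collapse = ", "), "\n")
  }
  invisible(x)
}

.CORRUPTION_CLASSES <- c("drop_atoms", "drop_coordinates", "swap_elements",
                         "perturb_distances", "add_atom")

#' Robustness suite over generated corrupted structures
#'
#' Generates `n` fixture variants spanning the corruption taxonomy
#' (missing atoms, whole side chains missing so bead coordinates cannot be
#' generated, swapped elements, perturbed ring distances, unexpected
#' atoms) plus clean controls, runs the full pipeline on each, and
#' classifies the outcome.  A corrupted variant must never convert
#' silently: every corrupted residue has to appear in the warning ledger.
#'
#' @param n number of variants.
#' @param seed base seed; variant i uses `seed + i`.
#' @param classes corruption classes to cycle through (`"clean"` included
#'   by default).
#' @param elastic also exercise elastic-network generation.
#' @return data.frame with one row per variant: `class`, `status`
#'   (`converted`/`warned`/`errored`), `flagged_ok` (all corrupted
#'   residues ledgered), `false_positive` (clean variant with warnings).
#' @export
robustness_suite <- function(n = 500L, seed = 1L,
                             classes = c("clean", .CORRUPTION_CLASSES),
                             elastic = FALSE) {
  out <- vector("list", n)
  clean_kinds <- c("linear_peptide", "two_chain_disulfide", "cyclic_peptide",
                   "crown_ether", "branched_polyethylene")
  for (i in seq_len(n)) {
    cls <- classes[((i - 1L) %% length(classes)) + 1L]
    vseed <- seed + i
    if (cls == "clean") {
      kind <- clean_kinds[((i - 1L) %/% length(classes)) %% length(clean_kinds) + 1L]
      fx <- make_structure(kind, n_res = 5L + (vseed %% 3L), seed = vseed)
    } else {
      kind <- "linear_peptide"
      fx <- make_structure(kind, n_res = 6L + (vseed %% 3L),
                           corruption = cls, seed = vseed)
    }
    res <- run_pipeline(fx$record, elastic = elastic)
    status <- c("converted", "warned", "errored")[res$exit_code + 1L]
    flagged <- ledger_context_keys(res$ledger, level = "warning")
    corrupted <- fx$manifest$corrupted
    want <- if (nrow(corrupted)) paste(corrupted$chain, corrupted$resid,
                                       sep = "|") else character()
    flagged_ok <- all(want %in% flagged)
    out[[i]] <- data.frame(
      class = cls, kind = kind, seed = vseed, status = status,
      n_warnings = length(ledger_blocking(res$ledger)),
      flagged_ok = flagged_ok,
      silent_conversion = (cls != "clean" && status == "converted"),
      false_positive = (cls == "clean" && status != "converted"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
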