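#' Typed warning ledger
#'
#' Diagnostics accumulated along the pipeline.  Each entry has a category
#' from a fixed taxonomy, a message, and residue/particle context.  Entries
#' at level `"warning"` block output unless their category is explicitly
#' ignored: output files are written iff the number of unignored warnings is
#' at most `max_warnings` (default 0), so downstream workflow steps never
#' silently consume corrupted files.  Level `"info"` entries (e.g. atom
#' renames performed by repair) never block.
#'
#' @param ignored character vector of categories to ignore.
#' @param max_warnings tolerated number of unignored warnings.
#' @return an environment of class `warning_ledger`.
#' @export
warning_ledger <- function(ignored = character(), max_warnings = 0L) {
  bad <- setdiff(ignored, LEDGER_CATEGORIES)
  if (length(bad)) stop("unknown warning category: ", paste(bad, collapse = ", "))
  env <- new.env(parent = emptyenv())
  env$entries <- list()
  env$ignored <- ignored
  env$max_warnings <- as.integer(max_warnings)
  class(env) <- "warning_ledger"
  env
}

#' @rdname warning_ledger
#' @format NULL
#' @export
LEDGER_CATEGORIES <- c("unrecognized-residue", "unexpected-atoms",
                       "missing-atoms", "missing-coordinates", "ss-failure",
                       "empty-selection", "io", "general")

#' Record a ledger entry
#' @param ledger a [warning_ledger()].
#' @param category one of `LEDGER_CATEGORIES`.
#' @param message human-readable message.
#' @param context named list, typically `list(chain=, resid=, resname=)`.
#' @param level `"warning"` (blocks output) or `"info"`.
#' @export
ledger_add <- function(ledger, category, message, context = list(),
                       level = "warning") {
  stopifnot(category %in% LEDGER_CATEGORIES, level %in% c("warning", "info"))
  ledger$entries[[length(ledger$entries) + 1L]] <-
    list(category = category, message = message, context = context,
         level = level)
  invisible(ledger)
}

#' Unignored blocking warnings in a ledger
#' @param ledger a [warning_ledger()].
#' @return list of entries.
#' @export
ledger_blocking <- function(ledger) {
  Filter(function(e) e$level == "warning" && !(e$category %in% ledger$ignored),
         ledger$entries)
}

#' Does the ledger permit output to be written?
#' @param ledger a [warning_ledger()].
#' @export
ledger_passes <- function(ledger) {
  length(ledger_blocking(ledger)) <= ledger$max_warnings
}

#' All entries of a given level/category
#' @param ledger a [warning_ledger()].
#' @param category optional category filter.
#' @param level optional level filter.
#' @export
ledger_entries <- function(ledger, category = NULL, level = NULL) {
  out <- ledger$entries
  if (!is.null(category)) out <- Filter(function(e) e$category %in% category, out)
  if (!is.null(level)) out <- Filter(function(e) e$level %in% level, out)
  out
}

ledger_context_keys <- function(ledger, level = NULL) {
  unique(vapply(ledger_entries(ledger, level = level), function(e) {
    ctx <- e$context
    if (!is.null(ctx$chain) || !is.null(ctx$resid)) {
      paste(ctx$chain %||% "", ctx$resid %||% "", sep = "|")
    } else NA_character_
  }, character(1)))
}

#' @export
print.warning_ledger <- function(x, ...) {
  cat(sprintf("<warning ledger: %d entries, %d blocking>\n",
              length(x$entries), length(ledger_blocking(x))))
  for (e in x$entries) {
    ctx <- e$context
    loc <- if (length(ctx)) {
      paste0(" [", paste(sprintf("%s=%s", names(ctx),
                                 vapply(ctx, format, character(1))),
                         collapse = " "), "]")
    } else ""
    cat(sprintf("  %s %-20s %s%s\n",
                if (e$level == "info") "." else "!", e$category, e$message, loc))
  }
  invisible(x)
}

#' Serialize a ledger as JSON lines
#' @param ledger a [warning_ledger()].
#' @return character vector, one JSON object per entry.
#' @export
ledger_jsonl <- function(ledger) {
  vapply(ledger$entries, function(e) {
    jsonlite::toJSON(e, auto_unbox = TRUE)
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
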