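#' Default node-match predicate: element equality, falling back to names
#'
#' Matches on element when both elements are known, otherwise on atom name.
#' This reduces dependence on accurate atom names, which often differ
#' between structure sources.
#'
#' @param p,t single-row data.frames of particle attributes.
#' @return logical.
#' @export
match_by_element <- function(p, t) {
  pe <- p$element; te <- t$element
  if (!is.na(pe) && !is.na(te)) return(identical(toupper(pe), toupper(te)))
  identical(p$atom_name, t$atom_name)
}

#' Node-match on atom name
#' @inheritParams match_by_element
#' @export
match_by_name <- function(p, t) identical(p$atom_name, t$atom_name)

#' Enumerate subgraph isomorphisms of a pattern into a target
#'
#' VF2-style recursive matching with candidate ordering by (degree,
#' attribute rarity).  Yields every injective mapping under which every
#' pattern edge maps to a target edge and `node_match` holds for every
#' matched pair.  Enumeration order is deterministic: the returned list is
#' sorted lexicographically by the target ids in pattern-node order.
#'
#' Note this is subgraph (monomorphism) matching: target edges between
#' matched nodes that have no pattern counterpart are allowed.  Set
#' `induced = TRUE` to forbid them.
#'
#' @param pattern,target [molgraph()] objects.
#' @param node_match predicate `function(pattern_row, target_row)`.
#' @param induced require induced embeddings.
#' @param max_matches stop after this many matches (Inf = all).
#' @return list of integer vectors `m` with `m[i]` the target node matched
#'   to pattern node `i`.  Empty list when no match exists.
#' @export
subgraph_isomorphisms <- function(pattern, target, node_match = match_by_element,
                                  induced = FALSE, max_matches = Inf) {
  np <- nrow(pattern$atoms); nt <- nrow(target$atoms)
  if (np == 0L) return(list())
  if (np > nt) return(list())
  compat <- matrix(FALSE, np, nt)
  for (i in seq_len(np)) {
    pi <- pattern$atoms[i, , drop = FALSE]
    for (j in seq_len(nt)) {
      compat[i, j] <- isTRUE(node_match(pi, target$atoms[j, , drop = FALSE]))
    }
  }
  if (any(rowSums(compat) == 0L)) return(list())
  padj <- adjacency_list(np, pattern$edges)
  tadj <- adjacency_list(nt, target$edges)
  pdeg <- lengths(padj)
  tdeg <- lengths(tadj)
  # degree pre-filter (only valid for plain monomorphism and induced alike)
  for (i in seq_len(np)) compat[i, tdeg < pdeg[i]] <- FALSE
  if (any(rowSums(compat) == 0L)) return(list())

  # Matching order: start at the rarest/highest-degree node, then always
  # prefer nodes adjacent to the already-ordered set (keeps the search
  # anchored), breaking ties by rarity, degree, then id.
  rarity <- rowSums(compat)
  order_ids <- integer(0)
  remaining <- seq_len(np)
  score <- function(ids, frontier) {
    ids[order(!(ids %in% frontier), rarity[ids], -pdeg[ids], ids)][1L]
  }
  while (length(remaining)) {
    frontier <- if (length(order_ids)) {
      unique(unlist(padj[order_ids]))
    } else integer(0)
    nxt <- score(remaining, frontier)
    order_ids <- c(order_ids, nxt)
    remaining <- setdiff(remaining, nxt)
  }

  results <- list()
  assign_t <- rep(NA_integer_, np)
  used <- rep(FALSE, nt)
  recurse <- function(depth) {
    if (length(results) >= max_matches) return()
    if (depth > np) {
      results[[length(results) + 1L]] <<- assign_t
      return()
    }
    p <- order_ids[depth]
    mapped_nbrs <- padj[[p]][!is.na(assign_t[padj[[p]]])]
    for (t in which(compat[p, ] & !used)) {
      ok <- TRUE
      for (q in mapped_nbrs) {
        if (!(assign_t[q] %in% tadj[[t]])) { ok <- FALSE; break }
      }
      if (ok && induced) {
        # no target edge may exist to a matched node that is not a
        # pattern neighbour
        others <- assign_t[!is.na(assign_t)]
        extra <- intersect(tadj[[t]], setdiff(others, assign_t[mapped_nbrs]))
        if (length(extra)) ok <- FALSE
      }
      if (ok) {
        assign_t[p] <<- t; used[t] <<- TRUE
        recurse(depth + 1L)
        assign_t[p] <<- NA_integer_; used[t] <<- FALSE
        if (length(results) >= max_matches) return()
      }
    }
  }
  recurse(1L)
  if (length(results) > 1L) {
    keyf <- vapply(results, function(m) paste(sprintf("%06d", m), collapse = ","),
                   character(1))
    results <- results[order(keyf)]
  }
  results
}

#' Maximum common induced subgraph of two particle graphs
#'
#' Computed as a maximum clique of the modular product graph (node pairs
#' compatible under `node_match`; product edges where adjacency agrees in
#' both graphs).  Among maximum-size correspondences the one with the most
#' exact atom-name agreements wins, then the lexicographically lowest
#' node-id assignment, so results are reproducible.
#'
#' @inheritParams subgraph_isomorphisms
#' @return integer vector `m` of length `nrow(pattern$atoms)`; `m[i]` is the
#'   matched target node or `NA` when pattern node `i` is not in the common
#'   subgraph.
#' @export
max_common_subgraph <- function(pattern, target, node_match = match_by_element) {
  np <- nrow(pattern$atoms); nt <- nrow(target$atoms)
  empty <- rep(NA_integer_, np)
  if (np == 0L || nt == 0L) return(empty)
  pairs <- list()
  for (i in seq_len(np)) {
    pi <- pattern$atoms[i, , drop = FALSE]
    for (j in seq_len(nt)) {
      if (isTRUE(node_match(pi, target$atoms[j, , drop = FALSE]))) {
        pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(pairs)) return(empty)
  pm <- do.call(rbind, pairs)
  npair <- nrow(pm)
  pA <- matrix(FALSE, np, np); tA <- matrix(FALSE, nt, nt)
  if (nrow(pattern$edges)) pA[pattern$edges] <- pA[pattern$edges[, 2:1]] <- TRUE
  if (nrow(target$edges)) tA[target$edges] <- tA[target$edges[, 2:1]] <- TRUE
  prod_edges <- list()
  for (u in seq_len(npair - 1L)) {
    for (v in seq((u + 1L), npair)) {
      iu <- pm[u, 1L]; ju <- pm[u, 2L]; iv <- pm[v, 1L]; jv <- pm[v, 2L]
      if (iu != iv && ju != jv && pA[iu, iv] == tA[ju, jv]) {
        prod_edges[[length(prod_edges) + 1L]] <- c(u, v)
      }
    }
  }
  pe <- do.call(rbind, prod_edges)
  g <- igraph::make_graph(edges = if (is.null(pe)) integer() else
    as.integer(t(pe)), n = npair, directed = FALSE)
  cl <- igraph::largest_cliques(g)
  if (!length(cl)) {  # no product edges: best single pair
    cl <- list(1L)
  }
  best <- NULL; best_key <- NULL
  for (clique in cl) {
    m <- empty
    idx <- sort(as.integer(clique))
    m[pm[idx, 1L]] <- pm[idx, 2L]
    nagree <- sum(pattern$atoms$atom_name[pm[idx, 1L]] ==
                    target$atoms$atom_name[pm[idx, 2L]], na.rm = TRUE)
    key <- paste(c(sprintf("%06d", 999999L - nagree),
                   sprintf("%06d", ifelse(is.na(m), 999999L, m))),
                 collapse = ",")
    if (is.null(best_key) || key < best_key) {
      best <- m; best_key <- key
    }
  }
  best
}
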