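# Independent oracles the implementation is checked against.

# Brute-force subgraph-isomorphism oracle: enumerate every node-compatible
# injective map pattern -> target by plain recursion over pattern nodes in
# id order, and test the edge constraints at the leaves.  No matching-order
# heuristics, no adjacency pruning — deliberately naive, just exhaustive.
brute_isomorphisms <- function(pattern, target, node_match = match_by_element) {
  np <- nrow(pattern$atoms); nt <- nrow(target$atoms)
  pe <- pattern$edges
  has_edge <- matrix(FALSE, nt, nt)
  if (nrow(target$edges)) {
    has_edge[target$edges] <- TRUE
    has_edge[target$edges[, 2:1]] <- TRUE
  }
  compat <- matrix(FALSE, max(np, 1L), max(nt, 1L))
  for (i in seq_len(np)) {
    for (j in seq_len(nt)) {
      compat[i, j] <- isTRUE(node_match(pattern$atoms[i, , drop = FALSE],
                                        target$atoms[j, , drop = FALSE]))
    }
  }
  results <- list()
  assign <- integer(np)
  recurse <- function(i) {
    if (i > np) {
      ok <- TRUE
      if (nrow(pe)) {
        for (e in seq_len(nrow(pe))) {
          if (!has_edge[assign[pe[e, 1L]], assign[pe[e, 2L]]]) ok <- FALSE
        }
      }
      if (ok) results[[length(results) + 1L]] <<- assign
      return()
    }
    for (t in seq_len(nt)) {
      if (compat[i, t] && !(t %in% assign[seq_len(i - 1L)])) {
        assign[i] <<- t
        recurse(i + 1L)
        assign[i] <<- 0L
      }
    }
  }
  if (np > 0L && np <= nt) recurse(1L)
  results
}

sort_matches <- function(ms) {
  if (!length(ms)) return(ms)
  ms[order(vapply(ms, function(m) paste(sprintf("%06d", m), collapse = ","),
                  character(1)))]
}

random_molgraph <- function(n, p_edge = 0.3, elements = c("C", "N", "O")) {
  atoms <- data.frame(atom_name = paste0("a", seq_len(n)), resname = "X",
                      resid = 1L,
                      element = sample(elements, n, replace = TRUE),
                      stringsAsFactors = FALSE)
  edges <- NULL
  if (n >= 2L) {
    all_pairs <- t(utils::combn(n, 2L))
    keep <- stats::runif(nrow(all_pairs)) < p_edge
    if (any(keep)) edges <- all_pairs[keep, , drop = FALSE]
  }
  molgraph(atoms, edges)
}

# O(n^2) triple-filter (distance AND rmd AND unit) enumeration the
# elastic-network generator must reproduce exactly.
brute_en_pairs <- function(pos, resid, chain, res_dist, params) {
  n <- nrow(pos)
  out <- NULL
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      d <- sqrt(sum((pos[a, ] - pos[b, ])^2))
      if (d < params$lower_cutoff || d > params$upper_cutoff) next
      if (res_dist[a, b] < params$rmd) next
      if (params$unit == "chain" && chain[a] != chain[b]) next
      if (params$unit == "region") {
        ra <- rb <- NA
        for (k in seq_along(params$regions)) {
          r <- params$regions[[k]]
          if (resid[a] >= r[1] && resid[a] <= r[2]) ra <- k
          if (resid[b] >= r[1] && resid[b] <= r[2]) rb <- k
        }
        if (is.na(ra) || is.na(rb) || ra != rb) next
      }
      out <- rbind(out, c(a, b))
    }
  }
  out
}

# a CG molecule of one backbone bead per residue on a line
linear_cg_chain <- function(n, spacing = 0.35, chain = "A", resname = "GLY") {
  atoms <- data.frame(atom_name = "BB", resname = resname,
                      resid = seq_len(n), chain = chain,
                      x = (seq_len(n) - 1L) * spacing, y = 0, z = 0,
                      particle_type = "P5", stringsAsFactors = FALSE)
  edges <- cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  molgraph(atoms, edges)
}
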