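# Independent oracles for the minimum spanning network.

# Exhaustive union of all minimum-weight spanning trees: enumerate every
# (n-1)-subset of the complete graph's edges, keep those that form a
# spanning tree, find the minimum total weight, and return the union of the
# edges of all trees attaining it. Feasible for n <= 6.
msn_oracle_exhaustive <- function(d) {
  n <- nrow(d)
  pairs <- t(utils::combn(n, 2L))
  w <- d[pairs]
  m <- nrow(pairs)
  combos <- utils::combn(m, n - 1L)
  best <- Inf
  best_edges <- list()
  for (c_i in seq_len(ncol(combos))) {
    sel <- combos[, c_i]
    # spanning-tree check by union-find
    parent <- seq_len(n)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    acyclic <- TRUE
    for (e in sel) {
      ra <- find(pairs[e, 1L]); rb <- find(pairs[e, 2L])
      if (ra == rb) { acyclic <- FALSE; break }
      parent[ra] <- rb
    }
    if (!acyclic) next
    tw <- sum(w[sel])
    if (tw < best - 1e-9) { best <- tw; best_edges <- list(sel) }
    else if (abs(tw - best) <= 1e-9) best_edges <- c(best_edges, list(sel))
  }
  sel_all <- sort(unique(unlist(best_edges)))
  list(weight = best,
       edges = data.frame(i = pairs[sel_all, 1L], j = pairs[sel_all, 2L],
                          steps = w[sel_all]))
}

# Faster independent route via igraph: an edge is in some MST iff forcing it
# (weight shrunk by epsilon) leaves the MST total weight unchanged.
msn_oracle_igraph <- function(d) {
  n <- nrow(d)
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  base_w <- sum(igraph::E(igraph::mst(g))$weight)
  pairs <- t(utils::combn(n, 2L))
  eps <- 1e-6
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    d2 <- d
    d2[pairs[k, 1L], pairs[k, 2L]] <- d2[pairs[k, 2L], pairs[k, 1L]] <-
      d[pairs[k, 1L], pairs[k, 2L]] - eps
    g2 <- igraph::graph_from_adjacency_matrix(d2, mode = "undirected",
                                              weighted = TRUE)
    w2 <- sum(igraph::E(igraph::mst(g2))$weight)
    # forced edge participates in a minimum tree iff the discounted optimum
    # drops by exactly eps
    keep[k] <- abs((base_w - w2) - eps) < 1e-9
  }
  list(weight = base_w,
       edges = data.frame(i = pairs[keep, 1L], j = pairs[keep, 2L],
                          steps = d[pairs[keep, , drop = FALSE]]))
}

# Canonical edge-set string for comparison (node indices, not labels).
edge_key <- function(df_i, df_j) {
  paste(sort(paste(pmin(df_i, df_j), pmax(df_i, df_j), sep = "-")),
        collapse = ";")
}

msn_edges_as_indices <- function(net) {
  fi <- match(net$edges$from, net$node_ids)
  ti <- match(net$edges$to, net$node_ids)
  list(i = fi, j = ti)
}

random_step_matrix <- function(n, max_steps = 8L) {
  d <- matrix(0L, n, n)
  vals <- sample.int(max_steps, n * (n - 1L) / 2L, replace = TRUE)
  d[upper.tri(d)] <- vals
  d <- d + t(d)
  d
}
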