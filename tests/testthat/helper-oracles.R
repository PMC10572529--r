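# Independent brute-force re-implementations used as oracles. These share
# no code with the package internals: adjacency is rebuilt edge by edge,
# scores are recomputed with explicit loops, argmins are found by linear
# scan, and shortest paths are enumerated by DFS.

oracle_adj <- function(net) {
  adj <- stats::setNames(lapply(net$nodes, function(x) character()), net$nodes)
  if (nrow(net$edges) > 0) {
    for (k in seq_len(nrow(net$edges))) {
      a <- unname(net$edges[k, 1]); b <- unname(net$edges[k, 2])
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

# Explicit double loop over node and neighbors: G = c * ln(c / S) with S
# summing the node's own concentration plus each covered neighbor's.
oracle_gibbs <- function(net, cvec) {
  adj <- oracle_adj(net)
  covered <- net$nodes[net$nodes %in% names(cvec)]
  G <- stats::setNames(numeric(length(covered)), covered)
  for (v in covered) {
    ci <- cvec[[v]]
    S <- ci
    for (u in adj[[v]]) {
      if (u %in% covered) S <- S + cvec[[u]]
    }
    G[[v]] <- if (ci == 0 || S == 0) 0 else ci * log(ci / S)
  }
  G
}

# Exhaustive selection: walk candidates in (G, name) order found by
# linear scans, take the first with a covered neighbor, then scan its
# neighbors for max concentration with lexicographic tie-break.
oracle_select <- function(net, cvec) {
  G <- oracle_gibbs(net, cvec)
  adj <- oracle_adj(net)
  remaining <- names(G)
  while (length(remaining) > 0) {
    best <- remaining[1]
    for (v in remaining[-1]) {
      if (G[[v]] < G[[best]] || (G[[v]] == G[[best]] && v < best)) best <- v
    }
    nb <- adj[[best]][adj[[best]] %in% names(G)]
    if (length(nb) > 0) {
      pbest <- nb[1]
      for (u in nb[-1]) {
        if (cvec[[u]] > cvec[[pbest]] || (cvec[[u]] == cvec[[pbest]] && u < pbest)) pbest <- u
      }
      return(c(anchor = best, partner = pbest))
    }
    remaining <- remaining[remaining != best]
  }
  NULL
}

# All shortest s-t paths by exhaustive simple-path DFS.
oracle_shortest_paths <- function(adj, s, t) {
  paths <- list()
  rec <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (u in adj[[v]]) if (!u %in% path) rec(c(path, u))
  }
  rec(s)
  if (length(paths) == 0) return(list())
  len <- vapply(paths, length, integer(1))
  paths[len == min(len)]
}

oracle_betweenness <- function(net) {
  adj <- oracle_adj(net)
  nodes <- net$nodes
  B <- stats::setNames(numeric(length(nodes)), nodes)
  if (length(nodes) < 3) return(B)
  prs <- utils::combn(nodes, 2)
  for (k in seq_len(ncol(prs))) {
    s <- prs[1, k]; t <- prs[2, k]
    sps <- oracle_shortest_paths(adj, s, t)
    if (length(sps) == 0) next
    for (v in nodes) {
      if (v == s || v == t) next
      through <- sum(vapply(sps, function(p) v %in% p, logical(1)))
      B[[v]] <- B[[v]] + through / length(sps)
    }
  }
  B
}

oracle_connected <- function(net) {
  if (length(net$nodes) <= 1) return(TRUE)
  adj <- oracle_adj(net)
  seen <- net$nodes[1]
  frontier <- seen
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(net$nodes)
}
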