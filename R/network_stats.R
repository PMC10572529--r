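#' Degree-distribution entropy of a network
#'
#' Shannon entropy of the node-degree distribution,
#' `H = -sum over observed degrees k >= 1 of p(k) log p(k)`, where
#' `p(k)` is the fraction of non-isolated nodes having degree `k`. Used
#' as a scalar complexity measure of a PPI network: regular graphs
#' (every node the same degree) have `H = 0`, and broader degree
#' distributions score higher. Isolated nodes (degree 0) are excluded
#' from the distribution.
#'
#' @param network a `ppi_network`.
#' @param base log base: `exp(1)` for nats (default) or 2 for bits.
#' @return Non-negative scalar entropy.
#' @export
degree_entropy <- function(network, base = exp(1)) {
  if (length(network$nodes) == 0) stop("empty network")
  deg <- network_degrees(network)
  deg <- deg[deg >= 1L]
  if (length(deg) == 0) stop("all nodes are isolated; degree distribution is empty")
  p <- as.numeric(table(deg)) / length(deg)
  -sum(p * log(p, base = base))
}

#' Betweenness centrality of every node
#'
#' For each node V, the sum over unordered node pairs \{s, t\} (both
#' distinct from V) of the fraction of shortest s--t paths that pass
#' through V. Unnormalized and endpoint-excluded; pairs in different
#' components contribute 0. Leaves and every node of a complete graph
#' score 0. Computation is delegated to igraph's Brandes algorithm.
#'
#' @param network a `ppi_network`.
#' @param normalized divide by `(n - 1)(n - 2) / 2`, the number of pairs.
#' @return Named numeric vector over all nodes, values `>= 0`.
#' @export
betweenness_centrality <- function(network, normalized = FALSE) {
  if (length(network$nodes) == 0) return(stats::setNames(numeric(), character()))
  g <- as_igraph(network)
  b <- igraph::betweenness(g, directed = FALSE, normalized = normalized)
  b[network$nodes]
}

#' Topological summary statistics of a network
#'
#' @param network a `ppi_network`.
#' @param base log base for the entropy.
#' @return A `network_stats` object: list with `n_nodes`, `n_edges`,
#'   `entropy_H`, and `betweenness` (named vector). Entropy is `NA` when
#'   every node is isolated.
#' @export
network_stats <- function(network, base = exp(1)) {
  H <- tryCatch(degree_entropy(network, base = base),
                error = function(e) NA_real_)
  structure(list(n_nodes = length(network$nodes),
                 n_edges = nrow(network$edges),
                 entropy_H = H,
                 betweenness = betweenness_centrality(network)),
            class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat("n =", x$n_nodes, " m =", x$n_edges,
      " H =", if (is.na(x$entropy_H)) "NA" else round(x$entropy_H, 4), "\n")
  top <- utils::head(sort(x$betweenness, decreasing = TRUE), 5L)
  if (length(top) > 0) {
    cat("highest betweenness:\n")
    print(round(top, 3))
  }
  invisible(x)
}

#' Write per-node network statistics as TSV
#'
#' Columns: node, degree, betweenness; plus a `# n=... m=... H=...`
#' comment line at the top.
#'
#' @param network a `ppi_network`.
#' @param path output file.
#' @return The data frame written, invisibly.
#' @export
write_stats <- function(network, path) {
  st <- network_stats(network)
  df <- data.frame(node = network$nodes,
                   degree = unname(network_degrees(network)),
                   betweenness = unname(st$betweenness),
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n=%d m=%d H=%s", st$n_nodes, st$n_edges,
                     format(st$entropy_H)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
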