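#' Construct an undirected simple PPI network
#'
#' The central graph container of the package: an undirected simple graph
#' whose nodes are gene/protein identifiers and whose edges are
#' protein-protein interactions. Self-loops are dropped (and counted) and
#' duplicate edges collapse, so the invariants hold by construction.
#'
#' @param edges two-column character matrix (or data frame) of edge
#'   endpoints; may have zero rows.
#' @param nodes character vector of node identifiers; endpoints of `edges`
#'   are added automatically, so this is only needed for isolated nodes.
#' @param provenance character vector naming the source pathway(s).
#' @return An object of class `ppi_network`: a list with elements
#'   `nodes` (sorted character vector), `edges` (two-column character
#'   matrix, each row sorted, rows in lexicographic order), `provenance`,
#'   and `n_self_loops_dropped`.
#' @examples
#' net <- ppi_network(rbind(c("A", "B"), c("B", "C")))
#' net
#' @export
ppi_network <- function(edges = NULL, nodes = character(), provenance = character()) {
  if (is.null(edges)) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  edges <- matrix(as.character(edges), ncol = 2L,
                  dimnames = list(NULL, c("from", "to")))
  nodes <- as.character(nodes)
  bad <- c(nodes, edges)[!nzchar(trimws(c(nodes, edges))) |
                           c(nodes, edges) != trimws(c(nodes, edges))]
  if (length(bad) > 0) {
    stop("node identifiers must be non-empty and free of surrounding whitespace; offending: ",
         paste(utils::head(unique(bad), 5L), collapse = ", "))
  }
  loop <- edges[, 1L] == edges[, 2L]
  n_loops <- sum(loop)
  # endpoints of dropped self-loops still name real proteins
  nodes <- c(nodes, edges[loop, 1L])
  edges <- edges[!loop, , drop = FALSE]
  if (nrow(edges) > 0) {
    swap <- edges[, 1L] > edges[, 2L]
    tmp <- edges[swap, 1L]
    edges[swap, 1L] <- edges[swap, 2L]
    edges[swap, 2L] <- tmp
    key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges <- edges[order(edges[, 1L], edges[, 2L], method = "radix"), , drop = FALSE]
  }
  nodes <- sort(unique(c(nodes, as.vector(edges))), method = "radix")
  structure(
    list(nodes = nodes, edges = edges,
         provenance = as.character(provenance),
         n_self_loops_dropped = n_loops),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("PPI network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (length(x$provenance) > 0) {
    cat("sources:", paste(x$provenance, collapse = ", "), "\n")
  }
  if (x$n_self_loops_dropped > 0) {
    cat("self-loops dropped:", x$n_self_loops_dropped, "\n")
  }
  invisible(x)
}

#' Merge pathway graphs into one PPI network
#'
#' Set union of node sets and edge sets across pathways, matching nodes by
#' exact identifier equality (the same semantics as a Cytoscape network
#' union). Duplicate edges collapse; provenance accumulates the input
#' pathway names.
#'
#' @param pathways a list of `ppi_network` objects (a single network is
#'   also accepted).
#' @return A merged `ppi_network`.
#' @examples
#' p1 <- ppi_network(rbind(c("A", "B")), provenance = "p1")
#' p2 <- ppi_network(rbind(c("B", "C")), provenance = "p2")
#' merge_networks(list(p1, p2))
#' @export
merge_networks <- function(pathways) {
  if (inherits(pathways, "ppi_network")) pathways <- list(pathways)
  if (!is.list(pathways) || length(pathways) == 0) {
    stop("merge_networks() needs a non-empty list of networks")
  }
  stopifnot(all(vapply(pathways, inherits, logical(1), "ppi_network")))
  edges <- do.call(rbind, lapply(pathways, `[[`, "edges"))
  nodes <- unique(unlist(lapply(pathways, `[[`, "nodes"), use.names = FALSE))
  prov <- unlist(lapply(pathways, `[[`, "provenance"), use.names = FALSE)
  net <- ppi_network(edges, nodes = nodes, provenance = unique(prov))
  net$n_self_loops_dropped <- sum(vapply(pathways, `[[`, integer(1),
                                         "n_self_loops_dropped"))
  net
}

#' @return named list mapping each node to the character vector of its
#'   neighbors; nodes with no edges map to `character(0)`.
#' @noRd
adjacency_list <- function(network) {
  adj <- stats::setNames(vector("list", length(network$nodes)), network$nodes)
  for (i in seq_along(adj)) adj[[i]] <- character()
  if (nrow(network$edges) > 0) {
    both <- rbind(network$edges, network$edges[, 2:1, drop = FALSE])
    sp <- split(both[, 2L], both[, 1L])
    adj[names(sp)] <- sp
  }
  adj
}

#' @noRd
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    d = as.data.frame(network$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE)
  )
}

#' Node degrees of a PPI network
#'
#' @param network a `ppi_network`.
#' @return named integer vector of degrees over all nodes.
#' @export
network_degrees <- function(network) {
  deg <- stats::setNames(integer(length(network$nodes)), network$nodes)
  if (nrow(network$edges) > 0) {
    tab <- table(as.vector(network$edges))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}
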