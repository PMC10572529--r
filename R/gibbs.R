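#' Gibbs free-energy contribution of each network protein
#'
#' For a node i with normalized concentration `c_i` and covered-neighbor
#' sum `S_i = c_i + sum over covered neighbors j of c_j`, the Gibbs score
#' is
#'
#'   G_i = c_i * ln(c_i / S_i)
#'
#' The denominator includes the node's own concentration, so the log
#' argument never exceeds 1 and every score is non-positive. The more
#' negative G_i, the larger the protein's contribution to the stability
#' of the expressed interaction network. G is a dimensionless surrogate
#' energy on the natural-log scale; no physical units are attached.
#'
#' Conventions at the boundary, both by continuity of `x ln x`:
#' `c_i = 0` gives `G_i = 0`, and `S_i = 0` (node and all covered
#' neighbors at zero) gives `G_i = 0`. An isolated covered node has
#' `S_i = c_i`, ratio 1, hence `G_i = 0`. Neighbors without expression
#' data are excluded from the sum rather than imputed; nodes without
#' expression are not scored at all.
#'
#' @param network a `ppi_network`.
#' @param profile an `expression_profile` from [normalize_sample()].
#' @return A `gibbs_scores` object: list with `sample_id`, `G` (named
#'   numeric, one entry per covered node, all `<= 0`), `c` (the covered
#'   nodes' concentrations), and `coverage`.
#' @examples
#' net <- make_rb1_toy_network()
#' prof <- normalize_sample(c(RB1 = 9, CCND1 = 10, E2F1 = 8, E2F2 = 8,
#'                            E2F3 = 8, CDK4 = 8, CDK6 = 8,
#'                            CDKN1A = 1, CDKN2A = 0))
#' gibbs_energy(net, prof)
#' @export
gibbs_energy <- function(network, profile) {
  aln <- align_to_network(profile, network)
  covered <- aln$covered
  cvec <- profile$c[covered]
  adj <- adjacency_list(network)
  G <- stats::setNames(numeric(length(covered)), covered)
  for (i in seq_along(covered)) {
    node <- covered[i]
    ci <- cvec[[node]]
    if (ci == 0) next
    nb <- intersect(adj[[node]], covered)
    S <- ci + sum(cvec[nb])
    if (S == 0) next
    G[i] <- ci * log(ci / S)
  }
  structure(list(sample_id = profile$sample_id, G = G, c = cvec,
                 coverage = aln$coverage),
            class = "gibbs_scores")
}

#' @export
print.gibbs_scores <- function(x, n = 6L, ...) {
  cat("Gibbs scores for sample '", x$sample_id, "' (",
      length(x$G), " scored nodes, coverage ",
      round(100 * x$coverage, 1), "%)\n", sep = "")
  ord <- order(x$G, names(x$G), method = "radix")
  show <- utils::head(ord, n)
  print(round(x$G[show], 4))
  invisible(x)
}

#' Write per-sample Gibbs scores as TSV
#'
#' Columns: node, c (normalized concentration), degree, covered_degree,
#' G; rows sorted by ascending G (most important protein first), ties by
#' node identifier.
#'
#' @param scores a `gibbs_scores` object.
#' @param network the `ppi_network` the scores were computed on.
#' @param path output file.
#' @return The data frame written, invisibly.
#' @export
write_scores <- function(scores, network, path) {
  adj <- adjacency_list(network)
  covered <- names(scores$G)
  df <- data.frame(
    node = covered,
    c = unname(scores$c[covered]),
    degree = unname(network_degrees(network)[covered]),
    covered_degree = vapply(covered, function(v)
      length(intersect(adj[[v]], covered)), integer(1)),
    G = unname(scores$G),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$G, df$node, method = "radix"), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
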