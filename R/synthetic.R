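#' Toy RB1 subnetwork
#'
#' A small hand-built subnetwork around the retinoblastoma protein: RB1
#' adjacent to its transcription-factor and kinase partners E2F1, E2F2,
#' E2F3, CCND1, CDK6 and CDK4, with CCND1 additionally adjacent to the
#' CDK inhibitors CDKN1A and CDKN2A. Used throughout the documentation
#' and tests as a worked example: with RB1's neighborhood highly
#' expressed and CCND1 the hottest neighbor, the method selects the
#' RB1--CCND1 interaction for inhibition.
#'
#' @return A `ppi_network` with 9 nodes and 8 edges.
#' @export
make_rb1_toy_network <- function() {
  ppi_network(rbind(
    c("RB1", "E2F1"), c("RB1", "E2F2"), c("RB1", "E2F3"),
    c("RB1", "CCND1"), c("RB1", "CDK6"), c("RB1", "CDK4"),
    c("CCND1", "CDKN1A"), c("CCND1", "CDKN2A")
  ), provenance = "rb1_toy")
}

#' Seeded Erdos-Renyi random network
#'
#' Simple undirected G(n, p) graph over nodes `N01 ... Nnn`, seeded for
#' reproducibility. Used to generate test instances; no attempt to mimic
#' the degree distribution of curated PPI networks.
#'
#' @param n_nodes number of nodes (>= 1).
#' @param edge_prob probability of each of the `n(n-1)/2` possible edges.
#' @param seed integer RNG seed.
#' @return A `ppi_network`.
#' @export
random_network <- function(n_nodes, edge_prob, seed = 1L) {
  stopifnot(n_nodes >= 1, edge_prob >= 0, edge_prob <= 1)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- if (n_nodes >= 2) t(utils::combn(nodes, 2L)) else
    matrix(character(), ncol = 2L)
  edges <- withr::with_seed(seed, {
    pairs[stats::runif(nrow(pairs)) < edge_prob, , drop = FALSE]
  })
  ppi_network(edges, nodes = nodes,
              provenance = sprintf("gnp_n%d_p%g_s%d", n_nodes, edge_prob, seed))
}

#' Simulate a cohort expression matrix with a planted target pair
#'
#' Generates raw expression for every network node across `n_samples`
#' samples so that, in the noise-free limit, the full pipeline provably
#' selects the planted anchor--partner interaction in every sample.
#' Pre-noise levels per sample: every gene at `background_level`, the
#' planted anchor and all its neighbors boosted to `anchor_level`, and
#' the planted partner to `partner_level` (the largest value, making it
#' the anchor's hottest neighbor). The anchor therefore carries the
#' heaviest closed neighborhood and attains the most negative Gibbs
#' score. Independent Gaussian noise (sd `noise_sd`) is added per gene
#' and sample, truncated at 0 to keep raw values valid.
#'
#' The default levels 0.1 / 0.9 / 1.0 leave a clean margin between
#' signal and background; they guarantee zero-noise recovery on anchor
#' nodes of degree >= 2 in sparse fixtures such as
#' [make_rb1_toy_network()] (verified against a brute-force oracle in
#' the test suite), but not on arbitrarily dense graphs where a
#' well-connected partner can out-score the anchor.
#'
#' @param network a `ppi_network`.
#' @param n_samples number of samples to simulate.
#' @param planted_anchor,planted_partner node identifiers; must be an
#'   existing network edge.
#' @param background_level,anchor_level,partner_level pre-noise raw
#'   levels, `background_level <= anchor_level < partner_level`.
#' @param noise_sd Gaussian noise standard deviation (>= 0), on the same
#'   scale as the levels.
#' @param seed integer RNG seed; identical seeds give identical matrices.
#' @return Numeric genes x samples matrix (samples `S001 ...`), valid
#'   input for [gibbs_targets()].
#' @export
simulate_cohort <- function(network, n_samples, planted_anchor,
                            planted_partner, background_level = 0.1,
                            anchor_level = 0.9, partner_level = 1.0,
                            noise_sd = 0, seed = 1L) {
  stopifnot(n_samples >= 1, noise_sd >= 0,
            background_level >= 0, background_level <= 1,
            background_level <= anchor_level, anchor_level < partner_level)
  adj <- adjacency_list(network)
  if (!planted_anchor %in% network$nodes ||
      !planted_partner %in% adj[[planted_anchor]]) {
    stop("planted pair (", planted_anchor, ", ", planted_partner,
         ") is not an edge of the network")
  }
  genes <- network$nodes
  base <- stats::setNames(rep(background_level, length(genes)), genes)
  base[c(planted_anchor, adj[[planted_anchor]])] <- anchor_level
  base[planted_partner] <- partner_level
  mat <- withr::with_seed(seed, {
    noise <- matrix(stats::rnorm(length(genes) * n_samples, sd = noise_sd),
                    nrow = length(genes))
    pmax(base + noise, 0)
  })
  dimnames(mat) <- list(genes, sprintf("S%03d", seq_len(n_samples)))
  mat
}
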