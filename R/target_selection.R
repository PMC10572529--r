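#' Select the anchor protein: most negative Gibbs score
#'
#' The anchor is the protein contributing the most to the overall energy
#' of the expressed network, i.e. the argmin of G. Ties break by
#' lexicographically smallest node identifier so selection is
#' deterministic.
#'
#' @param scores a `gibbs_scores` object.
#' @return A single node identifier.
#' @export
select_anchor <- function(scores) {
  if (length(scores$G) == 0) stop("no scored nodes; cannot select an anchor")
  ord <- order(scores$G, names(scores$G), method = "radix")
  names(scores$G)[ord[1L]]
}

#' Select the partner protein: anchor's highest-expressed neighbor
#'
#' Among the anchor's neighbors that carry expression data, the one with
#' the largest normalized concentration; ties break lexicographically.
#' The anchor-partner edge is the interaction proposed for inhibition.
#'
#' @param network a `ppi_network`.
#' @param anchor a node identifier.
#' @param profile an `expression_profile`.
#' @return A single node identifier.
#' @export
select_partner <- function(network, anchor, profile) {
  if (!anchor %in% network$nodes) stop("anchor '", anchor, "' is not a network node")
  nb <- intersect(adjacency_list(network)[[anchor]], names(profile$c))
  if (length(nb) == 0) {
    stop("anchor '", anchor, "' has no neighbor with expression data")
  }
  cv <- profile$c[nb]
  ord <- order(-cv, nb, method = "radix")
  nb[ord[1L]]
}

#' Select the target interaction for one sample
#'
#' Composes the full per-patient procedure: score every covered protein
#' with [gibbs_energy()], take the most-negative-G protein as anchor,
#' and pair it with its highest-expressed covered neighbor. If the top
#' anchor has no covered neighbor the next node in ascending-G order is
#' tried, so a sample is skipped only when no scored node has any
#' covered neighbor (the selected edge must exist, and on sparse data a
#' strict argmin could strand an isolated node).
#'
#' @param network a `ppi_network`.
#' @param profile an `expression_profile`.
#' @param scores optional precomputed `gibbs_scores` for this profile.
#' @return A `target_pair`: list with `sample_id`, `anchor`, `partner`,
#'   `anchor_G`, `partner_c`, and `anchor_rank` (1 if the global argmin
#'   anchor was usable, >1 if fallback occurred).
#' @examples
#' net <- make_rb1_toy_network()
#' prof <- normalize_sample(c(RB1 = 9, CCND1 = 10, E2F1 = 8, E2F2 = 8,
#'                            E2F3 = 8, CDK4 = 8, CDK6 = 8,
#'                            CDKN1A = 1, CDKN2A = 0))
#' select_target(net, prof)  # RB1 -- CCND1
#' @export
select_target <- function(network, profile, scores = NULL) {
  if (is.null(scores)) scores <- gibbs_energy(network, profile)
  ord <- order(scores$G, names(scores$G), method = "radix")
  adj <- adjacency_list(network)
  covered <- names(scores$G)
  for (rank in seq_along(ord)) {
    anchor <- covered[ord[rank]]
    nb <- intersect(adj[[anchor]], covered)
    if (length(nb) == 0) next
    cv <- scores$c[nb]
    partner <- nb[order(-cv, nb, method = "radix")[1L]]
    return(structure(
      list(sample_id = scores$sample_id, anchor = anchor, partner = partner,
           anchor_G = unname(scores$G[anchor]),
           partner_c = unname(scores$c[partner]),
           anchor_rank = rank),
      class = "target_pair"))
  }
  stop("no scored node in sample '", scores$sample_id,
       "' has a covered neighbor; sample skipped")
}

#' @export
print.target_pair <- function(x, ...) {
  cat("Target interaction for sample '", x$sample_id, "': ",
      x$anchor, " -- ", x$partner,
      "  (anchor G = ", signif(x$anchor_G, 4),
      ", partner c = ", signif(x$partner_c, 4), ")\n", sep = "")
  if (x$anchor_rank > 1L) {
    cat("note: anchor is the rank-", x$anchor_rank,
        " Gibbs minimum (better-ranked nodes had no covered neighbor)\n", sep = "")
  }
  invisible(x)
}

#' Aggregate per-sample target pairs into a cohort table
#'
#' Counts how many samples selected each target interaction and ranks
#' interactions by descending patient count (the ranking behind a Pareto
#' chart of cohort targets). By default pairs are keyed ordered, anchor
#' first, because the two roles are asymmetric (energy-selected versus
#' expression-selected); unordered keying merges A--B with B--A.
#'
#' @param pairs list of `target_pair` objects.
#' @param total_samples number of samples attempted (counts plus skips).
#' @param ordered key on the ordered (anchor, partner) pair.
#' @return A `cohort_targets` data frame with columns `anchor`,
#'   `partner`, `patient_count`, sorted by descending count then
#'   lexicographic key, and attributes `total_samples` and `n_skipped`.
#' @export
aggregate_cohort <- function(pairs, total_samples = length(pairs), ordered = TRUE) {
  if (length(pairs) > total_samples) {
    stop("total_samples is smaller than the number of selected pairs")
  }
  if (length(pairs) == 0) {
    tab <- data.frame(anchor = character(), partner = character(),
                      patient_count = integer(), stringsAsFactors = FALSE)
  } else {
    a <- vapply(pairs, `[[`, character(1), "anchor")
    p <- vapply(pairs, `[[`, character(1), "partner")
    if (!ordered) {
      swap <- a > p
      tmp <- a[swap]; a[swap] <- p[swap]; p[swap] <- tmp
    }
    key <- paste(a, p, sep = "\r")
    counts <- table(key)
    first <- !duplicated(key)
    km <- cbind(a[first], p[first])[order(key[first], method = "radix"), , drop = FALSE]
    tab <- data.frame(anchor = km[, 1L], partner = km[, 2L],
                      patient_count = as.integer(counts[sort(unique(key), method = "radix")]),
                      stringsAsFactors = FALSE)
    tab <- tab[order(-tab$patient_count, tab$anchor, tab$partner,
                     method = "radix"), , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(tab, class = c("cohort_targets", "data.frame"),
            total_samples = as.integer(total_samples),
            n_skipped = as.integer(total_samples - length(pairs)))
}

#' @export
as.data.frame.cohort_targets <- function(x, ...) {
  attr(x, "total_samples") <- NULL
  attr(x, "n_skipped") <- NULL
  class(x) <- "data.frame"
  x
}

#' Write per-sample targets as TSV
#'
#' Columns: sample_id, anchor, partner, anchor_G, partner_c.
#'
#' @param pairs list of `target_pair` objects.
#' @param path output file.
#' @return The data frame written, invisibly.
#' @export
write_targets <- function(pairs, path) {
  df <- data.frame(
    sample_id = vapply(pairs, `[[`, character(1), "sample_id"),
    anchor = vapply(pairs, `[[`, character(1), "anchor"),
    partner = vapply(pairs, `[[`, character(1), "partner"),
    anchor_G = vapply(pairs, `[[`, numeric(1), "anchor_G"),
    partner_c = vapply(pairs, `[[`, numeric(1), "partner_c"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write the cohort target table as TSV
#'
#' @param table a `cohort_targets` table from [aggregate_cohort()].
#' @param path output file.
#' @return The data frame written, invisibly.
#' @export
write_cohort_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(as.data.frame(table))
}
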