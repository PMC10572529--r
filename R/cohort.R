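#' Patient-specific target selection across a cohort
#'
#' The package's main entry point. For each sample of an expression
#' matrix it normalizes the sample to \[0, 1\], scores every covered
#' network protein's Gibbs free-energy contribution
#' `G_i = c_i ln(c_i / (c_i + sum of neighbor c))`, selects the
#' most-negative-G protein (anchor) and its highest-expressed covered
#' neighbor (partner), and aggregates the selected anchor--partner
#' interactions into a Pareto-ranked cohort table.
#'
#' Samples that share no genes with the network, or in which no scored
#' protein has a covered neighbor, are skipped and reported in the
#' result rather than dropped silently.
#'
#' @param network a `ppi_network`, e.g. from [parse_kgml()] +
#'   [merge_networks()] or [parse_edge_list()].
#' @param expression numeric genes x samples matrix as from
#'   [read_expression()] (raw non-negative values; normalization happens
#'   here, per sample).
#' @param log_transform apply `log2(x + 1)` before min-max rescaling.
#' @param ordered key the cohort table on the ordered (anchor, partner)
#'   pair; see [aggregate_cohort()].
#' @return An object of class `gibbs_targets`: list with
#'   \describe{
#'     \item{targets}{data frame of per-sample selections (sample_id,
#'       anchor, partner, anchor_G, partner_c, coverage)}
#'     \item{table}{`cohort_targets` Pareto table}
#'     \item{skipped}{data frame (sample_id, reason) of skipped samples}
#'     \item{network}{the input network}
#'     \item{call}{the matched call}
#'   }
#' @examples
#' net <- make_rb1_toy_network()
#' sim <- simulate_cohort(net, n_samples = 20, planted_anchor = "RB1",
#'                        planted_partner = "CCND1", noise_sd = 0.05,
#'                        seed = 1)
#' fit <- gibbs_targets(net, sim)
#' fit
#' summary(fit)
#' @export
gibbs_targets <- function(network, expression, log_transform = FALSE,
                          ordered = TRUE) {
  stopifnot(inherits(network, "ppi_network"), is.matrix(expression))
  samples <- colnames(expression)
  if (is.null(samples)) stop("expression matrix must have sample (column) names")
  pairs <- list()
  rows <- list()
  skipped <- list()
  for (sid in samples) {
    res <- tryCatch({
      prof <- normalize_sample(expression, sid, log_transform = log_transform)
      scores <- gibbs_energy(network, prof)
      pair <- select_target(network, prof, scores = scores)
      list(pair = pair, coverage = scores$coverage)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(sample_id = sid, reason = conditionMessage(res),
                   stringsAsFactors = FALSE)
      next
    }
    pairs[[length(pairs) + 1L]] <- res$pair
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sid, anchor = res$pair$anchor, partner = res$pair$partner,
      anchor_G = res$pair$anchor_G, partner_c = res$pair$partner_c,
      anchor_rank = res$pair$anchor_rank,
      coverage = res$coverage, stringsAsFactors = FALSE)
  }
  targets <- do.call(rbind, rows)
  if (is.null(targets)) {
    targets <- data.frame(sample_id = character(), anchor = character(),
                          partner = character(), anchor_G = numeric(),
                          partner_c = numeric(), anchor_rank = integer(),
                          coverage = numeric(), stringsAsFactors = FALSE)
  }
  skipped <- if (length(skipped) > 0) do.call(rbind, skipped) else
    data.frame(sample_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  structure(
    list(targets = targets,
         table = aggregate_cohort(pairs, total_samples = length(samples),
                                  ordered = ordered),
         skipped = skipped,
         network = network,
         call = match.call()),
    class = "gibbs_targets")
}

#' @export
print.gibbs_targets <- function(x, ...) {
  cat("Cohort PPI target selection (Gibbs free-energy scoring)\n")
  cat("network: ", length(x$network$nodes), " nodes, ",
      nrow(x$network$edges), " edges\n", sep = "")
  tot <- attr(x$table, "total_samples")
  cat("samples: ", tot, " (", nrow(x$skipped), " skipped)\n", sep = "")
  cat("distinct target interactions:", nrow(x$table), "\n")
  if (nrow(x$table) > 0) {
    top <- x$table[1L, ]
    cat("top target: ", top$anchor, " -- ", top$partner, " (",
        top$patient_count, " patients)\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.gibbs_targets <- function(object, n = 10L, ...) {
  structure(list(table = utils::head(as.data.frame(object$table), n),
                 n_interactions = nrow(object$table),
                 total_samples = attr(object$table, "total_samples"),
                 n_skipped = nrow(object$skipped),
                 mean_coverage = if (nrow(object$targets) > 0)
                   mean(object$targets$coverage) else NA_real_),
            class = "summary.gibbs_targets")
}

#' @export
print.summary.gibbs_targets <- function(x, ...) {
  cat("Cohort target table (top ", nrow(x$table), " of ",
      x$n_interactions, " interactions; ", x$total_samples, " samples, ",
      x$n_skipped, " skipped; mean network coverage ",
      round(100 * x$mean_coverage, 1), "%)\n\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Pareto chart of cohort target interactions
#'
#' Descending bar chart of patient counts per selected interaction, with
#' an optional cumulative-fraction line.
#'
#' @param x a `gibbs_targets` fit.
#' @param n show at most this many interactions.
#' @param cumulative overlay the cumulative fraction of patients.
#' @param ... passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot.gibbs_targets <- function(x, n = 20L, cumulative = TRUE, ...) {
  tab <- as.data.frame(x$table)
  if (nrow(tab) == 0) stop("no target interactions to plot")
  tab <- utils::head(tab, n)
  labs <- paste(tab$anchor, tab$partner, sep = "-")
  op <- graphics::par(mar = c(9, 4, 2, 4))
  on.exit(graphics::par(op))
  mids <- graphics::barplot(tab$patient_count, names.arg = labs, las = 2,
                            ylab = "patients", cex.names = 0.75, ...)
  if (cumulative && nrow(tab) > 1) {
    cum <- cumsum(tab$patient_count) / sum(x$table$patient_count)
    graphics::lines(mids, cum * max(tab$patient_count), type = "b", pch = 16)
    graphics::axis(4, at = pretty(c(0, 1)) * max(tab$patient_count),
                   labels = pretty(c(0, 1)))
    graphics::mtext("cumulative fraction", side = 4, line = 2.5)
  }
  invisible(mids)
}
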