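#' Read a cohort expression matrix
#'
#' Reads a delimited text file with genes in rows and samples in columns:
#' first column gene identifiers, first row sample identifiers. Values
#' must be non-negative raw expression (counts, RSEM, intensities);
#' empty cells and the token `NA` become missing values.
#'
#' @param path path to the file.
#' @param sep field delimiter; by default sniffed from the header line
#'   (tab if present, else comma).
#' @return A numeric matrix (genes x samples) with dimnames, possibly
#'   containing `NA`.
#' @export
read_expression <- function(path, sep = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("expression file needs a header line and at least one gene row")
  if (is.null(sep)) sep <- if (grepl("\t", lines[1L])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  header <- fields[[1L]]
  # header may or may not carry a stub for the gene-id column
  body_width <- widths[2L]
  n_samples <- body_width - 1L
  samples <- if (length(header) == body_width) header[-1L] else header
  if (length(samples) != n_samples) {
    stop("header declares ", length(samples), " samples but data rows have ",
         n_samples, " value columns")
  }
  bad <- which(widths[-1L] != body_width) + 1L
  if (length(bad) > 0) {
    stop("ragged row(s) at line ", paste(bad, collapse = ", "),
         ": expected ", body_width, " fields")
  }
  genes <- vapply(fields[-1L], `[[`, character(1), 1L)
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifier(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  vals <- t(vapply(fields[-1L], function(f) {
    x <- f[-1L]
    x[x %in% c("", "NA")] <- NA_character_
    suppressWarnings(as.numeric(x))
  }, numeric(n_samples)))
  if (n_samples == 1L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- list(genes, samples)
  raw_missing <- vapply(fields[-1L], function(f) sum(f[-1L] %in% c("", "NA")), integer(1))
  if (sum(is.na(vals)) > sum(raw_missing)) {
    stop("non-numeric value(s) in expression matrix")
  }
  if (any(vals < 0, na.rm = TRUE)) {
    stop("negative expression value(s); raw expression must be non-negative")
  }
  vals
}

#' Normalize one sample's expression to the unit interval
#'
#' Min-max rescaling within a sample across genes:
#' `c_g = (x_g - min) / (max - min)` over the sample's non-missing
#' values, so the most down-regulated gene maps to 0 and the most
#' up-regulated to 1. These normalized values stand in for protein
#' concentrations in the Gibbs scoring step. Normalization is
#' within-sample, never across samples, so each patient is rescaled
#' independently of the cohort.
#'
#' A constant sample (max equals min) is degenerate: all genes are set
#' to 0.5 with a warning, keeping cohort runs alive on pathological
#' samples.
#'
#' @param matrix numeric genes x samples matrix as from
#'   [read_expression()], or a named numeric vector for a single sample.
#' @param sample_id column to normalize (ignored for a vector input).
#' @param log_transform apply `log2(x + 1)` before rescaling.
#' @return An `expression_profile`: list with `sample_id` and `c`, a
#'   named numeric vector of normalized concentrations in `[0, 1]`.
#'   Missing genes are absent from `c`.
#' @export
normalize_sample <- function(matrix, sample_id = NULL, log_transform = FALSE) {
  if (is.null(dim(matrix))) {
    x <- matrix
    if (is.null(names(x))) stop("a vector sample must have gene names")
    if (is.null(sample_id)) sample_id <- "sample"
  } else {
    if (is.null(sample_id)) stop("sample_id is required for a matrix input")
    if (!sample_id %in% colnames(matrix)) stop("no such sample: ", sample_id)
    x <- matrix[, sample_id]
  }
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("sample '", sample_id, "' has no non-missing values")
  if (log_transform) x <- log2(x + 1)
  rng <- range(x)
  if (rng[1L] == rng[2L]) {
    warning("sample '", sample_id, "' is constant; all genes set to 0.5")
    cvec <- stats::setNames(rep(0.5, length(x)), names(x))
  } else {
    cvec <- (x - rng[1L]) / (rng[2L] - rng[1L])
  }
  structure(list(sample_id = sample_id, c = cvec), class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("Expression profile for sample '", x$sample_id, "': ",
      length(x$c), " genes in [", round(min(x$c), 3), ", ",
      round(max(x$c), 3), "]\n", sep = "")
  invisible(x)
}

#' Align an expression profile to a network
#'
#' Reports which network nodes carry expression values, as a
#' prerequisite for Gibbs scoring. Nodes without expression are
#' ineligible as anchor or partner.
#'
#' @param profile an `expression_profile`.
#' @param network a `ppi_network`.
#' @return A list: `covered` (character vector of network nodes with
#'   expression), `coverage` (fraction of network nodes covered),
#'   `n_unmatched_genes` (profile genes absent from the network).
#' @export
align_to_network <- function(profile, network) {
  covered <- intersect(network$nodes, names(profile$c))
  if (length(covered) == 0) {
    stop("sample '", profile$sample_id,
         "' shares no genes with the network; scoring is impossible")
  }
  list(covered = covered,
       coverage = length(covered) / length(network$nodes),
       n_unmatched_genes = sum(!names(profile$c) %in% network$nodes))
}
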