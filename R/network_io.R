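#' Parse a KEGG KGML pathway file into a PPI network
#'
#' Reads KEGG Markup Language (KGML) pathway XML. Each `entry` of type
#' `"gene"` contributes every gene identifier listed in its `name`
#' attribute (KGML entries frequently name a complex or gene family, e.g.
#' `"hsa:1869 hsa:1870"`). Each `relation` between two entries contributes
#' edges between every gene of the first entry and every gene of the
#' second (clique expansion), because the downstream scoring operates on
#' single gene-level nodes. Entries of type `"group"` are expanded to the
#' union of their component entries. Non-gene entries (compounds, linked
#' maps, orthologs) are skipped. Relation direction and subtype
#' (activation, inhibition, binding, ...) are discarded: the scoring and
#' selection steps use adjacency only. Self-loops are dropped and counted.
#'
#' @param path path to a KGML XML file, or a literal XML string.
#' @param id_map optional named character vector (or two-column data
#'   frame) mapping KGML gene identifiers (e.g. `"hsa:5925"`) to
#'   preferred identifiers (e.g. HGNC symbols); see [read_id_map()].
#'   Unmapped identifiers are kept as-is.
#' @return A `ppi_network` whose provenance records the pathway's
#'   `name`/`title` attribute.
#' @seealso [parse_edge_list()], [merge_networks()]
#' @export
parse_kgml <- function(path, id_map = NULL) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop("malformed KGML XML: ", conditionMessage(e), call. = FALSE)
  )
  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(xml2::xml_name(doc)) || xml2::xml_name(doc) != "pathway") {
    stop("not a KGML document: root element is <", xml2::xml_name(doc), ">, expected <pathway>")
  }
  pw_name <- xml2::xml_attr(doc, "name")
  if (is.na(pw_name)) pw_name <- xml2::xml_attr(doc, "title")
  if (is.na(pw_name)) pw_name <- "kgml"

  entries <- xml2::xml_find_all(doc, "./entry")
  entry_id <- xml2::xml_attr(entries, "id")
  entry_type <- xml2::xml_attr(entries, "type")
  entry_name <- xml2::xml_attr(entries, "name")

  # genes per entry id; gene entries list space-separated identifiers
  genes <- stats::setNames(vector("list", length(entry_id)), entry_id)
  for (i in seq_along(entries)) {
    if (identical(entry_type[i], "gene")) {
      genes[[i]] <- strsplit(trimws(entry_name[i]), "\\s+")[[1]]
    } else {
      genes[[i]] <- character()
    }
  }
  # group entries expand to the union of their components' genes
  for (i in seq_along(entries)) {
    if (identical(entry_type[i], "group")) {
      comp <- xml2::xml_attr(xml2::xml_find_all(entries[[i]], "./component"), "id")
      genes[[i]] <- unique(unlist(genes[comp], use.names = FALSE))
    }
  }

  if (sum(lengths(genes)) == 0) {
    warning("KGML pathway '", pw_name, "' contains no gene entries; returning an empty network")
    return(ppi_network(provenance = pw_name))
  }

  rels <- xml2::xml_find_all(doc, "./relation")
  e1 <- xml2::xml_attr(rels, "entry1")
  e2 <- xml2::xml_attr(rels, "entry2")
  edge_from <- character()
  edge_to <- character()
  for (i in seq_along(rels)) {
    g1 <- genes[[e1[i]]]
    g2 <- genes[[e2[i]]]
    if (length(g1) == 0 || length(g2) == 0) next
    grid <- expand.grid(g1, g2, stringsAsFactors = FALSE)
    edge_from <- c(edge_from, grid[[1L]])
    edge_to <- c(edge_to, grid[[2L]])
  }
  nodes <- unique(unlist(genes, use.names = FALSE))
  if (!is.null(id_map)) {
    id_map <- as_id_map(id_map)
    nodes <- remap_ids(nodes, id_map)
    edge_from <- remap_ids(edge_from, id_map)
    edge_to <- remap_ids(edge_to, id_map)
  }
  ppi_network(cbind(edge_from, edge_to), nodes = nodes, provenance = pw_name)
}

#' Parse a plain-text edge list into a PPI network
#'
#' Accepts the two common laboratory exchange formats: a two-column TSV
#' (endpoint, endpoint) and Cytoscape SIF (source, interaction type,
#' one or more targets, whitespace-delimited). Undirected edges are
#' deduplicated and self-loops dropped with a count kept on the network.
#'
#' @param path path to the file, or a character vector of lines via
#'   `text =`.
#' @param dialect `"tsv"` (two columns, tab- or whitespace-separated) or
#'   `"sif"`.
#' @param header logical; skip a single header line (TSV only).
#' @param text optional character vector of lines, bypassing `path`.
#' @param name provenance label for the resulting network.
#' @return A `ppi_network`.
#' @export
parse_edge_list <- function(path, dialect = c("tsv", "sif"), header = FALSE,
                            text = NULL, name = NULL) {
  dialect <- match.arg(dialect)
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  if (is.null(name)) name <- if (!is.null(text)) "edgelist" else basename(path)
  lineno <- seq_along(lines)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]; lineno <- lineno[keep]
  if (header && length(lines) > 0) { lines <- lines[-1L]; lineno <- lineno[-1L] }
  from <- character(); to <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[\t ]+")[[1]]
    if (dialect == "tsv") {
      if (length(f) < 2L) {
        stop("line ", lineno[i], ": expected two identifiers, found ", length(f))
      }
      from <- c(from, f[1L]); to <- c(to, f[2L])
    } else {
      if (length(f) == 1L) { # isolated node, legal SIF
        next
      }
      if (length(f) < 3L) {
        stop("line ", lineno[i], ": SIF record needs source, type, target(s); found ",
             length(f), " fields")
      }
      tgt <- f[-(1:2)]
      from <- c(from, rep(f[1L], length(tgt))); to <- c(to, tgt)
    }
  }
  # SIF single-field records contribute isolated nodes
  nodes <- character()
  if (dialect == "sif") {
    single <- vapply(strsplit(trimws(lines), "[\t ]+"), length, integer(1)) == 1L
    nodes <- trimws(lines[single])
  }
  ppi_network(cbind(from, to), nodes = nodes, provenance = name)
}

#' Write a PPI network as a plain-text edge list
#'
#' One record per edge, endpoints in lexicographic order within the
#' record and records sorted lexicographically, so output is canonical:
#' `parse_edge_list(write_edge_list(net))` reproduces `net` up to
#' provenance.
#'
#' @param network a `ppi_network`.
#' @param path output file, or `NULL` to return the lines invisibly.
#' @param dialect `"tsv"` or `"sif"` (interaction type written as `pp`).
#' @return The character vector of records, invisibly.
#' @export
write_edge_list <- function(network, path = NULL, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  e <- network$edges
  recs <- if (nrow(e) == 0) character() else if (dialect == "tsv") {
    paste(e[, 1L], e[, 2L], sep = "\t")
  } else {
    paste(e[, 1L], "pp", e[, 2L], sep = "\t")
  }
  # isolated nodes survive a SIF round-trip as single-field records
  if (dialect == "sif") {
    iso <- setdiff(network$nodes, as.vector(e))
    recs <- c(recs, iso)
  }
  if (!is.null(path)) writeLines(recs, path)
  invisible(recs)
}

#' Read a two-column identifier mapping table
#'
#' Exact-match mapping (e.g. Entrez `hsa:` identifiers to HGNC symbols)
#' applied when parsing KGML or via [apply_id_map()]. The first mapping
#' for a source identifier wins; unmapped identifiers pass through
#' unchanged.
#'
#' @param path two-column TSV (source_id, target_id), no header.
#' @return named character vector: `names` are source ids, values targets.
#' @export
read_id_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(tab) < 2L) stop("id map must have two tab-separated columns")
  as_id_map(tab)
}

as_id_map <- function(map) {
  if (is.data.frame(map) || is.matrix(map)) {
    map <- stats::setNames(as.character(map[, 2L]), as.character(map[, 1L]))
  }
  map[!duplicated(names(map))] # first mapping wins
}

remap_ids <- function(ids, map) {
  hit <- ids %in% names(map)
  ids[hit] <- unname(map[ids[hit]])
  ids
}

#' Relabel network nodes through an identifier map
#'
#' @param network a `ppi_network`.
#' @param id_map named character vector or two-column table; see
#'   [read_id_map()].
#' @return A relabeled `ppi_network`; the count of unmapped nodes is
#'   reported via `message()`.
#' @export
apply_id_map <- function(network, id_map) {
  id_map <- as_id_map(id_map)
  n_unmapped <- sum(!network$nodes %in% names(id_map))
  if (n_unmapped > 0) {
    message(n_unmapped, " node(s) had no mapping and keep their original identifiers")
  }
  out <- ppi_network(
    cbind(remap_ids(network$edges[, 1L], id_map),
          remap_ids(network$edges[, 2L], id_map)),
    nodes = remap_ids(network$nodes, id_map),
    provenance = network$provenance
  )
  out$n_self_loops_dropped <- network$n_self_loops_dropped + out$n_self_loops_dropped
  out
}
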