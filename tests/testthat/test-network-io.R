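test_that("KGML gene entries and relations become nodes and edges", {
  doc <- kgml_minimal(
    c('<entry id="1" name="hsa:1" type="gene"/>',
      '<entry id="2" name="hsa:2" type="gene"/>'),
    '<relation entry1="1" entry2="2" type="PPrel"/>'
  )
  g <- parse_kgml(doc)
  expect_equal(g$nodes, c("hsa:1", "hsa:2"))
  expect_equal(nrow(g$edges), 1L)

  # no relations: correct node set, zero edges
  g0 <- parse_kgml(kgml_minimal(
    c('<entry id="1" name="hsa:1" type="gene"/>',
      '<entry id="2" name="hsa:2" type="gene"/>'), character()))
  expect_equal(g0$nodes, c("hsa:1", "hsa:2"))
  expect_equal(nrow(g0$edges), 0L)
})

test_that("multi-gene KGML entries clique-expand across relations", {
  doc <- kgml_minimal(
    c('<entry id="1" name="hsa:1 hsa:2" type="gene"/>',
      '<entry id="2" name="hsa:3" type="gene"/>'),
    '<relation entry1="1" entry2="2" type="PPrel"/>'
  )
  g <- parse_kgml(doc)
  expect_equal(length(g$nodes), 3L)
  expect_equal(nrow(g$edges), 2L) # hsa:1-hsa:3 and hsa:2-hsa:3
  expect_setequal(g$edges[, 2], "hsa:3")
})

test_that("KGML group entries expand to their components", {
  doc <- kgml_minimal(
    c('<entry id="1" name="hsa:1" type="gene"/>',
      '<entry id="2" name="hsa:2" type="gene"/>',
      '<entry id="3" name="undefined" type="group">
         <component id="1"/><component id="2"/></entry>',
      '<entry id="4" name="hsa:4" type="gene"/>'),
    '<relation entry1="3" entry2="4" type="PPrel"/>'
  )
  g <- parse_kgml(doc)
  expect_equal(nrow(g$edges), 2L) # both group members wired to hsa:4
  expect_true(all(c("hsa:1", "hsa:2", "hsa:4") %in% g$nodes))
})

test_that("KGML non-gene entries are skipped and self-relations dropped", {
  doc <- kgml_minimal(
    c('<entry id="1" name="hsa:1" type="gene"/>',
      '<entry id="2" name="cpd:C00001" type="compound"/>',
      '<entry id="3" name="path:hsa00000" type="map"/>'),
    c('<relation entry1="1" entry2="2" type="PCrel"/>',
      '<relation entry1="1" entry2="1" type="PPrel"/>')
  )
  g <- parse_kgml(doc)
  expect_equal(g$nodes, "hsa:1")
  expect_equal(nrow(g$edges), 0L)
  expect_equal(g$n_self_loops_dropped, 1L)
})

test_that("KGML error and warning contracts hold", {
  expect_error(parse_kgml("<pathway><entry"), "malformed")
  expect_warning(
    g <- parse_kgml(kgml_minimal('<entry id="1" name="cpd:X" type="compound"/>',
                                 character())),
    "no gene entries")
  expect_equal(length(g$nodes), 0L)
})

test_that("KGML identifier mapping is applied, unmapped ids kept", {
  doc <- kgml_minimal(
    c('<entry id="1" name="hsa:5925" type="gene"/>',
      '<entry id="2" name="hsa:595" type="gene"/>',
      '<entry id="3" name="hsa:999999" type="gene"/>'),
    '<relation entry1="1" entry2="2" type="PPrel"/>'
  )
  g <- parse_kgml(doc, id_map = c("hsa:5925" = "RB1", "hsa:595" = "CCND1"))
  expect_setequal(g$nodes, c("RB1", "CCND1", "hsa:999999"))
  expect_equal(unname(g$edges[1, ]), c("CCND1", "RB1"))
})

test_that("the shipped synthetic KGML fixture reproduces the toy network", {
  kg <- parse_kgml(
    system.file("extdata", "synthetic_rb1_pathway.xml", package = "ppitarget"),
    id_map = read_id_map(system.file("extdata", "entrez_to_symbol.tsv",
                                     package = "ppitarget")))
  toy <- make_rb1_toy_network()
  expect_identical(kg$nodes, toy$nodes)
  expect_identical(kg$edges, toy$edges)
})

test_that("edge lists parse with deduplication and self-loop dropping", {
  g <- parse_edge_list(text = c("A\tB", "B\tC"), dialect = "tsv")
  expect_equal(length(g$nodes), 3L)
  expect_equal(nrow(g$edges), 2L)

  g2 <- parse_edge_list(text = "A pp A", dialect = "sif")
  expect_equal(g2$nodes, "A")
  expect_equal(nrow(g2$edges), 0L)
  expect_equal(g2$n_self_loops_dropped, 1L)

  g3 <- parse_edge_list(text = c("A\tB", "A\tB", "B\tA"), dialect = "tsv")
  expect_equal(nrow(g3$edges), 1L)

  # SIF multi-target records fan out
  g4 <- parse_edge_list(text = "A pp B C D", dialect = "sif")
  expect_equal(nrow(g4$edges), 3L)

  expect_error(parse_edge_list(text = c("A\tB", "C"), dialect = "tsv"),
               "line 2")
})

test_that("write_edge_list emits canonical sorted records and round-trips", {
  net <- ppi_network(rbind(c("C", "A"), c("B", "A")))
  expect_equal(write_edge_list(net), c("A\tB", "A\tC"))
  expect_equal(write_edge_list(ppi_network()), character())

  for (seed in 1:10) {
    n <- rnd_net(seed)
    for (dialect in c("tsv", "sif")) {
      back <- parse_edge_list(text = write_edge_list(n, dialect = dialect),
                              dialect = dialect)
      expect_identical(back$edges, n$edges)
      if (dialect == "sif") expect_identical(back$nodes, n$nodes)
    }
  }
})

test_that("merge is a union: idempotent, commutative, associative", {
  p1 <- ppi_network(rbind(c("A", "B")), provenance = "p1")
  p2 <- ppi_network(rbind(c("B", "C")), provenance = "p2")
  m <- merge_networks(list(p1, p2))
  expect_equal(m$nodes, c("A", "B", "C"))
  expect_equal(nrow(m$edges), 2L)
  expect_setequal(m$provenance, c("p1", "p2"))

  self <- merge_networks(list(p1, p1))
  expect_identical(self$nodes, p1$nodes)
  expect_identical(self$edges, p1$edges)

  for (seed in 1:8) {
    a <- rnd_net(seed, n_range = 2:8, p_range = c(0.4, 0.4))
    b <- rnd_net(seed + 100, n_range = 2:8, p_range = c(0.4, 0.4))
    cc <- rnd_net(seed + 200, n_range = 2:8, p_range = c(0.4, 0.4))
    ab <- merge_networks(list(a, b))
    ba <- merge_networks(list(b, a))
    expect_identical(ab$edges, ba$edges)
    expect_identical(ab$nodes, ba$nodes)
    left <- merge_networks(list(merge_networks(list(a, b)), cc))
    right <- merge_networks(list(a, merge_networks(list(b, cc))))
    expect_identical(left$edges, right$edges)
    # union semantics by brute-force set arithmetic
    expect_setequal(ab$nodes, union(a$nodes, b$nodes))
    key <- function(n) if (nrow(n$edges)) paste(n$edges[, 1], n$edges[, 2]) else character()
    expect_setequal(key(ab), union(key(a), key(b)))
  }
  expect_error(merge_networks(list()), "non-empty")
})

test_that("network construction rejects bad identifiers and keeps graphs simple", {
  expect_error(ppi_network(rbind(c(" A", "B"))), "whitespace")
  expect_error(ppi_network(nodes = ""), "non-empty")
  n <- ppi_network(rbind(c("A", "A"), c("B", "A"), c("A", "B")))
  expect_equal(nrow(n$edges), 1L)
  expect_equal(n$n_self_loops_dropped, 1L)
})

test_that("apply_id_map relabels nodes and reports unmapped ones", {
  net <- ppi_network(rbind(c("x1", "x2"), c("x2", "x3")))
  expect_message(out <- apply_id_map(net, c(x1 = "A", x2 = "B")), "1 node")
  expect_setequal(out$nodes, c("A", "B", "x3"))
  # mapping two ids onto one symbol collapses them and drops the loop
  out2 <- suppressMessages(apply_id_map(net, c(x1 = "A", x2 = "A", x3 = "C")))
  expect_setequal(out2$nodes, c("A", "C"))
  expect_equal(nrow(out2$edges), 1L)
})
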