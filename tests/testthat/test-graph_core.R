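test_that("load/construct validates, canonicalises and sums duplicates", {
  g <- toy_graph(rbind(c("A", "B")), sent = 3L, doc = 2L)
  expect_s3_class(g, "lbd_graph")
  expect_equal(nrow(g$entities), 2)
  expect_equal(nrow(g$observations), 1)

  # reversed duplicate rows collapse onto one canonical edge with summed counts
  e <- data.frame(entity1 = c("A", "B"), entity2 = c("B", "A"),
                  year = 2000L, sent_count = c(3L, 1L), doc_count = c(2L, 1L))
  nodes <- data.frame(entity = c("A", "B"), entity_type = "gene",
                      year = 2000L, sent_occurrence_count = 10L)
  totals <- data.frame(year = 2000L, total_sentences = 100L,
                       total_documents = 50L)
  g2 <- lbd_graph(e, nodes, totals)
  expect_equal(nrow(g2$observations), 1)
  expect_equal(g2$observations$u, "A")
  expect_equal(g2$observations$sent_count, 4L)
  expect_equal(g2$observations$doc_count, 3L)

  bad <- e; bad$doc_count <- c(5L, 1L)  # doc > sent
  expect_error(lbd_graph(bad, nodes, totals), class = "lbd_data_error")
  expect_error(lbd_graph(e[, -3], nodes, totals), class = "lbd_data_error")
  # endpoint missing from node records
  expect_error(lbd_graph(e, nodes[1, ], totals), class = "lbd_data_error")
})

test_that("TSV round trip preserves the graph; malformed rows name lines", {
  g <- toy_graph(rbind(c("A", "B"), c("B", "C")), sent = 4L, doc = 2L)
  dir <- withr::local_tempdir()
  write_graph_tsv(g, dir)
  g2 <- read_graph_tsv(file.path(dir, "edges.tsv"), file.path(dir, "nodes.tsv"),
                       file.path(dir, "totals.tsv"))
  expect_equal(g2$observations, g$observations)
  expect_equal(g2$node_counts, g$node_counts)
  expect_equal(g2$totals, g$totals)

  bad <- file.path(dir, "bad.tsv")
  writeLines(c("entity1\tentity2\tyear\tsent_count\tdoc_count",
               "A\tB\t2000\t3\t2", "A\tC\toops\t1\t1"), bad)
  err <- tryCatch(read_graph_tsv(bad, file.path(dir, "nodes.tsv"),
                                 file.path(dir, "totals.tsv")),
                  error = function(e) conditionMessage(e))
  expect_match(err, "line 3")
})

test_that("slicing keeps exactly the pre-cutoff years and sums counts", {
  e <- data.frame(entity1 = c("A", "A", "A"), entity2 = c("B", "B", "C"),
                  year = c(1998L, 2001L, 2015L),
                  sent_count = c(2L, 5L, 1L), doc_count = c(1L, 3L, 1L))
  nodes <- expand.grid(entity = c("A", "B", "C"),
                       year = c(1998L, 2001L, 2015L),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nodes$entity_type <- "gene"; nodes$sent_occurrence_count <- 20L
  totals <- data.frame(year = c(1998L, 2001L, 2015L),
                       total_sentences = 100L, total_documents = 60L)
  g <- lbd_graph(e, nodes, totals)

  s2000 <- graph_slice(g, 2000L)
  expect_equal(nrow(s2000$edges), 1)            # edge born 2015 absent; A-C absent
  expect_equal(s2000$edges$sent_count, 2L)      # only the 1998 observation
  expect_equal(s2000$N, 100L)
  expect_equal(unname(s2000$n_x["A"]), 20L)

  s_all <- graph_slice(g, 2020L)                # cutoff beyond max year: totals
  expect_equal(sort(s_all$edges$sent_count), c(1L, 7L))
  expect_equal(s_all$N, 300L)

  # monotonicity over random cutoffs
  s1 <- graph_slice(g, 1999L)
  expect_true(all(paste(s1$edges$u, s1$edges$v) %in%
                  paste(s2000$edges$u, s2000$edges$v)))
})

test_that("b_candidates is the common-neighbour set", {
  sl <- toy_slice(rbind(c("A", "B1"), c("B1", "C"), c("A", "B2"), c("B2", "D")))
  expect_equal(b_candidates(sl, "A", "C"), "B1")
  expect_equal(b_candidates(sl, "A", "D"), "B2")
  expect_equal(b_candidates(sl, "B1", "B2"), "A")
  expect_error(b_candidates(sl, "A", "ZZ"), class = "lbd_data_error")

  # a direct A-C edge does not disqualify the common neighbour
  sl2 <- toy_slice(rbind(c("A", "X"), c("X", "C"), c("A", "C")))
  expect_equal(b_candidates(sl2, "A", "C"), "X")

  # brute-force agreement on random graphs
  set.seed(42)
  for (rep in 1:5) {
    em <- random_edge_matrix(12, 0.3)
    if (nrow(em) < 3) next
    sl3 <- toy_slice(em)
    ids <- sl3$entities$entity
    a <- ids[1]; c_id <- ids[length(ids)]
    brute <- setdiff(intersect(slice_neighbors(sl3, a),
                               slice_neighbors(sl3, c_id)), c(a, c_id))
    expect_setequal(b_candidates(sl3, a, c_id), brute)
  }
})

test_that("c_candidates is the distance-exactly-2 set", {
  sl <- toy_slice(rbind(c("A", "B"), c("B", "C1"), c("B", "C2")))
  expect_setequal(c_candidates(sl, "A"), c("C1", "C2"))

  # direct neighbours are excluded even when reachable in two hops
  sl2 <- toy_slice(rbind(c("A", "B"), c("B", "C1"), c("A", "C1")))
  expect_equal(c_candidates(sl2, "A"), character())

  sl3 <- toy_slice(rbind(c("X", "Y")), extra_nodes = "A")  # isolated A
  expect_equal(c_candidates(sl3, "A"), character())

  # brute-force shortest-path-distance oracle on random graphs
  set.seed(7)
  for (rep in 1:5) {
    em <- random_edge_matrix(10, 0.25)
    if (!nrow(em)) next
    sl4 <- toy_slice(em)
    ids <- sl4$entities$entity
    adj <- sapply(ids, function(x) ids %in% slice_neighbors(sl4, x))
    rownames(adj) <- ids
    for (a in ids[1:2]) {
      d1 <- ids[adj[, a]]
      d2 <- setdiff(ids[colSums(adj[d1, ids, drop = FALSE]) > 0], c(a, d1))
      expect_setequal(c_candidates(sl4, a), d2)
    }
  }
})

test_that("timeslice_split partitions the new links reproducibly", {
  e <- expand.grid(entity1 = "A", entity2 = sprintf("B%02d", 1:12),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  e$year <- rep(c(2000L, 2018L), each = 6)
  e$sent_count <- 2L; e$doc_count <- 1L
  # one pair seen both before and after the cutoff: not "new"
  e <- rbind(e, data.frame(entity1 = "A", entity2 = "B01", year = 2018L,
                           sent_count = 1L, doc_count = 1L))
  nodes <- expand.grid(entity = c("A", sprintf("B%02d", 1:12)),
                       year = c(2000L, 2018L),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nodes$entity_type <- "gene"; nodes$sent_occurrence_count <- 50L
  totals <- data.frame(year = c(2000L, 2018L), total_sentences = 1000L,
                       total_documents = 500L)
  g <- lbd_graph(e, nodes, totals)

  sp <- timeslice_split(g, 2016L, dev_fraction = 0.5, seed = 5)
  expect_equal(nrow(sp$dev) + nrow(sp$test), 6)   # B07..B12 only
  expect_equal(nrow(sp$dev), 3)
  expect_false("B01" %in% c(sp$dev$v, sp$test$v)) # pre+post pair excluded
  expect_length(intersect(paste(sp$dev$u, sp$dev$v),
                          paste(sp$test$u, sp$test$v)), 0)
  sp2 <- timeslice_split(g, 2016L, dev_fraction = 0.5, seed = 5)
  expect_identical(sp[c("dev", "test")], sp2[c("dev", "test")])
  expect_error(timeslice_split(g, 2019L, 0.5, 1), class = "lbd_data_error")
})

test_that("case files round-trip through the key-value format", {
  cases <- list(discovery_case("A1", "G1", 2005L, c = "C1"),
                discovery_case("A2", "G2", 2010L))
  p <- withr::local_tempfile()
  write_cases(cases, p)
  back <- read_cases(p)
  expect_equal(back, cases)
  expect_error(discovery_case("A", "A", 2000L, c = "C"),
               class = "lbd_data_error")
})
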