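test_that("tie-median rank follows the worked rule", {
  # gold heads a tied block spanning ranks 10-20: rank 15
  scores <- c(seq(100, 92, length.out = 9), rep(50, 11), 10)
  ents <- c(sprintf("top%02d", 1:9), "gold", sprintf("tie%02d", 1:10), "last")
  r <- scored_ranking(ents, scores)
  expect_equal(tie_adjusted_rank(r, "gold"), 15)
  expect_equal(tie_adjusted_rank(r, "top01"), 1)
  expect_equal(tie_adjusted_rank(r, "last"), 21)
  expect_true(is.na(tie_adjusted_rank(r, "absent")))

  # two-way tie at positions 3-4 -> 3.5
  r2 <- scored_ranking(c("a", "b", "c", "d"), c(9, 8, 7, 7))
  expect_equal(tie_adjusted_rank(r2, "c"), 3.5)
  expect_equal(tie_adjusted_rank(r2, "d"), 3.5)

  # invariance under permutation of equal-scored items
  set.seed(70)
  for (i in 1:10) {
    sc <- sample(c(5, 5, 5, 3, 3, 1))
    ids <- sample(letters[1:6])
    rr <- scored_ranking(ids, sc)
    gold <- ids[sc == 3][1]
    expect_equal(tie_adjusted_rank(rr, gold),
                 tie_adjusted_rank(scored_ranking(rev(ids), rev(sc)), gold))
  }
})

test_that("summary metrics follow their IR definitions", {
  q <- function(rks, n, un = 0L) list(gold_ranks = rks, n_candidates = n,
                                      n_unranked = un)
  m1 <- rank_metrics(list(q(4, 10)))
  expect_equal(m1$mrr, 25)                        # 1/4 * 100
  expect_equal(m1$mean_rank, 4)

  m2 <- rank_metrics(list(q(c(1, 3), 10)))
  expect_equal(m2$map, 100 * (1 + 2 / 3) / 2, tolerance = 1e-12)
  expect_equal(m2$mrr, 100)
  expect_equal(m2$r_precision, 50)                # one of R=2 golds in top 2

  # antitone in the gold's rank
  worse <- rank_metrics(list(q(c(1, 5), 10)))
  expect_lte(worse$map, m2$map)
  expect_lte(worse$r_precision, m2$r_precision)
  set.seed(71)
  for (i in 1:10) {
    r0 <- sample(2:20, 1)
    a <- rank_metrics(list(q(r0, 30)))
    b <- rank_metrics(list(q(r0 + sample(1:5, 1), 30)))
    expect_lte(b$mrr, a$mrr)
    expect_lte(b$map, a$map)
    expect_lte(b$r_precision, a$r_precision)
  }

  # unrankable queries are excluded but counted
  m3 <- rank_metrics(list(q(2, 10), q(numeric(), 10, 1L)))
  expect_equal(m3$n_queries, 1)
  expect_equal(m3$n_excluded, 1)
  expect_error(rank_metrics(list()), class = "lbd_config_error")
})

test_that("case protocol on a deterministic baseline equals hand computation", {
  # two closed cases on a fixed graph; baseline count/min is deterministic,
  # with stronger B1 legs (sent 5) than B2 legs (sent 2)
  sl_edges <- rbind(c("A", "B1"), c("B1", "C"), c("A", "B2"), c("B2", "C"))
  g <- toy_graph(sl_edges, year = 2000L, sent = c(5L, 5L, 2L, 2L))
  cases <- list(discovery_case("A", "B1", 2001L, c = "C"),
                discovery_case("A", "B2", 2001L, c = "C"))
  rep <- run_case_protocol(g, cases, approach_baseline("count", "min"))
  # min leg counts: B1 -> 5 (rank 1), B2 -> 2 (rank 2)
  expect_equal(rep$ranks[, 1], c(1, 2))
  expect_equal(rep$mean_rank, 1.5)
  expect_equal(rep$median_rank, 1.5)

  # a case whose entity is missing is skipped with a warning
  cases2 <- c(cases, list(discovery_case("ZZ", "B1", 2001L, c = "C")))
  expect_warning(rep2 <- run_case_protocol(g, cases2,
                                           approach_baseline("count", "min")),
                 "skipped")
  expect_equal(rep2$n_skipped, 1)
  expect_equal(rep2$mean_rank, 1.5)
})

test_that("case protocol keeps the best checkpoint rank", {
  # tiny synthetic world; a trained CD-2 must report min-over-checkpoints
  cfg <- synthetic_preset("tiny", seed = 2)
  g <- generate_graph(cfg)
  cases <- derive_cases(g, cfg$cutoff_year, "closed", k = 3, seed = 1,
                        min_candidates = 2)
  ap <- approach_cd2(combiner = "hadamard", emb = fast_emb_config(),
                     train = fast_train_config(epochs = 10L))
  rep <- run_case_protocol(g, cases, ap, seeds = 1L)
  sl <- graph_slice(g, cfg$cutoff_year)
  ft <- fit_approach(ap, sl, 1L)
  for (ci in seq_along(cases)) {
    per_ck <- vapply(seq_along(ft$checkpoints), function(k)
      tie_adjusted_rank(rank_query(ft, sl, cases[[ci]]$a, cases[[ci]]$c,
                                   checkpoint = k), cases[[ci]]$gold),
      numeric(1))
    expect_equal(rep$ranks[ci, 1], min(per_ck, na.rm = TRUE))
  }
})

test_that("timeslice protocol selects the argmax dev-MRR checkpoint", {
  cfg <- synthetic_preset("tiny", seed = 4)
  g <- generate_graph(cfg)
  rep <- run_timeslice_protocol(g, cfg$cutoff_year, dev_fraction = 0.5,
                                n_queries = 8L, approach_baseline("jaccard",
                                                                  "min", "sum"),
                                seed = 2L, n_dev_queries = 5L)
  expect_s3_class(rep$report, "lbd_metric_report")
  expect_length(rep$dev_mrr, 1L)   # deterministic baseline: one checkpoint
  expect_true(rep$report$mrr >= 0 && rep$report$mrr <= 100)

  ap <- approach_cd1(combiner = "hadamard", aggregator = "min",
                     emb = fast_emb_config(), train = fast_train_config())
  expect_error(run_timeslice_protocol(g, cfg$cutoff_year, 0.5, 5L, ap, 1L, 5L),
               class = "lbd_config_error")
})

test_that("timeslice protocol reproduces a brute-force pipeline oracle", {
  cfg <- synthetic_preset("tiny", seed = 6)
  g <- generate_graph(cfg)
  seed <- 3L
  rep <- run_timeslice_protocol(g, cfg$cutoff_year, dev_fraction = 0.4,
                                n_queries = 6L,
                                approach_baseline("count", "min", "sum"),
                                seed = seed, n_dev_queries = 4L)
  # independent recomputation
  sp <- timeslice_split(g, cfg$cutoff_year, 0.4, seed)
  sl <- sp$train
  pool <- sort(unique(c(sp$test$u, sp$test$v)))
  pool <- pool[pool %in% sl$entities$entity]
  as_nodes <- if (length(pool) > 6)
    lbdrank:::with_lbd_seed(seed + 211L, sort(sample(pool, 6))) else pool
  res <- lapply(as_nodes, function(a) {
    golds <- c(sp$test$v[sp$test$u == a], sp$test$u[sp$test$v == a])
    rk <- baseline_open(sl, "count", "min", "sum", a)
    grk <- vapply(golds, function(gd) tie_adjusted_rank(rk, gd), numeric(1))
    list(gold_ranks = grk[!is.na(grk)], n_candidates = nrow(rk),
         n_unranked = sum(is.na(grk)))
  })
  want <- rank_metrics(res)
  expect_equal(rep$report$mrr, want$mrr)
  expect_equal(rep$report$mean_rank, want$mean_rank)
  expect_equal(rep$report$map, want$map)
  expect_equal(rep$report$r_precision, want$r_precision)
})
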