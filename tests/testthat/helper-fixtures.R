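# Shared fixtures and independent oracles used across the test files.

# Build a single-year graph from an edge list; observations get the given
# year and per-edge counts (`sent`/`doc` recycle over edges), and
# node/total counts are derived so that all invariants hold with slack.
toy_graph <- function(edges, year = 2000L, sent = 2L, doc = 1L,
                      extra_nodes = character()) {
  e <- data.frame(entity1 = edges[, 1], entity2 = edges[, 2],
                  year = year, sent_count = sent, doc_count = doc,
                  stringsAsFactors = FALSE)
  ids <- sort(unique(c(e$entity1, e$entity2, extra_nodes)))
  inc <- sapply(ids, function(id)
    sum(e$sent_count[e$entity1 == id | e$entity2 == id]))
  nodes <- data.frame(entity = ids, entity_type = "gene", year = year,
                      sent_occurrence_count = inc + 2L,
                      stringsAsFactors = FALSE)
  totals <- data.frame(year = year,
                       total_sentences = sum(nodes$sent_occurrence_count) + 10L,
                       total_documents = sum(nodes$sent_occurrence_count))
  lbd_graph(e, nodes, totals)
}

toy_slice <- function(edges, ...) {
  g <- toy_graph(edges, ...)
  graph_slice(g, max(g$observations$year))
}

# Random undirected graph as an edge matrix over n nodes (ids N01, N02...).
random_edge_matrix <- function(n, p = 0.25) {
  ids <- sprintf("N%02d", seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
}

# Independent contingency oracle: build explicit sentence incidence sets
# and compute every metric from first principles (set sizes and an
# explicit 2x2 table), sharing no code with the package implementations.
oracle_metrics_from_sets <- function(Sx, Sy, N) {
  n_x <- length(Sx); n_y <- length(Sy)
  n_xy <- length(intersect(Sx, Sy))
  p_xy <- n_xy / N; p_x <- n_x / N; p_y <- n_y / N
  O <- matrix(c(n_xy, n_y - n_xy, n_x - n_xy, N - n_x - n_y + n_xy), 2)
  E <- outer(c(n_x, N - n_x), c(n_y, N - n_y)) / N
  llr_terms <- mapply(function(o, e) if (o == 0) 0 else o * log(o / e), O, E)
  list(counts = list(n_xy = n_xy, n_x = n_x, n_y = n_y, N = N),
       count = n_xy,
       jaccard = length(intersect(Sx, Sy)) / length(union(Sx, Sy)),
       scp = (n_xy / n_y) * (n_xy / n_x),    # p(x|y) * p(y|x)
       npmi = if (n_xy == 0) -1 else log(p_xy / (p_x * p_y)) / (-log(p_xy)),
       chi2 = sum((O - E)^2 / E),
       ttest = if (p_xy == 0 && p_xy == p_x * p_y) 0 else
         (p_xy - p_x * p_y) / sqrt(p_xy / N),
       llr = 2 * sum(llr_terms))
}

random_sentence_sets <- function(N = 60L) {
  n_x <- sample(2:(N - 5), 1)
  n_y <- sample(2:(N - 5), 1)
  Sx <- sample.int(N, n_x)
  # bias towards overlap so that n_xy spans its range
  Sy <- if (stats::runif(1) < 0.5)
    c(sample(Sx, min(n_y, n_x)),
      sample(setdiff(seq_len(N), Sx), max(0, n_y - n_x)))[seq_len(n_y)]
  else sample.int(N, n_y)
  list(Sx = Sx, Sy = unique(Sy), N = N)
}

# Exhaustive open-discovery oracle: enumerate all A-B-C paths by brute
# force and fold with explicit base-R arithmetic.
oracle_open_scores <- function(slice, metric_fn, agg, acc, a) {
  ids <- slice$entities$entity
  has_edge <- function(u, v) {
    e <- slice$edges
    any((e$u == u & e$v == v) | (e$u == v & e$v == u))
  }
  nb <- function(x) ids[vapply(ids, function(y) y != x && has_edge(x, y), TRUE)]
  nb_a <- nb(a)
  cand <- setdiff(ids[vapply(ids, function(cc)
    cc != a && !has_edge(a, cc) && length(intersect(nb(cc), nb_a)) > 0, TRUE)],
    a)
  scores <- vapply(cand, function(cc) {
    bs <- intersect(nb_a, nb(cc))
    ps <- vapply(bs, function(b) {
      legs <- c(metric_fn(edge_contingency(slice, a, b)),
                metric_fn(edge_contingency(slice, b, cc)))
      switch(agg, min = min(legs), avg = sum(legs) / 2, max = max(legs))
    }, numeric(1))
    switch(acc, sum = sum(ps), max = max(ps))
  }, numeric(1))
  sort(scores, decreasing = TRUE)
}

oracle_closed_scores <- function(slice, metric_fn, agg, a, c) {
  e <- slice$edges
  has_edge <- function(u, v) any((e$u == u & e$v == v) | (e$u == v & e$v == u))
  ids <- slice$entities$entity
  bs <- ids[vapply(ids, function(b)
    !(b %in% c(a, c)) && has_edge(a, b) && has_edge(b, c), TRUE)]
  scores <- vapply(bs, function(b) {
    legs <- c(metric_fn(edge_contingency(slice, a, b)),
              metric_fn(edge_contingency(slice, b, c)))
    switch(agg, min = min(legs), avg = sum(legs) / 2, max = max(legs))
  }, numeric(1))
  sort(scores, decreasing = TRUE)
}

# Small shared configs for fast neural tests.
fast_emb_config <- function(seed = 1L)
  embedding_config(dim_per_order = 8L, total_samples = 8000L, seed = seed)

fast_train_config <- function(seed = 1L, epochs = 10L, lr = 1e-3)
  train_config(batch_size = 25L, train_set_size = 300L, epochs = epochs,
               learning_rate = lr, eval_interval_epochs = 5L, seed = seed)
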