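# A small slice with clear structure used across the scorer tests.
scorer_slice <- function() {
  cl <- function(ids) t(utils::combn(ids, 2))
  toy_slice(rbind(cl(sprintf("a%d", 1:5)), cl(sprintf("b%d", 1:5)),
                  c("a1", "b1"), c("a2", "b2")), sent = 3L)
}

rand_emb <- function(slice, d = 6L, seed = 2L) {
  withr::with_seed(seed, {
    ids <- slice$entities$entity
    matrix(stats::rnorm(length(ids) * d), length(ids),
           dimnames = list(ids, NULL))
  })
}

test_that("build_link_examples balances classes and avoids real edges", {
  sl <- scorer_slice()
  emb <- rand_emb(sl)
  ex <- build_link_examples(sl, emb, "hadamard", size = 10L, seed = 4L)
  expect_equal(sum(ex$label == 1), 5)
  expect_equal(sum(ex$label == 0), 5)
  keys <- lbdrank:::slice_edge_keys(sl)
  negs <- ex$pairs[ex$label == 0, ]
  expect_false(any(lbdrank:::pair_key(negs$u, negs$v) %in% keys))
  pos <- ex$pairs[ex$label == 1, ]
  expect_true(all(lbdrank:::pair_key(pos$u, pos$v) %in% keys))

  # features recompute from the embeddings
  for (i in sample(nrow(ex$features), 5))
    expect_equal(ex$features[i, ],
                 combine_vectors(list(emb[ex$pairs$u[i], ],
                                      emb[ex$pairs$v[i], ]), "hadamard"))
  ex2 <- build_link_examples(sl, emb, "hadamard", size = 10L, seed = 4L)
  expect_identical(ex, ex2)

  # complete graph cannot supply negatives
  full <- toy_slice(t(utils::combn(c("x", "y", "z"), 2)))
  expect_error(build_link_examples(full, rand_emb(full), "avg", 4L, 1L),
               class = "lbd_data_error")
})

test_that("build_path_examples yields triangles and open wedges", {
  sl <- scorer_slice()
  emb <- rand_emb(sl)
  ex <- build_path_examples(sl, emb, "avg", size = 20L, seed = 5L)
  expect_equal(sum(ex$label == 1), 10)
  has_edge <- function(u, v)
    lbdrank:::pair_key(u, v) %in% lbdrank:::slice_edge_keys(sl)
  for (i in seq_len(nrow(ex$triples))) {
    tr <- ex$triples[i, ]
    expect_true(has_edge(tr$a, tr$b))
    expect_true(has_edge(tr$b, tr$c))
    expect_equal(has_edge(tr$a, tr$c), ex$label[i] == 1)
  }
})

test_that("pack_windows chunks, zero-pads and sums correctly", {
  set.seed(6)
  d <- 4L
  pm <- matrix(stats::rnorm(120 * d), 120)
  w <- pack_windows(pm, 50L)
  expect_equal(dim(w), c(50L, d))
  expect_equal(attr(w, "n_windows"), 3L)
  expect_equal(attr(w, "pad_rows"), 30L)
  # brute-force oracle: pad then sum explicit chunks
  padded <- rbind(pm, matrix(0, 30, d))
  want <- padded[1:50, ] + padded[51:100, ] + padded[101:150, ]
  expect_equal(unname(w[, ]), want, ignore_attr = TRUE)

  # exact fit: summation is identity
  w2 <- pack_windows(pm[1:50, ], 50L)
  expect_equal(attr(w2, "pad_rows"), 0L)
  expect_equal(unname(w2[, ]), pm[1:50, ], ignore_attr = TRUE)
  expect_error(pack_windows(matrix(0, 0, 3), 5L), class = "lbd_config_error")
})

test_that("build_stack_examples rates pairs by their direct-link jaccard", {
  sl <- scorer_slice()
  emb <- rand_emb(sl)
  ex <- build_stack_examples(sl, emb, "avg", window_height = 10L,
                             size = 12L, seed = 6L)
  has_edge <- function(u, v)
    lbdrank:::pair_key(u, v) %in% lbdrank:::slice_edge_keys(sl)
  for (i in seq_along(ex$rating)) {
    a <- ex$pairs$a[i]; cc <- ex$pairs$c[i]
    if (has_edge(a, cc))
      expect_equal(ex$rating[i],
                   metric_jaccard(edge_contingency(sl, a, cc)))
    else expect_equal(ex$rating[i], 0)
    expect_equal(dim(ex$windows[[i]]), c(10L, 6L))
    # window equals an independent packing of the path matrix
    want <- pack_windows(lbdrank:::pair_path_matrix(sl, emb, "avg", a, cc), 10L)
    expect_equal(ex$windows[[i]], want, ignore_attr = TRUE)
  }
})

test_that("MLP loss gradient matches central differences", {
  withr::with_seed(31, {
    cfg <- mlp_config(5L, 7L, seed = 1L)
    params <- lbdrank:::mlp_init(cfg)
    X <- matrix(stats::rnorm(40), 8)
    y <- sample(0:1, 8, TRUE)
    g <- lbdrank:::mlp_grad(params, X, y)
    eps <- 1e-6
    for (nm in names(params)) {
      idx <- sample(length(params[[nm]]), min(6, length(params[[nm]])))
      for (i in idx) {
        p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
        num <- (lbdrank:::mlp_loss(p1, X, y) -
                  lbdrank:::mlp_loss(p2, X, y)) / (2 * eps)
        expect_equal(g[[nm]][i], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("MLP trains on separable data; scores are positive softplus units", {
  withr::with_seed(32, {
    n <- 60
    X <- rbind(matrix(stats::rnorm(n, 2), n / 2, 2),
               matrix(stats::rnorm(n, -2), n / 2, 2))
    y <- rep(c(1L, 0L), each = n / 2)
    m <- train_mlp(list(features = X, label = y), mlp_config(2L, 16L, seed = 1L),
                   train_config(batch_size = 10L, train_set_size = n,
                                epochs = 30L, learning_rate = 5e-3,
                                eval_interval_epochs = 5L, seed = 1L))
    expect_lt(m$losses[30], m$losses[1])
    expect_equal(length(m$checkpoints), 6L)
    expect_equal(vapply(m$checkpoints, `[[`, 0L, "epoch"),
                 c(5L, 10L, 15L, 20L, 25L, 30L))
    s <- score(m, X)
    expect_true(all(s >= 0))
    # positives outscore negatives after training
    expect_gt(mean(s[y == 1]), mean(s[y == 0]))
    # batched and single-item scoring agree; repeated calls identical
    expect_equal(s[3], score(m, X[3, ]), tolerance = 1e-9)
    expect_identical(s, score(m, X))
    expect_error(score(m, matrix(0, 1, 5)), class = "lbd_config_error")
  })
})

test_that("CNN loss gradient matches central differences", {
  withr::with_seed(33, {
    cfg <- cnn_config(width = 4L, window_height = 6L, conv_height = 3L,
                      conv_filters = 3L, fc_units = 4L, seed = 1L)
    params <- lbdrank:::cnn_init(cfg)
    Xf <- matrix(stats::rnorm(5 * 24), 5)
    r <- stats::runif(5)
    rs <- list(mean = numeric(3), var = rep(1, 3))
    g <- lbdrank:::cnn_grad(params, cfg, Xf, r, rs)$grads
    eps <- 1e-5
    for (nm in names(params)) {
      idx <- sample(length(params[[nm]]), min(5, length(params[[nm]])))
      for (i in idx) {
        p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
        num <- (lbdrank:::cnn_loss(p1, cfg, Xf, r, rs, TRUE) -
                  lbdrank:::cnn_loss(p2, cfg, Xf, r, rs, TRUE)) / (2 * eps)
        expect_equal(g[[nm]][i], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("CNN converges on a constant-rating toy set and scores deterministically", {
  withr::with_seed(34, {
    cfg <- cnn_config(width = 5L, window_height = 8L, conv_height = 3L,
                      conv_filters = 4L, fc_units = 6L, seed = 2L)
    windows <- replicate(30, matrix(stats::rnorm(40), 8), simplify = FALSE)
    ex <- list(windows = windows, rating = rep(0.5, 30))
    m <- train_cnn(ex, cfg, train_config(batch_size = 10L, train_set_size = 30L,
                                         epochs = 60L, learning_rate = 5e-3,
                                         eval_interval_epochs = 20L, seed = 1L))
    expect_lt(m$losses[60], 1e-3)
    s <- score(m, windows[1:3])
    expect_true(all(s >= 0))
    expect_identical(s, score(m, windows[1:3]))
    expect_equal(s[2], score(m, windows[[2]]), tolerance = 1e-12)
    # kernel output length along the stack axis: window 8, kernel 3 -> 6
    fw <- lbdrank:::cnn_forward(m$params, cfg,
                                lbdrank:::flatten_windows(windows[1], cfg),
                                m$run_stats, FALSE)
    expect_equal(fw$P, 6L)
    expect_error(cnn_config(width = 4L, window_height = 5L, conv_height = 7L),
                 class = "lbd_config_error")
  })
})

test_that("training is reproducible from seeds", {
  sl <- scorer_slice()
  emb <- rand_emb(sl)
  ex <- build_link_examples(sl, emb, "avg", size = 40L, seed = 1L)
  tc <- train_config(batch_size = 10L, train_set_size = 40L, epochs = 5L,
                     learning_rate = 1e-3, eval_interval_epochs = 5L, seed = 9L)
  m1 <- train_mlp(ex, mlp_config(6L, 8L, seed = 3L), tc)
  m2 <- train_mlp(ex, mlp_config(6L, 8L, seed = 3L), tc)
  expect_identical(m1$params, m2$params)
  m3 <- train_mlp(ex, mlp_config(6L, 8L, seed = 4L), tc)
  expect_false(identical(m1$params, m3$params))
})
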