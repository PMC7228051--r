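# LINE-style node embeddings: first- and second-order proximity trained by
# weighted edge sampling with negative sampling, then concatenated.

#' Alias sampler for discrete distributions
#'
#' Vose's alias method: O(n) setup, O(1) per draw. Used for weighted edge
#' sampling and for the noise distribution of negative sampling.
#'
#' @param weights nonnegative weights, at least one positive.
#' @return A function `(n)` drawing `n` indices from the distribution.
#' @export
alias_sampler <- function(weights) {
  if (!length(weights) || any(weights < 0) || sum(weights) <= 0)
    lbd_stop("lbd_config_error", "alias_sampler needs nonnegative weights with a positive sum")
  n <- length(weights)
  p <- weights / sum(weights) * n
  alias <- integer(n)
  prob <- numeric(n)
  small <- which(p < 1)
  large <- which(p >= 1)
  while (length(small) && length(large)) {
    s <- small[length(small)]; small <- small[-length(small)]
    l <- large[length(large)]; large <- large[-length(large)]
    prob[s] <- p[s]
    alias[s] <- l
    p[l] <- p[l] + p[s] - 1
    if (p[l] < 1) small <- c(small, l) else large <- c(large, l)
  }
  prob[c(small, large)] <- 1
  alias[c(small, large)] <- c(small, large)
  function(m) {
    i <- sample.int(n, m, replace = TRUE)
    flip <- stats::runif(m) >= prob[i]
    i[flip] <- alias[i[flip]]
    i
  }
}

#' Jaccard edge weights of a slice
#'
#' Scores every edge of the slice with the Jaccard index of its aggregated
#' sentence counts; these weights drive LINE's edge sampling.
#'
#' @param slice an [graph_slice()].
#' @return data.frame `u`, `v`, `weight`.
#' @export
edge_weights_jaccard <- function(slice) {
  e <- slice$edges
  if (!nrow(e))
    return(data.frame(u = character(), v = character(), weight = numeric()))
  den <- slice$n_x[e$u] + slice$n_x[e$v] - e$sent_count
  data.frame(u = e$u, v = e$v, weight = e$sent_count / den,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Embedding training configuration
#'
#' @param dim_per_order dimension of each proximity order's vectors; the
#'   concatenated table has `2 * dim_per_order` columns.
#' @param negative_samples negative node draws per positive edge sample.
#' @param learning_rate initial SGD step size, decayed linearly to ~0.
#' @param total_samples number of edge draws over the whole run.
#' @param batch_size edge draws applied per parameter update (gradients of a
#'   batch are computed at the same parameters and summed).
#' @param seed integer; fixes the full sampling sequence.
#' @export
embedding_config <- function(dim_per_order = 64L, negative_samples = 5L,
                             learning_rate = 0.025, total_samples = 100000L,
                             batch_size = 25L, seed = 1L) {
  cfg <- list(dim_per_order = as.integer(dim_per_order),
              negative_samples = as.integer(negative_samples),
              learning_rate = learning_rate,
              total_samples = as.integer(total_samples),
              batch_size = as.integer(batch_size),
              seed = as.integer(seed))
  if (cfg$dim_per_order < 1 || cfg$negative_samples < 1 ||
      cfg$learning_rate <= 0 || cfg$total_samples < 1 || cfg$batch_size < 1)
    lbd_stop("lbd_config_error", "embedding_config: all settings must be positive")
  cfg
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Per-sample LINE objective and gradient
#'
#' The log-likelihood of one positive edge draw `(i, j)` with `K` negative
#' node draws: `log s(u_i . t_j) + sum_k log s(-u_i . t_k)` where `s` is the
#' logistic function and `t` are the target vectors (the vertex vectors for
#' first-order proximity, context vectors for second-order).
#' `line_sample_gradient` returns the analytic gradient; both functions
#' exist separately from the training loop so the gradient can be checked
#' numerically.
#'
#' @param u_i source vector (length d).
#' @param t_pos positive target vector (length d).
#' @param t_neg matrix of negative target vectors (K x d).
#' @return `line_sample_objective`: scalar log-likelihood.
#' @export
line_sample_objective <- function(u_i, t_pos, t_neg) {
  s <- sum(log(sigmoid(sum(u_i * t_pos))))
  if (nrow(t_neg)) s <- s + sum(log(sigmoid(-drop(t_neg %*% u_i))))
  s
}

#' @rdname line_sample_objective
#' @return `line_sample_gradient`: list `d_u_i`, `d_t_pos`, `d_t_neg`
#'   (gradients of the objective, i.e. the ascent direction).
#' @export
line_sample_gradient <- function(u_i, t_pos, t_neg) {
  g_pos <- 1 - sigmoid(sum(u_i * t_pos))       # d/dx log s(x)
  d_u <- g_pos * t_pos
  d_tp <- g_pos * u_i
  if (nrow(t_neg)) {
    g_neg <- -sigmoid(drop(t_neg %*% u_i))     # d/dx log s(-x)
    d_u <- d_u + drop(crossprod(t_neg, g_neg))
    d_tn <- outer(g_neg, u_i)
  } else d_tn <- t_neg
  list(d_u_i = d_u, d_t_pos = d_tp, d_t_neg = d_tn)
}

#' Train one proximity order of LINE embeddings
#'
#' Stochastic ascent on the negative-sampling objective: edges are drawn
#' with probability proportional to their weight (alias method), each draw
#' is paired with `negative_samples` noise nodes drawn proportionally to
#' degree^0.75, and the sampled vectors are updated with a linearly decayed
#' step. First-order proximity updates a single vertex table; second-order
#' keeps separate context vectors for the target side and returns the
#' vertex table. Isolated nodes keep their random initial vectors so the
#' embedding stays total over `nodes`.
#'
#' @param edges data.frame `u`, `v`, `weight` (e.g. [edge_weights_jaccard()]).
#' @param nodes character vector of all entity ids to embed.
#' @param order `"first"` or `"second"`.
#' @param config an [embedding_config()].
#' @return numeric matrix, one row per node (rownames = ids).
#' @export
train_line <- function(edges, nodes, order = c("first", "second"),
                       config = embedding_config()) {
  order <- match.arg(order)
  nodes <- sort(unique(as.character(nodes)))
  if (!nrow(edges) || all(edges$weight <= 0))
    lbd_stop("lbd_data_error", "train_line: graph has no positively weighted edges")
  d <- config$dim_per_order
  K <- config$negative_samples
  idx <- stats::setNames(seq_along(nodes), nodes)
  eu <- idx[edges$u]; ev <- idx[edges$v]

  deg <- numeric(length(nodes))
  dw <- rowsum(c(edges$weight, edges$weight), c(eu, ev))
  deg[as.integer(rownames(dw))] <- dw[, 1]
  noise_w <- ifelse(deg > 0, deg^0.75, 0)
  if (sum(noise_w) <= 0)
    lbd_stop("lbd_data_error", "train_line: degenerate zero-weight graph")

  with_lbd_seed(config$seed + if (order == "first") 0L else 10007L, {
    U <- matrix((stats::runif(length(nodes) * d) - 0.5) / d,
                nrow = length(nodes), dimnames = list(nodes, NULL))
    Ctx <- if (order == "second")
      matrix(0, nrow = length(nodes), ncol = d, dimnames = list(nodes, NULL))
    else NULL
    draw_edge <- alias_sampler(edges$weight)
    draw_noise <- alias_sampler(noise_w)

    total <- config$total_samples
    B <- config$batch_size
    done <- 0L
    while (done < total) {
      b <- min(B, total - done)
      e <- draw_edge(b)
      # random orientation: undirected edges are used in both directions
      fl <- stats::runif(b) < 0.5
      src <- ifelse(fl, ev[e], eu[e])
      dst <- ifelse(fl, eu[e], ev[e])
      neg <- matrix(draw_noise(b * K), nrow = b)
      lr <- config$learning_rate * max(1 - done / total, 1e-4)

      Us <- U[src, , drop = FALSE]
      Tg <- if (order == "first") U else Ctx
      Tp <- Tg[dst, , drop = FALSE]
      g_pos <- 1 - sigmoid(rowSums(Us * Tp))
      dU <- g_pos * Tp
      dTp <- g_pos * Us
      negv <- as.vector(neg)
      Tn <- Tg[negv, , drop = FALSE]
      g_neg <- -sigmoid(rowSums(Tn * Us[rep(seq_len(b), K), , drop = FALSE]))
      dU <- dU + rowsum(g_neg * Tn, rep(seq_len(b), K), reorder = TRUE)
      dTn <- g_neg * Us[rep(seq_len(b), K), , drop = FALSE]

      # sum within-batch collisions, then apply one step
      upd_src <- rowsum(dU, src)
      U[as.integer(rownames(upd_src)), ] <-
        U[as.integer(rownames(upd_src)), , drop = FALSE] + lr * upd_src
      if (order == "first") {
        upd <- rowsum(rbind(dTp, dTn), c(dst, negv))
        U[as.integer(rownames(upd)), ] <-
          U[as.integer(rownames(upd)), , drop = FALSE] + lr * upd
      } else {
        upd <- rowsum(rbind(dTp, dTn), c(dst, negv))
        Ctx[as.integer(rownames(upd)), ] <-
          Ctx[as.integer(rownames(upd)), , drop = FALSE] + lr * upd
      }
      done <- done + b
    }
    U
  })
}

#' Concatenate first- and second-order embedding halves
#'
#' @param first,second matrices with identical rownames (node ids).
#' @return combined matrix `[first || second]`.
#' @export
concat_orders <- function(first, second) {
  if (!identical(rownames(first), rownames(second)))
    lbd_stop("lbd_data_error", "concat_orders: node sets differ")
  cbind(first, second)
}

#' Train the full embedding table of a slice
#'
#' Convenience wrapper: Jaccard edge weights, [train_line()] for both
#' proximity orders, and [concat_orders()]. All slice entities are embedded,
#' including degree-zero ones (random initial vectors).
#'
#' @param slice an [graph_slice()].
#' @param config an [embedding_config()].
#' @param order `"both"` (default, concatenated), `"first"` or `"second"`.
#' @return numeric matrix of node vectors (rownames = entity ids).
#' @export
line_embeddings <- function(slice, config = embedding_config(),
                            order = c("both", "first", "second")) {
  order <- match.arg(order)
  w <- edge_weights_jaccard(slice)
  nodes <- slice$entities$entity
  if (order == "both")
    concat_orders(train_line(w, nodes, "first", config),
                  train_line(w, nodes, "second", config))
  else train_line(w, nodes, order, config)
}

#' Save / load an embedding table as plain text
#'
#' Format: a header line `<count> <dim>` followed by one `id v1 ... vd`
#' line per node (space separated).
#'
#' @param table numeric matrix with node-id rownames.
#' @param path file path.
#' @export
save_embeddings <- function(table, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(table), ncol(table)), con)
  if (nrow(table)) {
    vals <- apply(table, 1, function(r)
      paste(formatC(r, format = "g", digits = 10), collapse = " "))
    writeLines(paste(rownames(table), vals), con)
  }
  invisible(path)
}

#' @rdname save_embeddings
#' @export
load_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) != 2 || anyNA(hdr))
    lbd_stop("lbd_data_error", "embedding file %s: malformed header", path)
  n <- hdr[1]; d <- hdr[2]
  if (length(lines) - 1L != n)
    lbd_stop("lbd_data_error", "embedding file %s: expected %d rows, found %d",
             path, n, length(lines) - 1L)
  if (!n) return(matrix(numeric(), 0, d))
  parts <- strsplit(trimws(lines[-1]), "\\s+")
  bad <- which(vapply(parts, length, 1L) != d + 1L)
  if (length(bad))
    lbd_stop("lbd_data_error", "embedding file %s line %d: expected %d values",
             path, bad[1] + 1L, d + 1L)
  ids <- vapply(parts, `[`, "", 1L)
  m <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  if (anyNA(m))
    lbd_stop("lbd_data_error", "embedding file %s: non-numeric vector entry", path)
  rownames(m) <- ids
  m
}
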