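# Training-set construction for the neural scorers. Positives come from
# structures present in the training slice; negatives are sampled
# structures that do not exist there (links that did not form, or wedges
# whose closing A-C link does not exist).

slice_edge_keys <- function(slice)
  paste(slice$edges$u, slice$edges$v, sep = "\r")

pair_key <- function(u, v) ifelse(u < v, paste(u, v, sep = "\r"),
                                  paste(v, u, sep = "\r"))

emb_rows <- function(emb, ids) {
  missing <- setdiff(ids, rownames(emb))
  if (length(missing))
    lbd_stop("lbd_data_error", "no embedding for entity '%s'", missing[1])
  emb[ids, , drop = FALSE]
}

#' Build link-level classification examples
#'
#' `size/2` positives (uniformly sampled slice edges, label 1) and `size/2`
#' negatives (uniformly sampled node pairs with no edge in the slice,
#' label 0); features are the combined endpoint embeddings.
#'
#' @param slice an [graph_slice()].
#' @param emb embedding matrix (rownames = entity ids).
#' @param combiner node combination method, see [combine_vectors()].
#' @param size total number of examples (positives + negatives).
#' @param seed integer seed.
#' @return list with `features` (matrix), `label` (0/1), `pairs`
#'   (data.frame `u`, `v`).
#' @export
build_link_examples <- function(slice, emb, combiner = "hadamard",
                                size = 1000L, seed = 1L) {
  e <- slice$edges
  nodes <- sort(intersect(slice$entities$entity, rownames(emb)))
  if (!nrow(e)) lbd_stop("lbd_data_error", "build_link_examples: empty slice")
  n_pos <- floor(size / 2); n_neg <- size - n_pos
  existing <- slice_edge_keys(slice)
  if (length(nodes) < 3 ||
      length(nodes) * (length(nodes) - 1) / 2 <= length(existing))
    lbd_stop("lbd_data_error",
             "build_link_examples: graph too small to supply negatives")
  with_lbd_seed(seed, {
    pi <- sample.int(nrow(e), n_pos, replace = TRUE)
    pos <- data.frame(u = e$u[pi], v = e$v[pi], stringsAsFactors = FALSE)
    neg_u <- character(0); neg_v <- character(0)
    guard <- 0L
    while (length(neg_u) < n_neg) {
      m <- (n_neg - length(neg_u)) * 2L + 10L
      cu <- sample(nodes, m, replace = TRUE)
      cv <- sample(nodes, m, replace = TRUE)
      ok <- cu != cv & !(pair_key(cu, cv) %in% existing)
      neg_u <- c(neg_u, cu[ok]); neg_v <- c(neg_v, cv[ok])
      guard <- guard + 1L
      if (guard > 1000L)
        lbd_stop("lbd_data_error", "build_link_examples: negative sampling stalled")
    }
    neg <- data.frame(u = neg_u[seq_len(n_neg)], v = neg_v[seq_len(n_neg)],
                      stringsAsFactors = FALSE)
    pairs <- rbind(pos, neg)
    feats <- combine_rows(list(emb_rows(emb, pairs$u), emb_rows(emb, pairs$v)),
                          combiner)
    list(features = unname(feats), label = rep(c(1L, 0L), c(n_pos, n_neg)),
         pairs = pairs)
  })
}

# All wedges a-b-c (b a common neighbour); closed = whether the a-c edge
# exists. Enumerated from the smaller adjacency side; rows canonical a < c.
enumerate_wedges <- function(slice) {
  e <- slice$edges
  if (!nrow(e)) return(data.frame(a = character(), b = character(),
                                  c = character(), closed = logical()))
  existing <- slice_edge_keys(slice)
  out <- vector("list", 0L)
  bs <- ls(slice$adj)
  for (b in bs) {
    nb <- get(b, envir = slice$adj)
    if (length(nb) < 2) next
    cmb <- utils::combn(nb, 2)
    out[[length(out) + 1L]] <-
      data.frame(a = cmb[1, ], b = b, c = cmb[2, ], stringsAsFactors = FALSE)
  }
  w <- do.call(rbind, out)
  w$closed <- pair_key(w$a, w$c) %in% existing
  w
}

#' Build path-level classification examples
#'
#' Positives are closed wedges (triangles): triples `(A, B, C)` where the
#' A--B, B--C and A--C edges all exist; negatives are open wedges whose
#' A--C link does not exist. Features combine the three node embeddings.
#'
#' @inheritParams build_link_examples
#' @export
build_path_examples <- function(slice, emb, combiner = "hadamard",
                                size = 1000L, seed = 1L) {
  w <- enumerate_wedges(slice)
  pos_pool <- w[w$closed, , drop = FALSE]
  neg_pool <- w[!w$closed, , drop = FALSE]
  if (!nrow(pos_pool) || !nrow(neg_pool))
    lbd_stop("lbd_data_error",
             "build_path_examples: slice lacks %s wedges",
             if (!nrow(pos_pool)) "closed" else "open")
  n_pos <- floor(size / 2); n_neg <- size - n_pos
  with_lbd_seed(seed, {
    pos <- pos_pool[sample.int(nrow(pos_pool), n_pos, replace = TRUE), ]
    neg <- neg_pool[sample.int(nrow(neg_pool), n_neg, replace = TRUE), ]
    tri <- rbind(pos, neg)
    feats <- combine_rows(list(emb_rows(emb, tri$a), emb_rows(emb, tri$b),
                               emb_rows(emb, tri$c)), combiner)
    list(features = unname(feats), label = rep(c(1L, 0L), c(n_pos, n_neg)),
         triples = tri[, c("a", "b", "c")])
  })
}

# Combined path vectors for every A-B-C path of a pair, Bs in lexicographic
# order (deterministic packing order).
pair_path_matrix <- function(slice, emb, combiner, a, c_id) {
  bs <- b_candidates(slice, a, c_id)
  if (!length(bs)) return(NULL)
  va <- emb_rows(emb, a); vc <- emb_rows(emb, c_id)
  combine_rows(list(va[rep(1, length(bs)), , drop = FALSE],
                    emb_rows(emb, bs),
                    vc[rep(1, length(bs)), , drop = FALSE]), combiner)
}

#' Build stacked-window regression examples for the CNN scorer
#'
#' For sampled A--C pairs that are connected by at least one two-hop path,
#' all combined A-B-C path vectors are packed into one window
#' ([pack_windows()]). The regression rating is the Jaccard index of the
#' A--C link when the direct edge exists in the slice and 0 when it does
#' not. Half the examples have a direct A--C edge, half do not.
#'
#' @inheritParams build_link_examples
#' @param window_height rows per window.
#' @return list with `windows` (list of matrices), `rating`, `pairs`.
#' @export
build_stack_examples <- function(slice, emb, combiner = "hadamard",
                                 window_height = 50L, size = 200L, seed = 1L) {
  w <- enumerate_wedges(slice)
  if (!nrow(w))
    lbd_stop("lbd_data_error", "build_stack_examples: slice has no wedges")
  pairs <- unique(w[, c("a", "c", "closed")])
  pos_pool <- pairs[pairs$closed, , drop = FALSE]
  neg_pool <- pairs[!pairs$closed, , drop = FALSE]
  if (!nrow(pos_pool) || !nrow(neg_pool))
    lbd_stop("lbd_data_error",
             "build_stack_examples: need both linked and unlinked wedge pairs")
  n_pos <- floor(size / 2); n_neg <- size - n_pos
  with_lbd_seed(seed, {
    sel <- rbind(pos_pool[sample.int(nrow(pos_pool), n_pos, replace = TRUE), ],
                 neg_pool[sample.int(nrow(neg_pool), n_neg, replace = TRUE), ])
    windows <- vector("list", nrow(sel))
    rating <- numeric(nrow(sel))
    keep <- logical(nrow(sel))
    for (i in seq_len(nrow(sel))) {
      pm <- pair_path_matrix(slice, emb, combiner, sel$a[i], sel$c[i])
      if (is.null(pm)) next  # cannot happen for wedge pairs, kept defensive
      windows[[i]] <- pack_windows(pm, window_height)
      rating[i] <- if (sel$closed[i])
        metric_jaccard(edge_contingency(slice, sel$a[i], sel$c[i])) else 0
      keep[i] <- TRUE
    }
    if (!all(keep)) warning(sprintf(
      "build_stack_examples: skipped %d pair(s) with no connecting path",
      sum(!keep)))
    list(windows = windows[keep], rating = rating[keep],
         pairs = sel[keep, c("a", "c")])
  })
}
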