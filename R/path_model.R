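# Node-combination methods and path score aggregation / accumulation.

#' Combine node vectors along a link path
#'
#' Merges an ordered list of equal-length node vectors (e.g. the A, B, C
#' embeddings of a two-hop path) into a single model input:
#' * `avg` -- elementwise mean;
#' * `concat` -- ordered concatenation (length `k * d`);
#' * `hadamard` -- elementwise product over all vectors;
#' * `w1` -- weighted-L1, pairwise `|a - b|` applied as a left fold;
#' * `w2` -- weighted-L2, pairwise `(a - b)^2` applied as a left fold.
#'
#' The pairwise operators `w1`/`w2` are extended to three or more vectors by
#' a left fold `f(f(a, b), c)`, the simplest total extension that keeps the
#' output length `d`.
#'
#' @param vectors list of >= 2 numeric vectors of equal length.
#' @param method one of `"avg"`, `"concat"`, `"hadamard"`, `"w1"`, `"w2"`.
#' @return A numeric vector (length `d`, or `k * d` for `concat`).
#' @export
combine_vectors <- function(vectors, method = c("avg", "concat", "hadamard", "w1", "w2")) {
  method <- match.arg(tolower(method[1]),
                      c("avg", "concat", "hadamard", "w1", "w2"))
  if (!is.list(vectors) || length(vectors) < 2)
    lbd_stop("lbd_config_error", "combine_vectors needs >= 2 vectors")
  d <- length(vectors[[1]])
  if (any(vapply(vectors, length, 1L) != d))
    lbd_stop("lbd_config_error", "combine_vectors: vector length mismatch")
  switch(method,
         avg = Reduce(`+`, vectors) / length(vectors),
         concat = unlist(vectors, use.names = FALSE),
         hadamard = Reduce(`*`, vectors),
         w1 = Reduce(function(a, b) abs(a - b), vectors),
         w2 = Reduce(function(a, b) (a - b)^2, vectors))
}

# Matrix form used on the hot ranking paths: each argument is an n x d
# matrix of row vectors; returns the n x d' matrix of combined rows.
combine_rows <- function(mats, method) {
  method <- tolower(method)
  switch(method,
         avg = Reduce(`+`, mats) / length(mats),
         concat = do.call(cbind, mats),
         hadamard = Reduce(`*`, mats),
         w1 = Reduce(function(a, b) abs(a - b), mats),
         w2 = Reduce(function(a, b) (a - b)^2, mats),
         lbd_stop("lbd_config_error", "unknown combiner '%s'", method))
}

combined_dim <- function(d, method, k = 2L) {
  if (tolower(method) == "concat") as.integer(k * d) else as.integer(d)
}

#' Aggregate the edge scores of one path into a path score
#'
#' @param edge_scores nonempty numeric vector of per-edge scores along a path.
#' @param f `"min"`, `"avg"` or `"max"`.
#' @return A single path score.
#' @export
aggregate_scores <- function(edge_scores, f = c("min", "avg", "max")) {
  f <- match.arg(tolower(f[1]), c("min", "avg", "max"))
  if (!length(edge_scores))
    lbd_stop("lbd_config_error", "aggregate_scores: empty score list")
  switch(f, min = min(edge_scores), avg = mean(edge_scores),
         max = max(edge_scores))
}

#' Accumulate the scores of all paths reaching one candidate
#'
#' @param path_scores nonempty numeric vector of path scores.
#' @param f `"sum"` or `"max"`.
#' @return A single candidate score.
#' @export
accumulate_scores <- function(path_scores, f = c("sum", "max")) {
  f <- match.arg(tolower(f[1]), c("sum", "max"))
  if (!length(path_scores))
    lbd_stop("lbd_config_error", "accumulate_scores: empty score list")
  switch(f, sum = sum(path_scores), max = max(path_scores))
}
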