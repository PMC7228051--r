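# Co-occurrence association metrics. Every metric consumes the sufficient
# statistics of one entity pair in one slice: sentence-level counts
# (n_xy, n_x, n_y, N) and document-level counts (d_xy, D; per-entity
# document counts are not part of the node schema and stay NA).

#' Contingency counts for an entity pair
#'
#' @param slice an [graph_slice()].
#' @param x,y entity ids.
#' @return list of class `lbd_contingency` with `n_xy`, `n_x`, `n_y`, `N`
#'   (sentence level) and `d_xy`, `d_x`, `d_y`, `D` (document level).
#' @export
edge_contingency <- function(slice, x, y) {
  if (!slice_has_entity(slice, x)) lbd_stop("lbd_data_error", "unknown entity '%s'", x)
  if (!slice_has_entity(slice, y)) lbd_stop("lbd_data_error", "unknown entity '%s'", y)
  key <- if (x < y) paste(x, y, sep = "\r") else paste(y, x, sep = "\r")
  cnt <- if (exists(key, envir = slice$ekey, inherits = FALSE))
    get(key, envir = slice$ekey) else c(sent = 0L, doc = 0L)
  contingency(n_xy = cnt[["sent"]], n_x = slice$n_x[[x]], n_y = slice$n_x[[y]],
              N = slice$N, d_xy = cnt[["doc"]], D = slice$D)
}

#' Construct contingency counts directly
#'
#' @param n_xy sentences containing both entities.
#' @param n_x,n_y sentences containing each entity.
#' @param N total sentences in the corpus slice.
#' @param d_xy documents containing both entities.
#' @param d_x,d_y documents containing each entity (optional, may be NA).
#' @param D total documents.
#' @export
contingency <- function(n_xy, n_x, n_y, N, d_xy = 0, d_x = NA, d_y = NA, D = NA) {
  if (n_xy < 0 || n_x < 0 || n_y < 0 || N < 1)
    lbd_stop("lbd_data_error", "negative contingency counts or N < 1")
  if (n_xy > min(n_x, n_y) || max(n_x, n_y) > N)
    lbd_stop("lbd_data_error",
             "invalid contingency counts: need n_xy <= min(n_x, n_y) <= N")
  structure(list(n_xy = as.numeric(n_xy), n_x = as.numeric(n_x),
                 n_y = as.numeric(n_y), N = as.numeric(N),
                 d_xy = as.numeric(d_xy), d_x = as.numeric(d_x),
                 d_y = as.numeric(d_y), D = as.numeric(D)),
            class = "lbd_contingency")
}

undef_score <- function(msg) {
  stop(structure(class = c("lbd_undefined_score", "lbd_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Co-occurrence metrics
#'
#' The eight association scores used to weight an edge between two entities,
#' computed from sentence-level contingency counts (`doc_count` uses the
#' document level). `chi_squared`, `t_test` and `llr` are the collocation
#' forms over the 2x2 sentence table with observed cells
#' `O11 = n_xy`, `O12 = n_x - n_xy`, `O21 = n_y - n_xy`,
#' `O22 = N - n_x - n_y + n_xy` and expected cells from the table marginals.
#' Natural logarithms are used throughout; `npmi` of a never-co-occurring
#' pair is defined as -1 (its infimum) so that rankings stay total.
#'
#' @param c an [edge_contingency()] / [contingency()] object.
#' @return A single numeric score.
#' @name cooc-metrics
NULL

#' @rdname cooc-metrics
#' @export
metric_count <- function(c) c$n_xy

#' @rdname cooc-metrics
#' @export
metric_doc_count <- function(c) c$d_xy

#' @rdname cooc-metrics
#' @export
metric_jaccard <- function(c) {
  den <- c$n_x + c$n_y - c$n_xy
  if (den <= 0) undef_score("jaccard undefined: both entities unseen")
  c$n_xy / den
}

#' @rdname cooc-metrics
#' @export
metric_scp <- function(c) {
  if (c$n_x <= 0 || c$n_y <= 0)
    undef_score("scp undefined: zero marginal count")
  c$n_xy^2 / (c$n_x * c$n_y)
}

#' @rdname cooc-metrics
#' @export
metric_npmi <- function(c) {
  if (c$n_xy == 0) return(-1)
  p_xy <- c$n_xy / c$N; p_x <- c$n_x / c$N; p_y <- c$n_y / c$N
  if (p_xy >= 1) undef_score("npmi undefined: joint probability 1")
  log(p_xy / (p_x * p_y)) / (-log(p_xy))
}

cont_table <- function(ct) {
  O <- c(ct$n_xy, ct$n_x - ct$n_xy, ct$n_y - ct$n_xy,
         ct$N - ct$n_x - ct$n_y + ct$n_xy)
  rx <- c(ct$n_x, ct$N - ct$n_x)   # row marginals (x present / absent)
  cy <- c(ct$n_y, ct$N - ct$n_y)
  E <- c(rx[1] * cy[1], rx[1] * cy[2], rx[2] * cy[1], rx[2] * cy[2]) / ct$N
  if (O[4] < 0) lbd_stop("lbd_data_error", "inconsistent counts: O22 < 0")
  list(O = O, E = E)
}

#' @rdname cooc-metrics
#' @export
metric_chi2 <- function(c) {
  tb <- cont_table(c)
  if (any(tb$E == 0)) undef_score("chi-squared undefined: zero expected cell")
  sum((tb$O - tb$E)^2 / tb$E)
}

#' @rdname cooc-metrics
#' @export
metric_ttest <- function(c) {
  p_xy <- c$n_xy / c$N; p_x <- c$n_x / c$N; p_y <- c$n_y / c$N
  num <- p_xy - p_x * p_y
  if (p_xy == 0) return(if (num == 0) 0 else -Inf)
  num / sqrt(p_xy / c$N)
}

#' @rdname cooc-metrics
#' @export
metric_llr <- function(c) {
  tb <- cont_table(c)
  if (any(tb$E == 0)) undef_score("llr undefined: zero expected cell")
  terms <- ifelse(tb$O == 0, 0, tb$O * log(tb$O / tb$E))  # 0 * log 0 == 0
  2 * sum(terms)
}

#' Look up a co-occurrence metric by name
#'
#' Accepted names (case-insensitive): `count`, `doc-count`, `jaccard`,
#' `scp`, `npmi`, `chi2`, `ttest`, `llr`. Underscores are treated as
#' hyphens.
#'
#' @param name metric name.
#' @return The metric function.
#' @export
cooc_metric <- function(name) {
  key <- gsub("_", "-", tolower(name))
  fns <- list("count" = metric_count, "doc-count" = metric_doc_count,
              "jaccard" = metric_jaccard, "scp" = metric_scp,
              "npmi" = metric_npmi, "chi2" = metric_chi2,
              "ttest" = metric_ttest, "llr" = metric_llr)
  if (!key %in% names(fns))
    lbd_stop("lbd_config_error", "unknown metric '%s' (expected one of %s)",
             name, paste(names(fns), collapse = ", "))
  fns[[key]]
}
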