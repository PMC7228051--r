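# Open and closed discovery: score candidate entities for one query and
# return a tie-aware ranking.

#' Scored candidate ranking
#'
#' Candidates sorted by descending score (ties broken by entity id for a
#' stable, deterministic order) with ordinal and tie-median ranks.
#'
#' @param entities character vector of candidate ids.
#' @param scores numeric scores (finite).
#' @param query optional [discovery_case()] describing the query.
#' @return data.frame of class `lbd_ranking` with columns `rank`, `entity`,
#'   `score`, `tie_adjusted_rank`.
#' @export
scored_ranking <- function(entities, scores, query = NULL) {
  stopifnot(length(entities) == length(scores))
  if (length(scores) && any(is.na(scores) | is.nan(scores)))
    lbd_stop("lbd_data_error", "scored_ranking: NA/NaN score")
  o <- order(-scores, entities)
  df <- data.frame(rank = seq_along(o), entity = unname(entities[o]),
                   score = unname(scores[o]), stringsAsFactors = FALSE,
                   row.names = NULL)
  df$tie_adjusted_rank <- tie_adjusted_ranks(df$score)
  attr(df, "query") <- query
  class(df) <- c("lbd_ranking", "data.frame")
  df
}

# Tie-median ranks of a descending-sorted score vector: a block of equal
# scores occupying positions p..q all receive (p + q) / 2.
tie_adjusted_ranks <- function(sorted_scores) {
  if (!length(sorted_scores)) return(numeric())
  r <- rle(sorted_scores)
  q <- cumsum(r$lengths)
  p <- q - r$lengths + 1
  rep((p + q) / 2, r$lengths)
}

#' @export
print.lbd_ranking <- function(x, n = 10, ...) {
  cat(sprintf("<lbd_ranking> %d candidates\n", nrow(x)))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat(sprintf("... %d more\n", nrow(x) - n))
  invisible(x)
}

# Scores for a set of links (pairs data.frame u, v) under either a trained
# neural scorer (combined embeddings) or a co-occurrence metric scorer.
link_scores <- function(scorer, slice, emb, combiner, pairs) {
  UseMethod("link_scores")
}

#' @export
link_scores.lbd_mlp <- function(scorer, slice, emb, combiner, pairs) {
  feats <- combine_rows(list(emb_rows(emb, pairs$u), emb_rows(emb, pairs$v)),
                        combiner)
  score(scorer, feats)
}

#' Metric pseudo-scorer
#'
#' Wraps a co-occurrence metric as a link scorer so the neural discovery
#' approaches (CD-1, OD-1) can be driven by a deterministic metric instead
#' of a trained network -- the oracle-substitution check that those
#' approaches reduce exactly to the baselines.
#'
#' @param metric metric name, see [cooc_metric()].
#' @export
metric_link_scorer <- function(metric) {
  structure(list(metric_fn = cooc_metric(metric), name = metric),
            class = c("lbd_metric_scorer", "lbd_scorer"))
}

#' @export
link_scores.lbd_metric_scorer <- function(scorer, slice, emb, combiner, pairs) {
  vapply(seq_len(nrow(pairs)), function(i)
    scorer$metric_fn(edge_contingency(slice, pairs$u[i], pairs$v[i])),
    numeric(1))
}

# Unique-link score cache: paths reuse many A-B / B-C links, so each
# distinct link is scored once (results are identical either way).
cached_link_scores <- function(scorer, slice, emb, combiner, u, v) {
  key <- paste(u, v, sep = "\r")
  uk <- !duplicated(key)
  s <- link_scores(scorer, slice, emb, combiner,
                   data.frame(u = u[uk], v = v[uk], stringsAsFactors = FALSE))
  unname(stats::setNames(s, key[uk])[key])
}

#' Baseline closed discovery
#'
#' Scores every B candidate by aggregating the metric scores of its two
#' legs: `agg(metric(A, B), metric(B, C))`.
#'
#' @param slice an [graph_slice()].
#' @param metric metric name, see [cooc_metric()].
#' @param aggregator `"min"`, `"avg"` or `"max"`.
#' @param a,c query entities.
#' @return An [scored_ranking()] over the B candidates.
#' @export
baseline_closed <- function(slice, metric, aggregator, a, c) {
  fn <- cooc_metric(metric)
  bs <- b_candidates(slice, a, c)
  if (!length(bs)) {
    warning(sprintf("no B candidates for (%s, %s)", a, c))
    return(scored_ranking(character(), numeric()))
  }
  s <- vapply(bs, function(b)
    aggregate_scores(c(fn(edge_contingency(slice, a, b)),
                       fn(edge_contingency(slice, b, c))), aggregator),
    numeric(1))
  scored_ranking(bs, unname(s))
}

#' Baseline open discovery
#'
#' For each C candidate, each connecting A-B-C path is scored by
#' aggregating its two leg metrics; the per-path scores are then
#' accumulated (`sum` or `max`) into the candidate score.
#'
#' @inheritParams baseline_closed
#' @param accumulator `"sum"` or `"max"`.
#' @export
baseline_open <- function(slice, metric, aggregator, accumulator, a) {
  fn <- cooc_metric(metric)
  cs <- c_candidates(slice, a)
  if (!length(cs)) {
    warning(sprintf("no C candidates for %s", a))
    return(scored_ranking(character(), numeric()))
  }
  nb_a <- slice_neighbors(slice, a)
  leg1 <- vapply(nb_a, function(b) fn(edge_contingency(slice, a, b)), numeric(1))
  s <- vapply(cs, function(cc) {
    bs <- intersect(nb_a, slice_neighbors(slice, cc))
    paths <- vapply(bs, function(b)
      aggregate_scores(c(leg1[[b]], fn(edge_contingency(slice, b, cc))),
                       aggregator), numeric(1))
    accumulate_scores(paths, accumulator)
  }, numeric(1))
  scored_ranking(cs, s)
}

#' Closed discovery, approach CD-1
#'
#' As [baseline_closed()], but each leg is scored by a trained link scorer
#' applied to the combined endpoint embeddings.
#'
#' @inheritParams baseline_closed
#' @param emb embedding matrix.
#' @param scorer a trained `lbd_mlp` (or a [metric_link_scorer()]).
#' @param combiner node combination method for the two link endpoints.
#' @export
closed_cd1 <- function(slice, emb, scorer, combiner, aggregator, a, c) {
  bs <- b_candidates(slice, a, c)
  bs <- drop_unembeddable(bs, emb, scorer)
  if (!length(bs)) return(scored_ranking(character(), numeric()))
  s1 <- cached_link_scores(scorer, slice, emb, combiner, rep(a, length(bs)), bs)
  s2 <- cached_link_scores(scorer, slice, emb, combiner, bs, rep(c, length(bs)))
  s <- mapply(function(x, y) aggregate_scores(c(x, y), aggregator), s1, s2)
  scored_ranking(bs, unname(s))
}

#' Closed discovery, approach CD-2
#'
#' Each B candidate is scored in one shot: the A, B, C embeddings are
#' combined into a single input and the path scorer predicts a score for
#' the whole A-B-C link; no aggregator is involved.
#'
#' @inheritParams closed_cd1
#' @export
closed_cd2 <- function(slice, emb, scorer, combiner, a, c) {
  bs <- b_candidates(slice, a, c)
  bs <- drop_unembeddable(bs, emb, scorer)
  if (!length(bs)) return(scored_ranking(character(), numeric()))
  va <- emb_rows(emb, a); vc <- emb_rows(emb, c)
  feats <- combine_rows(list(va[rep(1, length(bs)), , drop = FALSE],
                             emb_rows(emb, bs),
                             vc[rep(1, length(bs)), , drop = FALSE]), combiner)
  scored_ranking(bs, score(scorer, feats))
}

#' Open discovery, approach OD-1
#'
#' As [baseline_open()] with neural per-link scores: aggregate the two leg
#' scores of each path, accumulate path scores per candidate C.
#'
#' @inheritParams closed_cd1
#' @inheritParams baseline_open
#' @export
open_od1 <- function(slice, emb, scorer, combiner, aggregator, accumulator, a) {
  cs <- c_candidates(slice, a)
  cs <- drop_unembeddable(cs, emb, scorer)
  if (!length(cs)) return(scored_ranking(character(), numeric()))
  nb_a <- slice_neighbors(slice, a)
  # wedge list: one row per A-B-C path
  wl <- do.call(rbind, lapply(cs, function(cc) {
    bs <- intersect(nb_a, slice_neighbors(slice, cc))
    data.frame(b = bs, c = cc, stringsAsFactors = FALSE)
  }))
  s1 <- cached_link_scores(scorer, slice, emb, combiner,
                           rep(a, nrow(wl)), wl$b)
  s2 <- cached_link_scores(scorer, slice, emb, combiner, wl$b, wl$c)
  path <- vapply(seq_len(nrow(wl)), function(i)
    aggregate_scores(c(s1[i], s2[i]), aggregator), numeric(1))
  acc <- tapply(path, wl$c, accumulate_scores, f = accumulator)
  scored_ranking(names(acc), as.numeric(acc))
}

#' Open discovery, approach OD-2
#'
#' For each C candidate, all combined A-B-C path vectors are packed into a
#' fixed-height window ([pack_windows()]) and scored once by the CNN; no
#' aggregator or accumulator is involved.
#'
#' @inheritParams closed_cd1
#' @param scorer a trained `lbd_cnn`.
#' @param window_height window height; defaults to the scorer's.
#' @export
open_od2 <- function(slice, emb, scorer, combiner, a,
                     window_height = scorer$config$window_height) {
  cs <- c_candidates(slice, a)
  missing <- setdiff(cs, rownames(emb))
  if (length(missing)) {
    warning(sprintf("open_od2: skipping %d candidate(s) without embeddings",
                    length(missing)))
    cs <- setdiff(cs, missing)
  }
  if (!length(cs)) return(scored_ranking(character(), numeric()))
  windows <- lapply(cs, function(cc)
    pack_windows(pair_path_matrix(slice, emb, combiner, a, cc), window_height))
  scored_ranking(cs, as.numeric(score(scorer, windows)))
}

drop_unembeddable <- function(ids, emb, scorer) {
  if (inherits(scorer, "lbd_metric_scorer")) return(ids)
  missing <- setdiff(ids, rownames(emb))
  if (length(missing)) {
    warning(sprintf("skipping %d candidate(s) without embeddings",
                    length(missing)))
    ids <- setdiff(ids, missing)
  }
  ids
}
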