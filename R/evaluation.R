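# Tie-aware rank evaluation and the case-replication / time-sliced
# protocols, including checkpoint selection.

#' Tie-adjusted rank of a gold entity in a ranking
#'
#' If the gold's score is unique this is its ordinal rank; if it is tied
#' over positions `p..q` the rank is the median of the tied range,
#' `(p + q) / 2` (half-integral for even tie blocks). A gold ranked 10th
#' at the head of an 11-way tie spanning ranks 10-20 is therefore ranked
#' 15.
#'
#' @param ranking an [scored_ranking()].
#' @param gold entity id.
#' @return The tie-adjusted rank, or `NA` if the gold is not among the
#'   candidates (callers record such queries as unranked).
#' @export
tie_adjusted_rank <- function(ranking, gold) {
  i <- match(gold, ranking$entity)
  if (is.na(i)) return(NA_real_)
  ranking$tie_adjusted_rank[i]
}

query_result <- function(gold_ranks, n_candidates, n_unranked = 0L) {
  list(gold_ranks = gold_ranks, n_candidates = n_candidates,
       n_unranked = as.integer(n_unranked))
}

#' Summary metrics over a set of ranked queries
#'
#' Mean and median rank are computed over the per-query mean tie-adjusted
#' gold rank (for single-gold queries, simply the gold's rank). MRR uses
#' the best-ranked gold per query; MAP uses average precision at the
#' tie-adjusted gold ranks; R-precision counts the golds within the top R
#' positions where R is the query's gold count. MRR, MAP and R-precision
#' are reported on a 0-100 scale. Queries whose golds all fall outside the
#' candidate space are excluded from the averages and counted in
#' `n_excluded`.
#'
#' @param results list of query results, each a list with `gold_ranks`
#'   (tie-adjusted ranks of the golds found among candidates),
#'   `n_candidates`, and optionally `n_unranked` (golds not found).
#' @return list of class `lbd_metric_report`.
#' @export
rank_metrics <- function(results) {
  if (!length(results))
    lbd_stop("lbd_config_error", "rank_metrics: no query results")
  ok <- vapply(results, function(r) length(r$gold_ranks) > 0, logical(1))
  excluded <- sum(!ok)
  results <- results[ok]
  if (!length(results))
    lbd_stop("lbd_data_error", "rank_metrics: every query was unrankable")
  per_mean <- vapply(results, function(r) mean(r$gold_ranks), numeric(1))
  rr <- vapply(results, function(r) 1 / min(r$gold_ranks), numeric(1))
  ap <- vapply(results, function(r) {
    rks <- sort(r$gold_ranks)
    mean(vapply(rks, function(x) sum(rks <= x) / x, numeric(1)))
  }, numeric(1))
  rp <- vapply(results, function(r) {
    R <- length(r$gold_ranks) + r$n_unranked
    sum(r$gold_ranks <= R) / R
  }, numeric(1))
  structure(list(mean_rank = mean(per_mean),
                 median_rank = stats::median(per_mean),
                 mrr = 100 * mean(rr), map = 100 * mean(ap),
                 r_precision = 100 * mean(rp),
                 n_queries = length(results), n_excluded = excluded),
            class = "lbd_metric_report")
}

#' @export
print.lbd_metric_report <- function(x, ...) {
  cat(sprintf(paste0("<lbd_metric_report> %d queries (%d excluded)\n",
                     "  mean rank %.1f | median rank %.1f | MRR %.2f | ",
                     "MAP %.2f | R-prec %.2f\n"),
              x$n_queries, x$n_excluded, x$mean_rank, x$median_rank,
              x$mrr, x$map, x$r_precision))
  invisible(x)
}

#' Discovery approach specifications
#'
#' An approach bundles everything needed to (optionally) train and then
#' rank candidates for a discovery query: the scoring family, the node
#' combination method, aggregator/accumulator choices, and the embedding
#' and training configurations for the neural members.
#'
#' * `approach_baseline` -- co-occurrence metric with aggregator (closed)
#'   and accumulator (open); deterministic, no training.
#' * `approach_cd1` / `approach_od1` -- MLP link scorer on combined
#'   endpoint embeddings feeding the aggregator (and accumulator for open
#'   discovery).
#' * `approach_cd2` -- MLP path scorer on the combined A-B-C embeddings.
#' * `approach_od2` -- CNN over stacked combined path vectors.
#'
#' @param metric metric name for the baseline ([cooc_metric()]).
#' @param aggregator `"min"`, `"avg"` or `"max"`.
#' @param accumulator `"sum"` or `"max"`.
#' @param combiner node combination method ([combine_vectors()]).
#' @param emb embedding configuration ([embedding_config()]).
#' @param train training configuration ([train_config()]).
#' @param hidden_units MLP hidden layer size.
#' @param window_height,conv_height,conv_filters,fc_units CNN settings
#'   ([cnn_config()]).
#' @return list of class `lbd_approach`.
#' @name approaches
NULL

#' @rdname approaches
#' @export
approach_baseline <- function(metric = "jaccard", aggregator = "min",
                              accumulator = "sum") {
  structure(list(type = "baseline", metric = metric, aggregator = aggregator,
                 accumulator = accumulator, trained = FALSE),
            class = "lbd_approach")
}

#' @rdname approaches
#' @export
approach_cd1 <- function(combiner = "hadamard", aggregator = "min",
                         emb = embedding_config(), train = train_config(),
                         hidden_units = 100L) {
  structure(list(type = "cd1", combiner = combiner, aggregator = aggregator,
                 emb = emb, train = train, hidden_units = hidden_units,
                 trained = TRUE, kind = "link"),
            class = "lbd_approach")
}

#' @rdname approaches
#' @export
approach_cd2 <- function(combiner = "hadamard", emb = embedding_config(),
                         train = train_config(), hidden_units = 100L) {
  structure(list(type = "cd2", combiner = combiner, emb = emb, train = train,
                 hidden_units = hidden_units, trained = TRUE, kind = "path"),
            class = "lbd_approach")
}

#' @rdname approaches
#' @export
approach_od1 <- function(combiner = "hadamard", aggregator = "min",
                         accumulator = "sum", emb = embedding_config(),
                         train = train_config(), hidden_units = 100L) {
  structure(list(type = "od1", combiner = combiner, aggregator = aggregator,
                 accumulator = accumulator, emb = emb, train = train,
                 hidden_units = hidden_units, trained = TRUE, kind = "link"),
            class = "lbd_approach")
}

#' @rdname approaches
#' @export
approach_od2 <- function(combiner = "hadamard", emb = embedding_config(),
                         train = train_config(learning_rate = 1e-5),
                         window_height = 50L, conv_height = 7L,
                         conv_filters = 128L, fc_units = 128L) {
  structure(list(type = "od2", combiner = combiner, emb = emb, train = train,
                 window_height = as.integer(window_height),
                 conv_height = as.integer(conv_height),
                 conv_filters = as.integer(conv_filters),
                 fc_units = as.integer(fc_units), trained = TRUE,
                 kind = "stack"),
            class = "lbd_approach")
}

#' @export
print.lbd_approach <- function(x, ...) {
  cat(sprintf("<lbd_approach> %s%s\n", toupper(x$type),
              if (x$type == "baseline") paste0(" (", x$metric, ")") else
                paste0(" (", x$combiner, ")")))
  invisible(x)
}

#' Fit an approach on a training slice
#'
#' Baselines need no fitting. Neural approaches train LINE embeddings on
#' the slice, build their training examples, train the scorer, and keep a
#' checkpoint every `eval_interval_epochs` so the evaluation protocols can
#' select among epochs.
#'
#' @param approach an [approach_baseline()] family object.
#' @param slice training [graph_slice()].
#' @param seed integer run seed (combined with the config seeds).
#' @return list of class `lbd_fitted` with `emb` and `checkpoints` (a list
#'   of ready-to-use scorers with an `epoch` attribute; baselines have a
#'   single `NULL` checkpoint).
#' @export
fit_approach <- function(approach, slice, seed = 1L) {
  stopifnot(inherits(approach, "lbd_approach"))
  if (!approach$trained)
    return(structure(list(approach = approach, emb = NULL,
                          checkpoints = list(NULL)),
                     class = "lbd_fitted"))
  ecfg <- approach$emb
  ecfg$seed <- ecfg$seed + 7919L * as.integer(seed)
  tcfg <- approach$train
  tcfg$seed <- tcfg$seed + as.integer(seed)
  emb <- line_embeddings(slice, ecfg)
  d <- ncol(emb)
  if (approach$kind == "link") {
    ex <- build_link_examples(slice, emb, approach$combiner,
                              size = tcfg$train_set_size, seed = tcfg$seed)
    cfg <- mlp_config(combined_dim(d, approach$combiner, 2L),
                      approach$hidden_units, seed = tcfg$seed)
    model <- train_mlp(ex, cfg, tcfg)
    ckpts <- lapply(model$checkpoints, function(ck)
      structure(list(config = cfg, params = ck$params, epoch = ck$epoch),
                class = c("lbd_mlp", "lbd_scorer")))
  } else if (approach$kind == "path") {
    ex <- build_path_examples(slice, emb, approach$combiner,
                              size = tcfg$train_set_size, seed = tcfg$seed)
    cfg <- mlp_config(combined_dim(d, approach$combiner, 3L),
                      approach$hidden_units, seed = tcfg$seed)
    model <- train_mlp(ex, cfg, tcfg)
    ckpts <- lapply(model$checkpoints, function(ck)
      structure(list(config = cfg, params = ck$params, epoch = ck$epoch),
                class = c("lbd_mlp", "lbd_scorer")))
  } else {
    ex <- build_stack_examples(slice, emb, approach$combiner,
                               window_height = approach$window_height,
                               size = tcfg$train_set_size, seed = tcfg$seed)
    cfg <- cnn_config(combined_dim(d, approach$combiner, 3L),
                      approach$window_height, approach$conv_height,
                      approach$conv_filters, approach$fc_units,
                      seed = tcfg$seed)
    model <- train_cnn(ex, cfg, tcfg)
    ckpts <- lapply(model$checkpoints, function(ck)
      structure(list(config = cfg, params = ck$params,
                     run_stats = ck$run_stats,
                     rating_scale = ck$rating_scale, epoch = ck$epoch),
                class = c("lbd_cnn", "lbd_scorer")))
  }
  structure(list(approach = approach, emb = emb, checkpoints = ckpts,
                 model = model),
            class = "lbd_fitted")
}

#' Rank the candidates of one discovery query
#'
#' Dispatches to the approach's ranking routine using one fitted
#' checkpoint.
#'
#' @param fitted an [fit_approach()] result.
#' @param slice the query's [graph_slice()].
#' @param a source entity; `c` target entity for closed discovery
#'   (`NA`/missing for open).
#' @param c target entity or `NA`.
#' @param checkpoint index into `fitted$checkpoints` (default: last).
#' @return An [scored_ranking()].
#' @export
rank_query <- function(fitted, slice, a, c = NA_character_,
                       checkpoint = length(fitted$checkpoints)) {
  ap <- fitted$approach
  sc <- fitted$checkpoints[[checkpoint]]
  closed <- !is.na(c)
  switch(ap$type,
    baseline = if (closed)
      baseline_closed(slice, ap$metric, ap$aggregator, a, c)
    else baseline_open(slice, ap$metric, ap$aggregator, ap$accumulator, a),
    cd1 = {
      if (!closed) lbd_stop("lbd_config_error", "CD-1 is a closed approach")
      closed_cd1(slice, fitted$emb, sc, ap$combiner, ap$aggregator, a, c)
    },
    cd2 = {
      if (!closed) lbd_stop("lbd_config_error", "CD-2 is a closed approach")
      closed_cd2(slice, fitted$emb, sc, ap$combiner, a, c)
    },
    od1 = {
      if (closed) lbd_stop("lbd_config_error", "OD-1 is an open approach")
      open_od1(slice, fitted$emb, sc, ap$combiner, ap$aggregator,
               ap$accumulator, a)
    },
    od2 = {
      if (closed) lbd_stop("lbd_config_error", "OD-2 is an open approach")
      open_od2(slice, fitted$emb, sc, ap$combiner, a)
    })
}

#' Case-replication protocol
#'
#' For each seed the approach is fitted on each case's pre-cutoff slice
#' (cases sharing a cutoff share one fit) and every checkpoint ranks the
#' case's gold; the best checkpoint rank per case is kept. The report
#' averages per-case best ranks within each run and then across runs,
#' with the standard deviation of the per-run means. Cases whose query
#' entities are absent from their slice are skipped with a warning; cases
#' whose gold is outside the candidate set are recorded as unranked and
#' excluded from the averages.
#'
#' @param graph an [lbd_graph()].
#' @param cases list of [discovery_case()] records.
#' @param approach an approach specification, see [approaches].
#' @param seeds integer vector of run seeds (deterministic approaches run
#'   once).
#' @return list of class `lbd_case_report`: per-case best ranks per seed,
#'   per-seed means/medians, overall `mean_rank`, `median_rank`,
#'   `sd_mean_rank`, and skip/unranked counts.
#' @export
run_case_protocol <- function(graph, cases, approach, seeds = 1L) {
  stopifnot(length(cases) >= 1)
  if (!approach$trained) seeds <- seeds[1]
  cutoffs <- vapply(cases, function(cs) cs$cutoff_year, integer(1))
  slices <- lapply(sort(unique(cutoffs)), function(y) graph_slice(graph, y))
  names(slices) <- sort(unique(cutoffs))
  ranks <- matrix(NA_real_, length(cases), length(seeds))
  skipped <- 0L
  for (si in seq_along(seeds)) {
    fits <- lapply(slices, function(sl) fit_approach(approach, sl, seeds[si]))
    for (ci in seq_along(cases)) {
      cs <- cases[[ci]]
      sl <- slices[[as.character(cs$cutoff_year)]]
      ids <- c(cs$a, if (!is.na(cs$c)) cs$c)
      if (!all(ids %in% sl$entities$entity)) {
        if (si == 1L) {
          warning(sprintf("case %d: query entity absent from slice; skipped", ci))
          skipped <- skipped + 1L
        }
        next
      }
      ft <- fits[[as.character(cs$cutoff_year)]]
      best <- Inf
      for (k in seq_along(ft$checkpoints)) {
        rk <- tie_adjusted_rank(rank_query(ft, sl, cs$a, cs$c, checkpoint = k),
                                cs$gold)
        if (!is.na(rk)) best <- min(best, rk)
      }
      ranks[ci, si] <- if (is.finite(best)) best else NA_real_
    }
  }
  per_seed_mean <- colMeans(ranks, na.rm = TRUE)
  per_seed_median <- apply(ranks, 2, stats::median, na.rm = TRUE)
  structure(list(ranks = ranks, seeds = seeds,
                 per_seed_mean = per_seed_mean,
                 per_seed_median = per_seed_median,
                 mean_rank = mean(per_seed_mean),
                 median_rank = mean(per_seed_median),
                 sd_mean_rank = if (length(seeds) > 1)
                   stats::sd(per_seed_mean) else NA_real_,
                 n_cases = length(cases), n_skipped = skipped,
                 n_unranked = sum(is.na(ranks[, 1])) - skipped),
            class = "lbd_case_report")
}

#' @export
print.lbd_case_report <- function(x, ...) {
  cat(sprintf(paste0("<lbd_case_report> %d cases, %d run(s): mean rank %.1f",
                     " (sd %s), median %.1f; %d skipped\n"),
              x$n_cases, length(x$seeds), x$mean_rank,
              if (is.na(x$sd_mean_rank)) "-" else sprintf("%.1f", x$sd_mean_rank),
              x$median_rank, x$n_skipped))
  invisible(x)
}

# Gold partners of `a` among post-cutoff new links.
new_partners <- function(pairs, a) {
  c(pairs$v[pairs$u == a], pairs$u[pairs$v == a])
}

#' Time-sliced protocol
#'
#' The graph is split at `cutoff_year` into a training slice and
#' development/test sets of new links. The approach is fitted on the
#' training slice; every checkpoint is scored on the development queries
#' and the checkpoint with the highest development MRR is evaluated once
#' on the test queries. A query takes one sampled A node, ranks its
#' two-hop candidates, and treats A's new post-cutoff partners inside the
#' candidate set as golds; queries with no rankable gold are excluded and
#' counted.
#'
#' @inheritParams run_case_protocol
#' @param cutoff_year split year.
#' @param dev_fraction fraction of new links assigned to development.
#' @param n_queries number of A nodes sampled from the test set (all are
#'   used, with a warning, if fewer are available).
#' @param n_dev_queries A nodes sampled from the development set for
#'   checkpoint selection.
#' @param seed integer seed (split, sampling, training).
#' @return list of class `lbd_timeslice_report` with the test
#'   [rank_metrics()] report, the selected checkpoint epoch, and the
#'   per-checkpoint development MRR curve.
#' @export
run_timeslice_protocol <- function(graph, cutoff_year, dev_fraction = 0.5,
                                   n_queries = 1000L, approach,
                                   seed = 1L, n_dev_queries = 100L) {
  sp <- timeslice_split(graph, cutoff_year, dev_fraction, seed)
  slice <- sp$train
  fitted <- fit_approach(approach, slice, seed)
  sample_as <- function(pairs, n, what) {
    pool <- sort(unique(c(pairs$u, pairs$v)))
    pool <- pool[pool %in% slice$entities$entity]
    if (length(pool) > n)
      pool <- with_lbd_seed(seed + 211L, sort(sample(pool, n)))
    else if (length(pool) < n)
      warning(sprintf("only %d %s A nodes available (requested %d)",
                      length(pool), what, n))
    pool
  }
  dev_as <- sample_as(sp$dev, n_dev_queries, "development")
  test_as <- sample_as(sp$test, n_queries, "test")
  dev_mrr <- vapply(seq_along(fitted$checkpoints), function(k) {
    res <- timeslice_queries_ck(fitted, slice, sp$dev, dev_as, k)
    tryCatch(rank_metrics(res)$mrr, lbd_error = function(e) -Inf)
  }, numeric(1))
  best <- which.max(dev_mrr)
  res <- timeslice_queries_ck(fitted, slice, sp$test, test_as, best)
  report <- rank_metrics(res)
  structure(list(report = report, dev_mrr = dev_mrr,
                 selected_epoch = if (!is.null(fitted$checkpoints[[best]]))
                   fitted$checkpoints[[best]]$epoch else NA_integer_,
                 n_dev_queries = length(dev_as),
                 n_test_queries = length(test_as)),
            class = "lbd_timeslice_report")
}

timeslice_queries_ck <- function(fitted, slice, pairs, as_nodes, k) {
  lapply(as_nodes, function(a) {
    golds <- new_partners(pairs, a)
    rk <- rank_query(fitted, slice, a, checkpoint = k)
    grk <- vapply(golds, function(g) tie_adjusted_rank(rk, g), numeric(1))
    query_result(grk[!is.na(grk)], nrow(rk), sum(is.na(grk)))
  })
}

#' @export
print.lbd_timeslice_report <- function(x, ...) {
  cat(sprintf("<lbd_timeslice_report> checkpoint epoch %s selected by dev MRR\n",
              x$selected_epoch))
  print(x$report)
  invisible(x)
}

#' Write a ranking to TSV
#'
#' Columns `rank`, `entity`, `score`, `tie_adjusted_rank` -- the audit dump
#' format of the command-line pipeline.
#'
#' @param ranking an [scored_ranking()].
#' @param path output file.
#' @export
write_ranking <- function(ranking, path) {
  df <- as.data.frame(ranking)
  df$score <- formatC(df$score, format = "g", digits = 10)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
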