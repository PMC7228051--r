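# Synthetic temporal co-occurrence graphs with planted triadic closure.
# The generator emulates the structure of literature co-occurrence graphs:
# a sparse undirected graph with community structure, per-year edge birth
# times, count-valued edge attributes, and post-cutoff links whose log-odds
# increase with the number of pre-cutoff shared neighbours.

#' Synthetic graph configuration
#'
#' @param n_nodes number of entities.
#' @param n_communities number of equally sized communities; edges inside a
#'   community are more likely than between communities, giving the
#'   embeddings second-order structure to exploit.
#' @param years inclusive range of calendar years (length-2 integer).
#' @param cutoff_year last pre-cutoff year; edges born after it are the
#'   "future" links that discovery should predict.
#' @param p_within,p_between pre-cutoff edge probabilities inside / across
#'   communities.
#' @param mean_sent baseline mean of the (shifted Poisson, >= 1) per-year
#'   sentence co-occurrence count. The expected count of an edge scales
#'   with its association strength: up (x1.5) inside communities, down
#'   (x0.5) across them, and up with the edge's pre-cutoff triadic density
#'   (`1 + 0.5 *` shared-neighbour count), with mild gamma
#'   overdispersion. Strongly associated pairs therefore co-occur more
#'   often -- the property that makes the Jaccard index an informative
#'   association rating. Document counts are a binomial thinning of the
#'   sentence counts, keeping `doc <= sent`.
#' @param mean_occ mean per-year solo-mention count of an entity (sentences
#'   mentioning it outside its stored co-occurrences). Occurrence counts in
#'   literature are dominated by mentions that do not co-occur with any one
#'   partner, which keeps the Jaccard index of an edge approximately
#'   proportional to its co-occurrence intensity rather than to the
#'   endpoints' degrees.
#' @param p_post baseline probability that a previously unlinked pair
#'   forms a post-cutoff link when it has no shared neighbours.
#' @param closure_strength nonnegative real controlling how strongly the
#'   pre-cutoff shared neighbours of a pair raise its post-cutoff link
#'   probability. Each shared neighbour `b` of a pair `(a, c)` contributes
#'   its minimum leg Jaccard `min(J(a,b), J(b,c))`, normalised by the mean
#'   edge Jaccard of the slice, to a weighted wedge count; the link
#'   log-odds are `logit(p_post) + closure_strength *` that count. Future
#'   links therefore preferentially close wedges with high-Jaccard legs;
#'   at 0 they are independent of the wedge structure.
#' @param seed integer seed; the graph is a deterministic function of the
#'   configuration.
#' @export
synthetic_config <- function(n_nodes = 300L, n_communities = 6L,
                             years = c(2000L, 2010L), cutoff_year = 2005L,
                             p_within = 0.08, p_between = 0.004,
                             mean_sent = 3, mean_occ = 15, p_post = 1e-4,
                             closure_strength = 4, seed = 1L) {
  cfg <- list(n_nodes = as.integer(n_nodes),
              n_communities = as.integer(n_communities),
              years = as.integer(years), cutoff_year = as.integer(cutoff_year),
              p_within = p_within, p_between = p_between,
              mean_sent = mean_sent, mean_occ = mean_occ, p_post = p_post,
              closure_strength = closure_strength, seed = as.integer(seed))
  if (cfg$n_nodes < 2)
    lbd_stop("lbd_config_error", "synthetic_config: need n_nodes >= 2")
  if (any(c(p_within, p_between, p_post) < 0) ||
      any(c(p_within, p_between, p_post) > 1))
    lbd_stop("lbd_config_error", "synthetic_config: probabilities must be in [0, 1]")
  if (closure_strength < 0)
    lbd_stop("lbd_config_error", "synthetic_config: closure_strength must be >= 0")
  if (cfg$cutoff_year < cfg$years[1] || cfg$cutoff_year >= cfg$years[2])
    lbd_stop("lbd_config_error",
             "synthetic_config: cutoff must lie inside the year range")
  cfg
}

# entity ids E001 ... with a cycling type label
synth_entity_ids <- function(n) {
  types <- c("chemical", "gene", "disease", "mutation", "species")
  list(id = sprintf("E%04d", seq_len(n)),
       type = types[(seq_len(n) - 1L) %% length(types) + 1L])
}

#' Generate a synthetic temporal co-occurrence graph
#'
#' Pre-cutoff edges follow a stochastic-block model with a random birth
#' year in the pre-cutoff range; each edge may recur in later pre-cutoff
#' years. Post-cutoff new edges are drawn with log-odds
#' `logit(p_post) + closure_strength * s(a, c)` where `s` is the
#' Jaccard-weighted shared-neighbour count of the pair in the pre-cutoff
#' slice (see [synthetic_config()]), planting the triadic-closure signal
#' discovery methods are meant to recover: future links preferentially
#' close wedges with high-Jaccard legs. Per-entity occurrence counts and
#' corpus totals are derived so that all graph invariants hold by
#' construction.
#'
#' @param config a [synthetic_config()].
#' @return An [lbd_graph()].
#' @export
generate_graph <- function(config = synthetic_config()) {
  cfg <- config
  with_lbd_seed(cfg$seed, {
    n <- cfg$n_nodes
    ent <- synth_entity_ids(n)
    comm <- rep(seq_len(cfg$n_communities), length.out = n)
    pre_years <- cfg$years[1]:cfg$cutoff_year
    post_years <- (cfg$cutoff_year + 1L):cfg$years[2]
    all_years <- cfg$years[1]:cfg$years[2]

    pr <- utils::combn(n, 2)
    same <- comm[pr[1, ]] == comm[pr[2, ]]
    p_edge <- ifelse(same, cfg$p_within, cfg$p_between)
    pre_sel <- stats::runif(ncol(pr)) < p_edge
    pre_i <- pr[1, pre_sel]; pre_j <- pr[2, pre_sel]
    if (!length(pre_i))
      lbd_stop("lbd_data_error", "generate_graph: no edges generated; raise p_within")

    # shared-neighbour counts in the pre-cutoff edge set, for edge strength
    pre_adj <- matrix(0L, n, n)
    pre_wedge_of <- function(i, j) {
      vapply(seq_along(i), function(k)
        sum(pre_adj[i[k], ] * pre_adj[j[k], ]), numeric(1))
    }
    draw_obs <- function(i, j, years_pool, recur_p = 0.4) {
      # each edge is observed in its birth year and, independently, in each
      # later year of the pool; the expected count scales with association
      # strength (community co-membership and triadic density) plus mild
      # gamma overdispersion, tying co-occurrence intensity to structure
      birth <- years_pool[sample.int(length(years_pool), length(i),
                                     replace = TRUE)]
      fac <- ifelse(comm[i] == comm[j], 1.5, 0.5) *
        (1 + 0.5 * pre_wedge_of(i, j)) *
        stats::rgamma(length(i), shape = 4, rate = 4)
      rows <- lapply(seq_along(i), function(k) {
        ys <- years_pool[years_pool > birth[k]]
        ys <- c(birth[k], ys[stats::runif(length(ys)) < recur_p])
        data.frame(entity1 = ent$id[i[k]], entity2 = ent$id[j[k]], year = ys,
                   mean_count = cfg$mean_sent * fac[k],
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }
    add_counts <- function(obs) {
      obs$sent_count <- 1L + stats::rpois(nrow(obs),
                                          pmax(obs$mean_count - 1, 0))
      obs$doc_count <- 1L + stats::rbinom(nrow(obs), obs$sent_count - 1L, 0.7)
      obs$mean_count <- NULL
      obs
    }
    # per-(entity, year) occurrence counts covering all incident edge
    # co-occurrences that year plus solo mentions
    node_counts_for <- function(obs, years) {
      grid <- expand.grid(entity = ent$id, year = years,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      base <- integer(nrow(grid))
      if (!is.null(obs) && nrow(obs)) {
        inc <- rowsum(c(obs$sent_count, obs$sent_count),
                      paste(c(obs$entity1, obs$entity2),
                            c(obs$year, obs$year), sep = "\r"))
        hit <- match(rownames(inc), paste(grid$entity, grid$year, sep = "\r"))
        base[hit[!is.na(hit)]] <- as.integer(inc[!is.na(hit), 1])
      }
      grid$sent_occurrence_count <- base + 1L +
        stats::rpois(nrow(grid), cfg$mean_occ)
      grid
    }

    pre_adj[cbind(pre_i, pre_j)] <- 1L
    pre_adj[cbind(pre_j, pre_i)] <- 1L
    obs_pre <- add_counts(draw_obs(pre_i, pre_j, pre_years))
    grid_pre <- node_counts_for(obs_pre, pre_years)

    # pre-cutoff slice Jaccard per edge, from the aggregated counts
    esum <- rowsum(obs_pre$sent_count, paste(obs_pre$entity1,
                                             obs_pre$entity2, sep = "\r"))
    n_x <- rowsum(grid_pre$sent_occurrence_count, grid_pre$entity)[, 1]
    ep <- do.call(rbind, strsplit(rownames(esum), "\r", fixed = TRUE))
    jac <- esum[, 1] / (n_x[ep[, 1]] + n_x[ep[, 2]] - esum[, 1])
    Jm <- matrix(0, n, n)
    ei <- match(ep[, 1], ent$id); ej <- match(ep[, 2], ent$id)
    Jm[cbind(ei, ej)] <- jac; Jm[cbind(ej, ei)] <- jac
    mean_j <- mean(jac)

    # Jaccard-weighted wedge statistic for candidate (non-edge) pairs
    Adj <- (Jm > 0) + 0
    W2 <- Adj %*% Adj
    cand <- which(!pre_sel & W2[cbind(pr[1, ], pr[2, ])] > 0)
    s_stat <- numeric(ncol(pr))
    for (k in cand) {
      i <- pr[1, k]; j <- pr[2, k]
      b <- which(Adj[i, ] > 0 & Adj[j, ] > 0)
      s_stat[k] <- sum(pmin(Jm[i, b], Jm[j, b])) / mean_j
    }
    eta <- stats::qlogis(cfg$p_post) + cfg$closure_strength * s_stat
    post_sel <- !pre_sel & stats::runif(ncol(pr)) < stats::plogis(eta)
    obs_post <- if (any(post_sel))
      add_counts(draw_obs(pr[1, post_sel], pr[2, post_sel], post_years,
                          recur_p = 0.2))
    else NULL
    grid_post <- node_counts_for(obs_post, post_years)

    obs <- rbind(obs_pre, obs_post)
    grid <- rbind(grid_pre, grid_post)
    grid$entity_type <- ent$type[match(grid$entity, ent$id)]

    tot <- rowsum(grid$sent_occurrence_count, grid$year)
    totals <- data.frame(year = as.integer(rownames(tot)),
                         total_sentences = as.integer(tot[, 1]),
                         total_documents = as.integer(ceiling(tot[, 1] * 0.6)))

    lbd_graph(edges = obs[, c("entity1", "entity2", "year",
                              "sent_count", "doc_count")],
              nodes = grid[, c("entity", "entity_type", "year",
                               "sent_occurrence_count")],
              totals = totals)
  })
}

#' Derive discovery cases from a synthetic graph
#'
#' Each case is built from a post-cutoff *new* link (A, C) that closes at
#' least one pre-cutoff wedge, so its gold is guaranteed to be inside the
#' candidate generator's output: for open discovery the gold is C itself
#' (C is at distance exactly 2 from A pre-cutoff); for closed discovery the
#' gold is the common neighbour B with the strongest legs (largest minimum
#' leg Jaccard).
#'
#' @param graph an [lbd_graph()].
#' @param cutoff_year pre-cutoff slice year.
#' @param mode `"open"` or `"closed"`.
#' @param k number of cases requested; if fewer eligible links exist all
#'   are returned with a warning.
#' @param seed integer sampling seed.
#' @param min_candidates minimum number of B candidates a new link must
#'   have to be eligible (ranking a single candidate is degenerate;
#'   protocols that compare against the random-expectation rank should
#'   require a few).
#' @return list of [discovery_case()] records.
#' @export
derive_cases <- function(graph, cutoff_year, mode = c("open", "closed"),
                         k = 20L, seed = 1L, min_candidates = 1L) {
  mode <- match.arg(mode)
  slice <- graph_slice(graph, cutoff_year)
  obs <- graph$observations
  pre <- unique(paste(obs$u, obs$v, sep = "\r")[obs$year <= cutoff_year])
  post <- unique(paste(obs$u, obs$v, sep = "\r")[obs$year > cutoff_year])
  new_keys <- setdiff(post, pre)
  if (!length(new_keys))
    lbd_stop("lbd_data_error", "derive_cases: no new post-cutoff links")
  parts <- do.call(rbind, strsplit(sort(new_keys), "\r", fixed = TRUE))
  eligible <- vapply(seq_len(nrow(parts)), function(i)
    length(b_candidates(slice, parts[i, 1], parts[i, 2])) >= max(1L, min_candidates),
    logical(1))
  parts <- parts[eligible, , drop = FALSE]
  if (!nrow(parts))
    lbd_stop("lbd_data_error",
             "derive_cases: no new link closes a pre-cutoff wedge")
  if (nrow(parts) < k) {
    warning(sprintf("derive_cases: only %d eligible case(s), requested %d",
                    nrow(parts), k))
    k <- nrow(parts)
  }
  sel <- with_lbd_seed(seed, sample.int(nrow(parts), k))
  lapply(sel, function(i) {
    # both orientations are valid queries; take the lexicographic source
    a <- parts[i, 1]; c_id <- parts[i, 2]
    if (mode == "open") {
      discovery_case(a, gold = c_id, cutoff_year = cutoff_year)
    } else {
      bs <- b_candidates(slice, a, c_id)
      leg <- vapply(bs, function(b)
        min(metric_jaccard(edge_contingency(slice, a, b)),
            metric_jaccard(edge_contingency(slice, b, c_id))), numeric(1))
      discovery_case(a, gold = bs[which.max(leg)], cutoff_year = cutoff_year,
                     c = c_id)
    }
  })
}

#' Synthetic presets
#'
#' Named bundles of generator settings used by the command-line interface:
#' `tiny` (60 nodes, for smoke tests), `small` (150), `medium` (300).
#'
#' @param preset preset name.
#' @param seed integer seed.
#' @return A [synthetic_config()].
#' @export
synthetic_preset <- function(preset = c("tiny", "small", "medium"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
         tiny = synthetic_config(n_nodes = 60L, n_communities = 4L,
                                 p_within = 0.3, p_between = 0.02,
                                 p_post = 1e-3, closure_strength = 6,
                                 seed = seed),
         small = synthetic_config(n_nodes = 150L, n_communities = 5L,
                                  p_within = 0.15, p_between = 0.008,
                                  p_post = 5e-4, closure_strength = 5,
                                  seed = seed),
         medium = synthetic_config(seed = seed))
}
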