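#' @keywords internal
"_PACKAGE"

# Classed conditions used across the package: lbd_config_error (bad
# configuration / arguments), lbd_data_error (malformed or inconsistent
# input data), lbd_undefined_score (a metric is undefined for the given
# contingency counts).
lbd_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "lbd_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Temporal co-occurrence graph
#'
#' Builds a validated temporal co-occurrence graph from tabular records.
#' Nodes are biomedical entities (genes, chemicals, diseases, ...); an edge
#' observation records that two entities co-occurred in sentences of the
#' literature published in a given year.
#'
#' Edges are undirected: endpoint pairs are canonicalised to `u < v`
#' (lexicographic) and duplicate `(u, v, year)` observations are summed.
#' Entities that appear only in `nodes` (degree zero) are retained so that
#' occurrence statistics remain defined for them.
#'
#' @param edges data.frame with columns `entity1`, `entity2`, `year`,
#'   `sent_count` (sentence co-occurrences that year), `doc_count`
#'   (document co-occurrences, `<= sent_count`).
#' @param nodes data.frame with columns `entity`, `entity_type`, `year`,
#'   `sent_occurrence_count` (sentences mentioning the entity that year).
#' @param totals data.frame with columns `year`, `total_sentences`,
#'   `total_documents` (corpus-wide totals per year).
#' @return An object of class `lbd_graph`.
#' @seealso [read_graph_tsv()], [graph_slice()], [generate_graph()]
#' @export
lbd_graph <- function(edges, nodes, totals) {
  edges  <- as.data.frame(edges,  stringsAsFactors = FALSE)
  nodes  <- as.data.frame(nodes,  stringsAsFactors = FALSE)
  totals <- as.data.frame(totals, stringsAsFactors = FALSE)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      lbd_stop("lbd_data_error", "%s records missing column(s): %s",
               what, paste(miss, collapse = ", "))
  }
  need(edges,  c("entity1", "entity2", "year", "sent_count", "doc_count"), "edge")
  need(nodes,  c("entity", "entity_type", "year", "sent_occurrence_count"), "node")
  need(totals, c("year", "total_sentences", "total_documents"), "totals")

  edges$entity1 <- as.character(edges$entity1)
  edges$entity2 <- as.character(edges$entity2)
  for (col in c("year", "sent_count", "doc_count")) {
    edges[[col]] <- as.integer(edges[[col]])
    if (anyNA(edges[[col]]))
      lbd_stop("lbd_data_error", "edge row %d: non-integer '%s'",
               which(is.na(edges[[col]]))[1], col)
  }
  nodes$entity <- as.character(nodes$entity)
  nodes$entity_type <- as.character(nodes$entity_type)
  nodes$year <- as.integer(nodes$year)
  nodes$sent_occurrence_count <- as.integer(nodes$sent_occurrence_count)
  totals[] <- lapply(totals, as.integer)

  if (any(edges$entity1 == edges$entity2))
    lbd_stop("lbd_data_error", "edge row %d: self loop '%s'",
             which(edges$entity1 == edges$entity2)[1], edges$entity1[1])
  if (any(edges$sent_count < 1))
    lbd_stop("lbd_data_error", "edge row %d: sent_count < 1",
             which(edges$sent_count < 1)[1])
  bad <- edges$doc_count > edges$sent_count | edges$doc_count < 0
  if (any(bad))
    lbd_stop("lbd_data_error",
             "edge row %d: doc_count outside [0, sent_count]", which(bad)[1])

  # canonicalise u < v, sum duplicates
  swap <- edges$entity1 > edges$entity2
  u <- ifelse(swap, edges$entity2, edges$entity1)
  v <- ifelse(swap, edges$entity1, edges$entity2)
  key <- paste(u, v, edges$year, sep = "\r")
  agg <- rowsum(cbind(sent = edges$sent_count, doc = edges$doc_count), key)
  parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  obs <- data.frame(u = parts[, 1], v = parts[, 2],
                    year = as.integer(parts[, 3]),
                    sent_count = as.integer(agg[, "sent"]),
                    doc_count = as.integer(agg[, "doc"]),
                    stringsAsFactors = FALSE)
  obs <- obs[order(obs$u, obs$v, obs$year), , drop = FALSE]
  rownames(obs) <- NULL

  # sum duplicate node/(entity, year) rows
  nkey <- paste(nodes$entity, nodes$year, sep = "\r")
  nagg <- rowsum(nodes$sent_occurrence_count, nkey)
  nparts <- do.call(rbind, strsplit(rownames(nagg), "\r", fixed = TRUE))
  etype <- tapply(nodes$entity_type, nodes$entity, function(x) x[[1]])
  node_counts <- data.frame(entity = nparts[, 1],
                            year = as.integer(nparts[, 2]),
                            sent_occurrence_count = as.integer(nagg[, 1]),
                            stringsAsFactors = FALSE)
  node_counts <- node_counts[order(node_counts$entity, node_counts$year), ]
  rownames(node_counts) <- NULL

  entities <- data.frame(entity = names(etype),
                         entity_type = unname(etype),
                         stringsAsFactors = FALSE)

  known <- entities$entity
  missing_ep <- setdiff(unique(c(obs$u, obs$v)), known)
  if (length(missing_ep))
    lbd_stop("lbd_data_error",
             "edge endpoint(s) absent from node records: %s",
             paste(utils::head(missing_ep, 5), collapse = ", "))

  tot <- rowsum(cbind(N = totals$total_sentences, D = totals$total_documents),
                totals$year)
  totals <- data.frame(year = as.integer(rownames(tot)),
                       total_sentences = as.integer(tot[, "N"]),
                       total_documents = as.integer(tot[, "D"]))
  totals <- totals[order(totals$year), ]
  rownames(totals) <- NULL

  g <- structure(list(entities = entities, observations = obs,
                      node_counts = node_counts, totals = totals),
                 class = "lbd_graph")
  validate_lbd_graph(g)
  g
}

validate_lbd_graph <- function(g) {
  obs <- g$observations
  if (!nrow(obs)) return(invisible(g))
  # per-(entity, year) occurrence lookups; an edge can only be observed in a
  # year where both endpoints have occurrence counts at least as large.
  nk <- paste(g$node_counts$entity, g$node_counts$year, sep = "\r")
  nc <- stats::setNames(g$node_counts$sent_occurrence_count, nk)
  cu <- nc[paste(obs$u, obs$year, sep = "\r")]
  cv <- nc[paste(obs$v, obs$year, sep = "\r")]
  bad <- is.na(cu) | is.na(cv) | obs$sent_count > pmin(cu, cv)
  if (any(bad))
    lbd_stop("lbd_data_error",
             "edge (%s, %s, %d): sent_count %d exceeds an endpoint's occurrence count for that year",
             obs$u[which(bad)[1]], obs$v[which(bad)[1]],
             obs$year[which(bad)[1]], obs$sent_count[which(bad)[1]])
  Ny <- stats::setNames(g$totals$total_sentences, g$totals$year)
  ny <- Ny[as.character(g$node_counts$year)]
  if (anyNA(ny) || any(g$node_counts$sent_occurrence_count > ny))
    lbd_stop("lbd_data_error",
             "node occurrence count exceeds corpus total for its year")
  invisible(g)
}

#' @export
print.lbd_graph <- function(x, ...) {
  yrs <- range(c(x$observations$year, x$totals$year))
  cat(sprintf("<lbd_graph> %d entities, %d edge observations (%d unique pairs), years %d-%d\n",
              nrow(x$entities), nrow(x$observations),
              length(unique(paste(x$observations$u, x$observations$v))),
              yrs[1], yrs[2]))
  invisible(x)
}

#' Aggregate a temporal graph up to a cutoff year
#'
#' Retains exactly the edge observations with `year <= cutoff_year` and sums
#' counts additively over the retained years, yielding the static weighted
#' graph visible to a discovery method at that point in time. Per-entity
#' occurrence counts and corpus totals are aggregated the same way.
#'
#' @param graph an [lbd_graph()].
#' @param cutoff_year integer calendar year (inclusive).
#' @return An object of class `lbd_slice` with aggregated edges, per-entity
#'   sentence occurrence counts, corpus totals `N` (sentences) and `D`
#'   (documents), and an adjacency index.
#' @export
graph_slice <- function(graph, cutoff_year) {
  stopifnot(inherits(graph, "lbd_graph"))
  cutoff_year <- as.integer(cutoff_year)
  obs <- graph$observations[graph$observations$year <= cutoff_year, , drop = FALSE]
  if (nrow(obs)) {
    key <- paste(obs$u, obs$v, sep = "\r")
    agg <- rowsum(cbind(sent = obs$sent_count, doc = obs$doc_count), key)
    parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
    edges <- data.frame(u = parts[, 1], v = parts[, 2],
                        sent_count = as.integer(agg[, "sent"]),
                        doc_count = as.integer(agg[, "doc"]),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$u, edges$v), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(u = character(), v = character(),
                        sent_count = integer(), doc_count = integer(),
                        stringsAsFactors = FALSE)
  }
  ncs <- graph$node_counts[graph$node_counts$year <= cutoff_year, , drop = FALSE]
  n_x <- stats::setNames(rep(0L, nrow(graph$entities)), graph$entities$entity)
  if (nrow(ncs)) {
    s <- rowsum(ncs$sent_occurrence_count, ncs$entity)
    n_x[rownames(s)] <- as.integer(s[, 1])
  }
  tt <- graph$totals[graph$totals$year <= cutoff_year, , drop = FALSE]
  adj <- new.env(parent = emptyenv(), hash = TRUE)
  if (nrow(edges)) {
    nb <- split(c(edges$v, edges$u), c(edges$u, edges$v))
    for (id in names(nb)) assign(id, sort(unique(nb[[id]])), envir = adj)
  }
  ekey <- new.env(parent = emptyenv(), hash = TRUE)
  if (nrow(edges))
    for (i in seq_len(nrow(edges)))
      assign(paste(edges$u[i], edges$v[i], sep = "\r"),
             c(sent = edges$sent_count[i], doc = edges$doc_count[i]),
             envir = ekey)
  structure(list(cutoff_year = cutoff_year, edges = edges, n_x = n_x,
                 N = sum(tt$total_sentences), D = sum(tt$total_documents),
                 entities = graph$entities, adj = adj, ekey = ekey),
            class = "lbd_slice")
}

#' @export
print.lbd_slice <- function(x, ...) {
  cat(sprintf("<lbd_slice> cutoff %d: %d entities, %d edges, N = %d sentences\n",
              x$cutoff_year, nrow(x$entities), nrow(x$edges), x$N))
  invisible(x)
}

slice_has_entity <- function(slice, id) id %in% slice$entities$entity

#' Neighbours of an entity in a slice
#'
#' @param slice an [graph_slice()] result.
#' @param id entity identifier.
#' @return Character vector of adjacent entity ids (sorted).
#' @export
slice_neighbors <- function(slice, id) {
  if (!slice_has_entity(slice, id))
    lbd_stop("lbd_data_error", "unknown entity '%s'", id)
  if (exists(id, envir = slice$adj, inherits = FALSE))
    get(id, envir = slice$adj) else character()
}

#' Linking-term (B) candidates for a closed discovery query
#'
#' The B candidates for a source/target pair are the common neighbours of
#' `a` and `c` in the slice, excluding `a` and `c` themselves. A direct
#' `a`--`c` edge does not disqualify a common neighbour.
#'
#' @inheritParams slice_neighbors
#' @param a,c entity ids of the source (A) and target (C) terms.
#' @return Character vector of candidate B ids (sorted).
#' @export
b_candidates <- function(slice, a, c) {
  nb_a <- slice_neighbors(slice, a)
  nb_c <- slice_neighbors(slice, c)
  setdiff(intersect(nb_a, nb_c), c(a, c))
}

#' Target-term (C) candidates for an open discovery query
#'
#' Nodes at shortest-path distance exactly two from `a`: reachable through
#' at least one intermediate B but not directly linked to `a`. Direct
#' neighbours are excluded because an existing link is not a discovery.
#'
#' @inheritParams b_candidates
#' @return Character vector of candidate C ids (sorted).
#' @export
c_candidates <- function(slice, a) {
  nb_a <- slice_neighbors(slice, a)
  if (!length(nb_a)) return(character())
  two_hop <- unique(unlist(lapply(nb_a, function(b) slice_neighbors(slice, b)),
                           use.names = FALSE))
  sort(setdiff(two_hop, c(a, nb_a)))
}

#' Split a temporal graph at a cutoff for time-sliced evaluation
#'
#' Training data is the slice up to `cutoff_year`. The evaluation pool is
#' the set of *new* links -- unordered pairs first observed after the cutoff
#' that were never observed before it -- randomly partitioned into
#' development and test sets.
#'
#' @inheritParams graph_slice
#' @param dev_fraction fraction of new post-cutoff links assigned to the
#'   development set, in (0, 1).
#' @param seed integer seed making the partition reproducible.
#' @return list with elements `train` (an `lbd_slice`), `dev` and `test`
#'   (data.frames of canonical `u`, `v` pairs).
#' @export
timeslice_split <- function(graph, cutoff_year, dev_fraction = 0.5, seed = 1L) {
  stopifnot(inherits(graph, "lbd_graph"))
  if (!(dev_fraction > 0 && dev_fraction < 1))
    lbd_stop("lbd_config_error", "dev_fraction must be in (0, 1)")
  obs <- graph$observations
  pre  <- unique(paste(obs$u, obs$v, sep = "\r")[obs$year <= cutoff_year])
  post <- unique(paste(obs$u, obs$v, sep = "\r")[obs$year > cutoff_year])
  new_links <- setdiff(post, pre)
  if (!length(new_links))
    lbd_stop("lbd_data_error", "no new links after cutoff %d", cutoff_year)
  new_links <- sort(new_links)
  n_dev <- round(dev_fraction * length(new_links))
  n_dev <- max(min(n_dev, length(new_links) - 1L), 1L)
  perm <- with_lbd_seed(seed, sample.int(length(new_links)))
  dev_keys <- new_links[perm[seq_len(n_dev)]]
  test_keys <- new_links[perm[-seq_len(n_dev)]]
  unkey <- function(k) {
    if (!length(k)) return(data.frame(u = character(), v = character()))
    p <- do.call(rbind, strsplit(k, "\r", fixed = TRUE))
    data.frame(u = p[, 1], v = p[, 2], stringsAsFactors = FALSE)
  }
  list(train = graph_slice(graph, cutoff_year),
       dev = unkey(sort(dev_keys)), test = unkey(sort(test_keys)))
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
with_lbd_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
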