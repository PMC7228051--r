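# Plain-text interchange formats. All files are UTF-8, tab-separated with a
# header row; the case file is a flat key-value format with blank-line
# separated records.

read_tsv_checked <- function(path, cols, int_cols, what) {
  if (!file.exists(path))
    lbd_stop("lbd_data_error", "%s file not found: %s", what, path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  miss <- setdiff(cols, names(df))
  if (length(miss))
    lbd_stop("lbd_data_error", "%s file %s: missing column(s) %s",
             what, path, paste(miss, collapse = ", "))
  for (col in int_cols) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (anyNA(v))
      # +1 for the header row so the number matches the file line
      lbd_stop("lbd_data_error", "%s file %s line %d: malformed '%s' value '%s'",
               what, path, which(is.na(v))[1] + 1L, col,
               df[[col]][which(is.na(v))[1]])
    df[[col]] <- v
  }
  df
}

#' Read a temporal graph from its three TSV files
#'
#' @param edge_path TSV with header
#'   `entity1  entity2  year  sent_count  doc_count`.
#' @param node_path TSV with header
#'   `entity  entity_type  year  sent_occurrence_count`.
#' @param totals_path TSV with header `year  total_sentences  total_documents`.
#' @return An [lbd_graph()].
#' @export
read_graph_tsv <- function(edge_path, node_path, totals_path) {
  edges <- read_tsv_checked(edge_path,
                            c("entity1", "entity2", "year", "sent_count", "doc_count"),
                            c("year", "sent_count", "doc_count"), "edge")
  nodes <- read_tsv_checked(node_path,
                            c("entity", "entity_type", "year", "sent_occurrence_count"),
                            c("year", "sent_occurrence_count"), "node")
  totals <- read_tsv_checked(totals_path,
                             c("year", "total_sentences", "total_documents"),
                             c("year", "total_sentences", "total_documents"),
                             "totals")
  lbd_graph(edges, nodes, totals)
}

#' Write a temporal graph to the three TSV files
#'
#' @param graph an [lbd_graph()].
#' @param dir output directory (created if absent).
#' @param prefix filename prefix; files are `<prefix>edges.tsv`,
#'   `<prefix>nodes.tsv`, `<prefix>totals.tsv`.
#' @return Invisibly, the three paths.
#' @export
write_graph_tsv <- function(graph, dir, prefix = "") {
  stopifnot(inherits(graph, "lbd_graph"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("edges.tsv", "nodes.tsv", "totals.tsv")))
  edges <- graph$observations
  names(edges)[1:2] <- c("entity1", "entity2")
  nodes <- merge(graph$node_counts, graph$entities, by = "entity", sort = TRUE)
  nodes <- nodes[order(nodes$entity, nodes$year),
                 c("entity", "entity_type", "year", "sent_occurrence_count")]
  wr <- function(df, p) utils::write.table(df, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE, fileEncoding = "UTF-8")
  wr(edges, paths[1]); wr(nodes, paths[2]); wr(graph$totals, paths[3])
  invisible(paths)
}

#' Discovery cases
#'
#' A discovery case is one evaluation unit: for closed discovery an
#' `(a, c, gold B, cutoff_year)` quadruple, for open discovery an
#' `(a, gold C, cutoff_year)` triple (the `c` field is absent).
#'
#' @param a,c,gold entity ids; `c = NA` for an open case.
#' @param cutoff_year last literature year available to the method.
#' @return A one-row data.frame of class `lbd_case`.
#' @export
discovery_case <- function(a, gold, cutoff_year, c = NA_character_) {
  if (!is.na(c) && (a == c || gold %in% c(a, c)))
    lbd_stop("lbd_data_error",
             "closed case requires a != c and gold outside {a, c}")
  structure(data.frame(a = a, c = c, gold = gold,
                       cutoff_year = as.integer(cutoff_year),
                       stringsAsFactors = FALSE),
            class = c("lbd_case", "data.frame"))
}

case_mode <- function(case) if (is.na(case$c)) "open" else "closed"

#' Read / write discovery case files
#'
#' The case file is a flat key-value text format: one `key: value` line per
#' field (`a`, `c`, `gold`, `cutoff_year`), records separated by blank
#' lines; `c` is omitted or empty for open-discovery cases.
#'
#' @param path file path.
#' @return `read_cases`: a list of [discovery_case()] records.
#' @export
read_cases <- function(path) {
  if (!file.exists(path))
    lbd_stop("lbd_data_error", "case file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  out <- list()
  for (bl in blocks) {
    bl <- bl[nzchar(trimws(bl))]
    if (!length(bl)) next
    kv <- regmatches(bl, regexec("^([a-z_]+)\\s*:\\s*(.*)$", bl))
    bad <- vapply(kv, length, 1L) != 3L
    if (any(bad))
      lbd_stop("lbd_data_error", "case file %s: malformed line '%s'",
               path, bl[which(bad)[1]])
    rec <- stats::setNames(vapply(kv, `[`, "", 3L), vapply(kv, `[`, "", 2L))
    for (k in c("a", "gold", "cutoff_year"))
      if (!k %in% names(rec) || !nzchar(rec[[k]]))
        lbd_stop("lbd_data_error", "case file %s: record missing '%s'", path, k)
    cc <- if ("c" %in% names(rec) && nzchar(rec[["c"]])) rec[["c"]] else NA_character_
    out[[length(out) + 1L]] <- discovery_case(rec[["a"]], rec[["gold"]],
                                              as.integer(rec[["cutoff_year"]]),
                                              c = cc)
  }
  out
}

#' @rdname read_cases
#' @param cases list of [discovery_case()] records.
#' @export
write_cases <- function(cases, path) {
  fmt <- function(cs) {
    l <- c(sprintf("a: %s", cs$a),
           if (!is.na(cs$c)) sprintf("c: %s", cs$c),
           sprintf("gold: %s", cs$gold),
           sprintf("cutoff_year: %d", cs$cutoff_year))
    paste(l, collapse = "\n")
  }
  writeLines(paste(vapply(cases, fmt, ""), collapse = "\n\n"), path,
             useBytes = TRUE)
  invisible(path)
}
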