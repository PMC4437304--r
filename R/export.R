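#' Export a network to SIF, GraphML or JSON
#'
#' * `sif` — one line per edge, relation token `ppi` for undirected PPI
#'   edges and `pathway:<id>` for directed pathway edges; isolated nodes are
#'   written as single-column lines.
#' * `graphml` — full node/edge attributes (list-valued attributes are
#'   pipe-joined), via igraph.
#' * `json` (alias `json-graph`) — the canonical lossless round-trip
#'   format; read back with [read_network_json()].
#'
#' @param net A [meta_network()] or an igraph object (e.g. from
#'   [cooccurrence_network()]).
#' @param path Output path.
#' @param format `"sif"`, `"graphml"`, `"json"` or `"json-graph"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("json", "sif", "graphml",
                                                 "json-graph")) {
  format <- match.arg(format)
  if (format == "json-graph") format <- "json"
  if (inherits(net, "igraph")) net <- meta_from_igraph(net)
  if (!inherits(net, "meta_network")) {
    litnet_stop("unsupported network object of class %s",
                paste(class(net), collapse = "/"))
  }
  switch(format,
    sif = write_sif(net, path),
    graphml = write_graphml(net, path),
    json = write_network_json(net, path))
  invisible(path)
}

# Generic igraph (co-occurrence networks) -> meta_network-shaped container
# so one set of writers serves both.
meta_from_igraph <- function(g) {
  nodes <- igraph::as_data_frame(g, what = "vertices")
  names(nodes)[names(nodes) == "name"] <- "id"
  edges <- igraph::as_data_frame(g, what = "edges")
  if (nrow(edges) > 0) {
    edges$kind <- "cooccurrence"
  } else {
    edges$kind <- character(0)
  }
  net <- meta_network(nodes["id"], edges[c("from", "to", "kind")])
  for (col in setdiff(names(nodes), c("id"))) net$nodes[[col]] <- nodes[[col]]
  for (col in setdiff(names(edges), c("from", "to", "kind"))) {
    net$edges[[col]] <- edges[[col]]
  }
  net
}

sif_relation <- function(edges) {
  ifelse(edges$kind == "pathway-directed",
         paste0("pathway:", edges$pathway_id),
         ifelse(edges$kind == "ppi-undirected", "ppi", edges$kind))
}

write_sif <- function(net, path) {
  lines <- character(0)
  if (nrow(net$edges) > 0) {
    lines <- paste(net$edges$from, sif_relation(net$edges), net$edges$to,
                   sep = "\t")
  }
  isolated <- setdiff(net$nodes$id, c(net$edges$from, net$edges$to))
  lines <- c(lines, isolated)
  writeLines(lines, path)
}

collapse_attr <- function(x) {
  vapply(x, function(v) paste(v, collapse = "|"), character(1))
}

as_igraph_meta <- function(net) {
  nodes <- net$nodes
  for (col in names(nodes)) {
    if (is.list(nodes[[col]])) nodes[[col]] <- collapse_attr(nodes[[col]])
  }
  names(nodes)[names(nodes) == "id"] <- "name"
  edges <- net$edges
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

write_graphml <- function(net, path) {
  g <- as_igraph_meta(net)
  igraph::write_graph(g, path, format = "graphml")
}

write_network_json <- function(net, path) {
  nodes <- lapply(seq_len(nrow(net$nodes)), function(i) {
    row <- net$nodes[i, , drop = FALSE]
    out <- list(id = row$id)
    for (col in setdiff(names(net$nodes), "id")) {
      v <- if (is.list(net$nodes[[col]])) net$nodes[[col]][[i]]
           else net$nodes[[col]][[i]]
      if (is.list(net$nodes[[col]])) {
        out[[col]] <- as.list(v)
      } else if (!is.na(v)) {
        out[[col]] <- v
      }
    }
    out
  })
  edges <- lapply(seq_len(nrow(net$edges)), function(i) {
    out <- list()
    for (col in names(net$edges)) {
      v <- net$edges[[col]][[i]]
      if (!is.na(v)) out[[col]] <- v
    }
    out
  })
  doc <- list(format = "litnet-network", version = 1L,
              nodes = nodes, edges = edges)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
}

#' Read a network back from the canonical JSON export
#'
#' @param path A file written by [export_network()] with `format = "json"`.
#' @return A [meta_network()].
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "litnet-network")) {
    litnet_stop("%s is not a litnet network JSON document", path)
  }
  n <- length(doc$nodes)
  nodes <- data.frame(
    id = vapply(doc$nodes, function(x) x$id, character(1)),
    level = vapply(doc$nodes, function(x) {
      if (is.null(x$level)) NA_integer_ else as.integer(x$level)
    }, integer(1)),
    stringsAsFactors = FALSE)
  nodes$compartments <- lapply(doc$nodes, function(x) {
    as.character(unlist(x$compartments))
  })
  nodes$pathway_ids <- lapply(doc$nodes, function(x) {
    as.character(unlist(x$pathway_ids))
  })
  nodes$expr_value <- vapply(doc$nodes, function(x) {
    if (is.null(x$expr_value)) NA_real_ else as.numeric(x$expr_value)
  }, numeric(1))
  nodes$expr_direction <- vapply(doc$nodes, function(x) {
    if (is.null(x$expr_direction)) NA_character_
    else as.character(x$expr_direction)
  }, character(1))
  m <- length(doc$edges)
  grab <- function(field, default, as_fun) {
    vapply(doc$edges, function(x) {
      if (is.null(x[[field]])) default else as_fun(x[[field]])
    }, default)
  }
  edges <- data.frame(
    from = vapply(doc$edges, function(x) x$from, character(1)),
    to = vapply(doc$edges, function(x) x$to, character(1)),
    kind = vapply(doc$edges, function(x) x$kind, character(1)),
    confidence = grab("confidence", NA_real_, as.numeric),
    confidence_class = grab("confidence_class", NA_character_, as.character),
    pathway_id = grab("pathway_id", NA_character_, as.character),
    stringsAsFactors = FALSE)
  if (m == 0) {
    edges <- data.frame(from = character(0), to = character(0),
                        kind = character(0), confidence = numeric(0),
                        confidence_class = character(0),
                        pathway_id = character(0), stringsAsFactors = FALSE)
  }
  meta_network(nodes, edges)
}
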