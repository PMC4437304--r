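#' Co-authorship graph
#'
#' Nodes are author keys — surname plus initials exactly as stored, with no
#' disambiguation — and each paper contributes one unit of weight to every
#' unordered pair among its author list. The node attribute `n_papers`
#' counts the papers an author appears on within the scope.
#'
#' @param corpus An [annotated_corpus()].
#' @param scope_ids Optional abstract ids restricting the scope.
#' @return An object of class `coauthor_graph` with elements `nodes`
#'   (`author`, `n_papers`) and `edges` (`author_a`, `author_b`, `weight`).
#' @export
build_coauthor_graph <- function(corpus, scope_ids = NULL) {
  ab <- corpus$abstracts
  if (!is.null(scope_ids)) ab <- ab[ab$abstract_id %in% scope_ids, , drop = FALSE]
  node_tab <- list()
  edge_tab <- list()
  for (i in seq_len(nrow(ab))) {
    au <- ab$authors[[i]]
    if (nrow(au) == 0) next
    keys <- unique(trimws(paste(au$surname, au$initials)))
    node_tab[[length(node_tab) + 1]] <- keys
    if (length(keys) >= 2) {
      pairs <- utils::combn(sort(keys), 2)
      edge_tab[[length(edge_tab) + 1]] <- data.frame(
        author_a = pairs[1, ], author_b = pairs[2, ],
        stringsAsFactors = FALSE)
    }
  }
  all_nodes <- unlist(node_tab, use.names = FALSE)
  nodes <- data.frame(author = character(0), n_papers = integer(0),
                      stringsAsFactors = FALSE)
  if (length(all_nodes) > 0) {
    tab <- table(all_nodes)
    nodes <- data.frame(author = names(tab), n_papers = as.integer(tab),
                        stringsAsFactors = FALSE)
    nodes <- nodes[order(nodes$author), , drop = FALSE]
  }
  edges <- data.frame(author_a = character(0), author_b = character(0),
                      weight = integer(0), stringsAsFactors = FALSE)
  if (length(edge_tab) > 0) {
    e <- do.call(rbind, edge_tab)
    key <- paste(e$author_a, e$author_b, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    edges <- data.frame(author_a = vapply(parts, `[[`, character(1), 1),
                        author_b = vapply(parts, `[[`, character(1), 2),
                        weight = as.integer(tab), stringsAsFactors = FALSE)
    edges <- edges[order(-edges$weight, edges$author_a, edges$author_b), ,
                   drop = FALSE]
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "coauthor_graph")
}

#' @export
print.coauthor_graph <- function(x, ...) {
  cat(sprintf("<coauthor_graph> %d authors, %d co-authorship edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Convert a co-authorship graph to igraph
#'
#' @param graph A [build_coauthor_graph()] result.
#' @return An undirected [igraph::igraph] with edge `weight` and vertex
#'   `n_papers`.
#' @export
coauthor_igraph <- function(graph) {
  nodes <- graph$nodes
  names(nodes)[1] <- "name"
  igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                vertices = nodes)
}

#' Most frequent authors in scope
#'
#' @param corpus An [annotated_corpus()].
#' @param scope_ids Optional abstract ids restricting the scope.
#' @param k Number of authors to return.
#' @return Data frame `author`, `n_papers`, sorted by paper count
#'   descending, author key ascending on ties, truncated to `k`.
#' @export
top_authors <- function(corpus, scope_ids = NULL, k = 10) {
  if (k < 1) litnet_stop("k must be >= 1")
  g <- build_coauthor_graph(corpus, scope_ids)
  nodes <- g$nodes[order(-g$nodes$n_papers, g$nodes$author), , drop = FALSE]
  nodes <- utils::head(nodes, k)
  rownames(nodes) <- NULL
  nodes
}

#' Country publication statistics
#'
#' Each paper is attributed to its single normalized country (derived at
#' corpus read from the first affiliation); papers without a resolvable
#' country fall into the `"unresolved"` bucket, so the counts always sum to
#' the scope size.
#'
#' @param corpus An [annotated_corpus()].
#' @param scope_ids Optional abstract ids restricting the scope.
#' @return Data frame `country`, `n_papers`, sorted by count descending
#'   then country name.
#' @export
country_stats <- function(corpus, scope_ids = NULL) {
  ab <- corpus$abstracts
  if (!is.null(scope_ids)) ab <- ab[ab$abstract_id %in% scope_ids, , drop = FALSE]
  country <- ifelse(is.na(ab$country), "unresolved", ab$country)
  if (length(country) == 0) {
    return(data.frame(country = character(0), n_papers = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(country)
  out <- data.frame(country = names(tab), n_papers = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_papers, out$country), , drop = FALSE]
  rownames(out) <- NULL
  out
}
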