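#' Pair and triad co-occurrence extraction
#'
#' Two (or three) entities co-occurring in the same abstract are taken as
#' evidence of a functional association. Extraction works on entity
#' presence per abstract (set semantics): each abstract contributes every
#' cross-product combination of its entities of the requested types.
#' Same-type pairs are unordered (stored with the smaller id first);
#' cross-type records keep members in the declared type order. Self-pairs
#' (the same canonical id twice) are excluded.
#'
#' @param corpus An [annotated_corpus()] with mentions.
#' @param scope_ids Abstract ids defining the extraction scope (e.g. a query
#'   result); defaults to the whole corpus.
#' @param type_a,type_b Entity types of the two members.
#' @return Data frame with columns `id_a`, `id_b`, `type_a`, `type_b`,
#'   `count` and list column `support_ids`, sorted by count descending then
#'   ids.
#' @export
extract_pairs <- function(corpus, scope_ids = NULL, type_a, type_b) {
  pres <- entity_presence(corpus, scope_ids)
  a <- pres[pres$entity_type == type_a, c("abstract_id", "canonical_id")]
  b <- pres[pres$entity_type == type_b, c("abstract_id", "canonical_id")]
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      type_a = character(0), type_b = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  empty$support_ids <- list()
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  m <- merge(a, b, by = "abstract_id", suffixes = c("_a", "_b"))
  if (type_a == type_b) {
    m <- m[m$canonical_id_a < m$canonical_id_b, , drop = FALSE]
  } else {
    m <- m[m$canonical_id_a != m$canonical_id_b, , drop = FALSE]
  }
  if (nrow(m) == 0) return(empty)
  key <- paste(m$canonical_id_a, m$canonical_id_b, sep = "\r")
  supp <- lapply(split(m$abstract_id, key), function(x) sort(unique(x)))
  ids <- strsplit(names(supp), "\r", fixed = TRUE)
  out <- data.frame(id_a = vapply(ids, `[[`, character(1), 1),
                    id_b = vapply(ids, `[[`, character(1), 2),
                    type_a = type_a, type_b = type_b,
                    count = lengths(supp), stringsAsFactors = FALSE)
  out$support_ids <- unname(supp)
  ord <- order(-out$count, out$id_a, out$id_b)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Unique (abstract_id, canonical_id, entity_type) presence rows in scope.
entity_presence <- function(corpus, scope_ids = NULL) {
  m <- corpus$mentions[c("abstract_id", "canonical_id", "entity_type")]
  if (!is.null(scope_ids)) m <- m[m$abstract_id %in% scope_ids, , drop = FALSE]
  m[!duplicated(m), , drop = FALSE]
}

#' Extract typed triads (e.g. gene-drug-disease)
#'
#' @param corpus An [annotated_corpus()] with mentions.
#' @param scope_ids Abstract ids defining the scope; defaults to the whole
#'   corpus.
#' @param triple_types Character vector of three entity types, classically
#'   `c("gene", "drug", "disease")` or `c("gene", "disease", "process")`.
#' @return Data frame with `id_a`, `id_b`, `id_c`, `type_a..c`, `count` and
#'   list column `support_ids`, sorted by count descending (the most
#'   frequent combinations first).
#' @export
extract_triads <- function(corpus, scope_ids = NULL,
                           triple_types = c("gene", "drug", "disease")) {
  if (length(triple_types) != 3) litnet_stop("triple_types must name 3 types")
  pres <- entity_presence(corpus, scope_ids)
  parts <- lapply(triple_types, function(tt) {
    pres[pres$entity_type == tt, c("abstract_id", "canonical_id")]
  })
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      id_c = character(0), type_a = character(0),
                      type_b = character(0), type_c = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  empty$support_ids <- list()
  if (any(vapply(parts, nrow, integer(1)) == 0)) return(empty)
  m <- merge(parts[[1]], parts[[2]], by = "abstract_id",
             suffixes = c("_a", "_b"))
  names(parts[[3]])[2] <- "canonical_id_c"
  m <- merge(m, parts[[3]], by = "abstract_id")
  m <- m[m$canonical_id_a != m$canonical_id_b &
           m$canonical_id_a != m$canonical_id_c &
           m$canonical_id_b != m$canonical_id_c, , drop = FALSE]
  if (triple_types[[1]] == triple_types[[2]]) {
    m <- m[m$canonical_id_a < m$canonical_id_b, , drop = FALSE]
  }
  if (triple_types[[2]] == triple_types[[3]]) {
    m <- m[m$canonical_id_b < m$canonical_id_c, , drop = FALSE]
  }
  if (triple_types[[1]] == triple_types[[3]]) {
    m <- m[m$canonical_id_a < m$canonical_id_c, , drop = FALSE]
  }
  if (nrow(m) == 0) return(empty)
  key <- paste(m$canonical_id_a, m$canonical_id_b, m$canonical_id_c,
               sep = "\r")
  supp <- lapply(split(m$abstract_id, key), function(x) sort(unique(x)))
  ids <- strsplit(names(supp), "\r", fixed = TRUE)
  out <- data.frame(id_a = vapply(ids, `[[`, character(1), 1),
                    id_b = vapply(ids, `[[`, character(1), 2),
                    id_c = vapply(ids, `[[`, character(1), 3),
                    type_a = triple_types[[1]], type_b = triple_types[[2]],
                    type_c = triple_types[[3]],
                    count = lengths(supp), stringsAsFactors = FALSE)
  out$support_ids <- unname(supp)
  ord <- order(-out$count, out$id_a, out$id_b, out$id_c)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach query- and global-context mutual information to pairs
#'
#' The query-context score uses the query result as the denominator
#' population; the global score uses the whole corpus. A context in which
#' the pair (or a member) has no support gets `NA` rather than an error.
#'
#' @param pairs Output of [extract_pairs()].
#' @param corpus An [annotated_corpus()].
#' @param query_ids Abstract ids of the query result (the query context).
#' @return `pairs` with added numeric columns `mi_query` and `mi_global`.
#' @export
score_pairs <- function(pairs, corpus, query_ids) {
  all_ids <- corpus$abstracts$abstract_id
  n_query <- length(query_ids)
  n_global <- length(all_ids)
  ctx_mi <- function(i, ctx_ids, n_total, context) {
    sup <- intersect(pairs$support_ids[[i]], ctx_ids)
    if (length(sup) == 0) return(NA_real_)
    n_x <- length(intersect(corpus$index[[pairs$id_a[[i]]]], ctx_ids))
    n_y <- length(intersect(corpus$index[[pairs$id_b[[i]]]], ctx_ids))
    if (n_x == 0 || n_y == 0) return(NA_real_)
    mutual_information(length(sup), n_x, n_y, n_total, context)$mi
  }
  pairs$mi_query <- vapply(seq_len(nrow(pairs)), ctx_mi, numeric(1),
                           ctx_ids = query_ids, n_total = n_query,
                           context = "query")
  pairs$mi_global <- vapply(seq_len(nrow(pairs)), ctx_mi, numeric(1),
                            ctx_ids = all_ids, n_total = n_global,
                            context = "global")
  pairs
}

#' Score triads with the hypergeometric test
#'
#' A triad is scored by splitting it into the leading pair versus the third
#' member: within the scope, `X` counts abstracts containing members 1 and
#' 2, `Z` counts abstracts containing member 3, `A` counts abstracts
#' containing all three, and the universe `N` is the scope abstracts
#' carrying at least one entity mention. The upper-tail hypergeometric
#' probability then asks how surprising it is that the third member lands on
#' the pair's abstracts that often. `split = "symmetric"` averages the
#' probability over the three possible pair-vs-member splits, removing the
#' dependence on member order.
#'
#' @param triads Output of [extract_triads()].
#' @param corpus An [annotated_corpus()].
#' @param scope_ids Scope abstract ids (the query result by default
#'   semantics); defaults to the whole corpus.
#' @param split `"third-member"` (default) or `"symmetric"`.
#' @return `triads` with added numeric columns `p` and `score`.
#' @export
score_triads <- function(triads, corpus, scope_ids = NULL,
                         split = c("third-member", "symmetric")) {
  split <- match.arg(split)
  if (is.null(scope_ids)) scope_ids <- corpus$abstracts$abstract_id
  pres <- entity_presence(corpus, scope_ids)
  universe <- unique(pres$abstract_id)
  N <- length(universe)
  in_scope <- function(id) intersect(corpus$index[[id]], universe)
  one_split <- function(pair1, pair2, third) {
    s1 <- in_scope(pair1); s2 <- in_scope(pair2); s3 <- in_scope(third)
    pair_ids <- intersect(s1, s2)
    X <- length(pair_ids)
    if (X == 0) litnet_stop("degenerate triad table: pair support is empty in scope")
    Z <- length(s3)
    A <- length(intersect(pair_ids, s3))
    tab <- contingency_table(A, X - A, Z - A, N - X - Z + A)
    hypergeometric_p(tab, "upper")
  }
  score_one <- function(i) {
    a <- triads$id_a[[i]]; b <- triads$id_b[[i]]; c <- triads$id_c[[i]]
    p <- if (split == "third-member") {
      one_split(a, b, c)
    } else {
      mean(c(one_split(a, b, c), one_split(a, c, b), one_split(b, c, a)))
    }
    p
  }
  p <- vapply(seq_len(nrow(triads)), score_one, numeric(1))
  triads$p <- p
  triads$score <- vapply(p, function(pp) association_score(pp)$score,
                         numeric(1))
  triads
}

#' Build a co-occurrence network from pair/triad records
#'
#' Nodes are bio-entities (typed, so a display can color-code them); each
#' pair contributes an edge whose weight is the number of supporting
#' abstracts; each triad expands to a 3-clique whose edges carry the triad
#' id.
#'
#' @param pairs Output of [extract_pairs()] (optionally scored), or `NULL`.
#' @param triads Output of [extract_triads()], or `NULL`.
#' @return An [igraph::igraph] with vertex attribute `entity_type` and edge
#'   attributes `weight` (support count) and `triad` (triad key or `NA`).
#' @export
cooccurrence_network <- function(pairs = NULL, triads = NULL) {
  nodes <- data.frame(id = character(0), entity_type = character(0),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = character(0), to = character(0),
                      weight = integer(0), triad = character(0),
                      stringsAsFactors = FALSE)
  add_nodes <- function(nodes, ids, types) {
    rbind(nodes, data.frame(id = ids, entity_type = types,
                            stringsAsFactors = FALSE))
  }
  if (!is.null(pairs) && nrow(pairs) > 0) {
    nodes <- add_nodes(nodes, c(pairs$id_a, pairs$id_b),
                       c(pairs$type_a, pairs$type_b))
    edges <- rbind(edges, data.frame(from = pairs$id_a, to = pairs$id_b,
                                     weight = pairs$count,
                                     triad = NA_character_,
                                     stringsAsFactors = FALSE))
  }
  if (!is.null(triads) && nrow(triads) > 0) {
    nodes <- add_nodes(nodes, c(triads$id_a, triads$id_b, triads$id_c),
                       c(triads$type_a, triads$type_b, triads$type_c))
    tkey <- paste(triads$id_a, triads$id_b, triads$id_c, sep = "|")
    for (i in seq_len(nrow(triads))) {
      combos <- rbind(c(triads$id_a[[i]], triads$id_b[[i]]),
                      c(triads$id_a[[i]], triads$id_c[[i]]),
                      c(triads$id_b[[i]], triads$id_c[[i]]))
      edges <- rbind(edges, data.frame(from = combos[, 1], to = combos[, 2],
                                       weight = triads$count[[i]],
                                       triad = tkey[[i]],
                                       stringsAsFactors = FALSE))
    }
  }
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Write pair or triad records as TSV
#'
#' @param records Output of [extract_pairs()]/[extract_triads()] with any
#'   score columns attached.
#' @param path Output path.
#' @export
write_cooccurrence <- function(records, path) {
  df <- records
  df$support_ids <- vapply(df$support_ids, paste, character(1), collapse = ",")
  for (col in intersect(c("mi_query", "mi_global", "p", "score"), names(df))) {
    df[[col]] <- fmt_num(df[[col]], 10)
  }
  write_tsv_file(df, path)
}
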