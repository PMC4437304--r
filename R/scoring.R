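#' Publication contingency tables
#'
#' The association between a query and a bio-entity is judged on a 2x2
#' table of publication counts over the universe `U` of abstracts that
#' contain at least one entity of the same class (e.g. at least one gene):
#'
#' * `A` — query-matching publications containing the entity
#' * `B` — query-matching publications without the entity
#' * `C` — publications with the entity but outside the query
#' * `D` — publications with neither, but with some entity of the class
#'
#' Derived margins: `X = A + B` (query side), `Y = C + D` (rest),
#' `N = X + Y` (universe), `Z = A + C` (entity side).
#'
#' @param A,B,C,D Non-negative integer counts.
#' @return An object of class `contingency_table` with fields
#'   `A,B,C,D,X,Y,N,Z`.
#' @export
contingency_table <- function(A, B, C, D) {
  counts <- c(A = A, B = B, C = C, D = D)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    litnet_stop("contingency counts must be non-negative integers")
  }
  tab <- list(A = as.integer(A), B = as.integer(B), C = as.integer(C),
              D = as.integer(D))
  tab$X <- tab$A + tab$B
  tab$Y <- tab$C + tab$D
  tab$N <- tab$X + tab$Y
  tab$Z <- tab$A + tab$C
  structure(tab, class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> A=%d B=%d C=%d D=%d (X=%d Y=%d N=%d Z=%d)\n",
              x$A, x$B, x$C, x$D, x$X, x$Y, x$N, x$Z))
  invisible(x)
}

#' Build the query-vs-entity contingency table from a corpus
#'
#' The universe is restricted to abstracts carrying at least one mention of
#' the given entity class, following the design in which `Y` counts
#' publications "in which at least one bio-entity term is found".
#'
#' @param query_ids Abstract ids retrieved by the query.
#' @param entity_id Canonical id of the entity under test.
#' @param corpus An [annotated_corpus()] with mentions.
#' @param entity_type Entity class defining the universe.
#' @return A [contingency_table()].
#' @export
build_contingency <- function(query_ids, entity_id, corpus, entity_type) {
  if (!entity_id %in% names(corpus$index)) {
    litnet_stop("entity '%s' not present in the corpus index", entity_id)
  }
  type_mentions <- corpus$mentions[corpus$mentions$entity_type == entity_type, ]
  universe <- unique(type_mentions$abstract_id)
  entity_ids <- intersect(corpus$index[[entity_id]], universe)
  query_u <- intersect(query_ids, universe)
  A <- length(intersect(query_u, entity_ids))
  B <- length(query_u) - A
  C <- length(entity_ids) - A
  D <- length(universe) - A - B - C
  contingency_table(A, B, C, D)
}

#' Hypergeometric probability of an observed association
#'
#' Under the null that the `Z` entity-bearing publications are drawn at
#' random from the universe of `N`, the point probability of seeing exactly
#' `A` of them inside the `X` query publications is
#' `choose(X, A) * choose(Y, C) / choose(N, Z)`. The upper tail sums the
#' point masses for `a = A .. min(X, Z)` and is the default enrichment
#' reading ("at least this much overlap by chance"). Both are computed in
#' log space, so very small probabilities do not underflow through the
#' binomial coefficients.
#'
#' @param table A [contingency_table()].
#' @param tail `"upper"` (default) or `"point"`.
#' @return Probability in (0, 1].
#' @export
hypergeometric_p <- function(table, tail = c("upper", "point")) {
  tail <- match.arg(tail)
  stopifnot(inherits(table, "contingency_table"))
  A <- table$A; X <- table$X; Y <- table$Y; N <- table$N; Z <- table$Z
  if (A > X || table$C > Y || Z > N) {
    litnet_stop("inconsistent contingency table")
  }
  log_point <- function(a) lchoose(X, a) + lchoose(Y, Z - a) - lchoose(N, Z)
  if (tail == "point") {
    p <- exp(log_point(A))
  } else {
    a_lo <- max(A, Z - Y)
    a_hi <- min(X, Z)
    p <- exp(logsumexp(vapply(a_lo:a_hi, log_point, numeric(1))))
  }
  min(max(p, 0), 1)
}

#' Log-transformed association score
#'
#' `score = -log2(p) / 100`. The binomial-coefficient combinations can make
#' the probability extremely small, so the score is the base-2 log of the
#' probability, negated so larger means more significant, and divided by the
#' constant 100 to keep it on a convenient scale. A probability of 1 (no
#' surprise) gives score 0.
#'
#' @param p Probability in (0, 1].
#' @param tail Which tail produced `p` (recorded, not used in the formula).
#' @return An object of class `association_score` with fields `p_hgd`,
#'   `score`, `tail`.
#' @export
association_score <- function(p, tail = "upper") {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p <= 0 || p > 1) {
    litnet_stop("p must be a probability in (0, 1]")
  }
  structure(list(p_hgd = p, score = -log2(p) / 100, tail = tail),
            class = "association_score")
}

#' @export
print.association_score <- function(x, ...) {
  cat(sprintf("<association_score> p=%.4g score=%.6f (%s tail)\n",
              x$p_hgd, x$score, x$tail))
  invisible(x)
}

#' Mutual information of a co-occurring pair
#'
#' Pointwise mutual information of two entities over a context of `n_total`
#' abstracts: `mi = log2( (n_xy / n_total) / ((n_x / n_total) * (n_y /
#' n_total)) )`, the log-ratio of the observed joint occurrence probability
#' to the product of the marginals. Zero means exact independence; positive
#' values mean the pair co-occurs more often than chance. The context is
#' either the query result (`n_total` = number of retrieved abstracts) or
#' the whole corpus.
#'
#' @param n_xy Abstracts containing both entities (must be >= 1).
#' @param n_x,n_y Abstracts containing each entity in the context.
#' @param n_total Context size.
#' @param context `"query"` or `"global"`.
#' @return An object of class `mi_score` with fields `n_xy`, `n_x`, `n_y`,
#'   `n_total`, `mi`, `context`.
#' @export
mutual_information <- function(n_xy, n_x, n_y, n_total,
                               context = c("query", "global")) {
  context <- match.arg(context)
  if (n_xy == 0) litnet_stop("no co-occurrence support (n_xy = 0)")
  if (n_xy < 0 || n_xy > min(n_x, n_y) || max(n_x, n_y) > n_total) {
    litnet_stop("invalid counts: need 0 < n_xy <= min(n_x, n_y) <= n_total")
  }
  mi <- log2(n_xy) + log2(n_total) - log2(n_x) - log2(n_y)
  structure(list(n_xy = n_xy, n_x = n_x, n_y = n_y, n_total = n_total,
                 mi = mi, context = context),
            class = "mi_score")
}

#' @export
print.mi_score <- function(x, ...) {
  cat(sprintf("<mi_score> mi=%.4f (n_xy=%d, n_x=%d, n_y=%d, N=%d, %s context)\n",
              x$mi, x$n_xy, x$n_x, x$n_y, x$n_total, x$context))
  invisible(x)
}

#' Rank entities of one class against a query
#'
#' Every entity of the class with at least one abstract inside the query
#' result is scored with the hypergeometric association score and ranked:
#' score descending, then count-in-query descending, then canonical id
#' ascending.
#'
#' @param corpus An [annotated_corpus()] with mentions.
#' @param query_ids Abstract ids retrieved by the query.
#' @param entity_type Entity class to rank.
#' @param tail Passed to [hypergeometric_p()].
#' @param dictionary Optional [entity_dictionary()] used to attach preferred
#'   names.
#' @return Data frame with columns `rank`, `canonical_id`, `preferred_name`,
#'   `entity_type`, `count_in_query`, `total_count`, `p`, `score`.
#' @export
rank_entities <- function(corpus, query_ids, entity_type,
                          tail = c("upper", "point"), dictionary = NULL) {
  tail <- match.arg(tail)
  out0 <- data.frame(rank = integer(0), canonical_id = character(0),
                     preferred_name = character(0), entity_type = character(0),
                     count_in_query = integer(0), total_count = integer(0),
                     p = numeric(0), score = numeric(0),
                     stringsAsFactors = FALSE)
  if (length(query_ids) == 0) return(out0)
  type_mentions <- corpus$mentions[corpus$mentions$entity_type == entity_type, ]
  if (nrow(type_mentions) == 0) return(out0)
  ids <- sort(unique(type_mentions$canonical_id))
  rows <- lapply(ids, function(id) {
    tab <- build_contingency(query_ids, id, corpus, entity_type)
    if (tab$A == 0) return(NULL)
    p <- hypergeometric_p(tab, tail)
    data.frame(canonical_id = id, count_in_query = tab$A,
               total_count = tab$Z, p = p,
               score = association_score(p, tail)$score,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(out0)
  ord <- order(-rows$score, -rows$count_in_query, rows$canonical_id)
  rows <- rows[ord, , drop = FALSE]
  rows$rank <- seq_len(nrow(rows))
  rows$entity_type <- entity_type
  rows$preferred_name <- if (!is.null(dictionary)) {
    dictionary$preferred_name[match(rows$canonical_id, dictionary$canonical_id)]
  } else NA_character_
  rownames(rows) <- NULL
  rows[c("rank", "canonical_id", "preferred_name", "entity_type",
         "count_in_query", "total_count", "p", "score")]
}

#' Write a ranked-entity table as TSV
#'
#' @param ranked Output of [rank_entities()].
#' @param path Output path.
#' @export
write_ranked_entities <- function(ranked, path) {
  df <- ranked
  df$p <- fmt_num(df$p, 10)
  df$score <- fmt_num(df$score, 10)
  write_tsv_file(df, path)
}
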