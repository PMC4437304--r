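#' Run the full search-and-rank workflow
#'
#' Ties the modules together the way the command-line `search` front end
#' does: parse the query, expand secondary terms with dictionary synonyms,
#' run the primary search (optionally restricted to papers by a given
#' author), sort the hits into mutually exclusive secondary combination
#' buckets and rank entities of every type present in the corpus.
#'
#' @param corpus An [annotated_corpus()] (tagged, or with mentions read in).
#' @param dictionary An [entity_dictionary()].
#' @param primary,secondary,exclude Query strings (see [parse_query()]).
#' @param author Optional `"Surname Initials"` key: restrict the scope to
#'   papers with that author.
#' @param tail Passed to [rank_entities()].
#' @return List with `query`, `result_ids`, `buckets` and `ranked` (a list
#'   of data frames, one per entity type present).
#' @export
run_search <- function(corpus, dictionary, primary, secondary = "",
                       exclude = "", author = NULL,
                       tail = c("upper", "point")) {
  tail <- match.arg(tail)
  query <- parse_query(primary, secondary, exclude)
  query$secondary_groups <- lapply(query$secondary_groups, expand_terms,
                                   dictionary = dictionary)
  result_ids <- search_corpus(corpus, query)
  if (!is.null(author)) {
    keys <- lapply(corpus$abstracts$authors, function(au) {
      trimws(paste(au$surname, au$initials))
    })
    with_author <- corpus$abstracts$abstract_id[
      vapply(keys, function(k) author %in% k, logical(1))]
    result_ids <- intersect(result_ids, with_author)
  }
  buckets <- combination_buckets(result_ids, corpus, query$secondary_groups)
  types <- sort(unique(corpus$mentions$entity_type))
  ranked <- lapply(types, function(tt) {
    rank_entities(corpus, result_ids, tt, tail = tail,
                  dictionary = dictionary)
  })
  names(ranked) <- types
  list(query = query, result_ids = result_ids, buckets = buckets,
       ranked = ranked)
}

#' Generate the summary report
#'
#' A single sectioned plain-text document mirroring the emailed summary a
#' literature-mining server would send: abstract counts per secondary
#' combination bucket, the top entities of every type with their
#' hypergeometric scores, the most frequent pairs and triads, crosstalk
#' proteins, frequent authors and country statistics. Every number in the
#' report is the corresponding module output; the document is byte-stable
#' for identical inputs.
#'
#' @param corpus,dictionary As in [run_search()].
#' @param primary,secondary,exclude Query strings.
#' @param pathways Optional pathway table from [load_pathways()].
#' @param top_k Rows per section.
#' @param out_file Output path; `NULL` returns the lines invisibly only.
#' @return The report lines, invisibly.
#' @export
run_report <- function(corpus, dictionary, primary, secondary = "",
                       exclude = "", pathways = NULL, top_k = 10,
                       out_file = NULL) {
  res <- run_search(corpus, dictionary, primary, secondary, exclude)
  ids <- res$result_ids
  lines <- c("# litnet summary report",
             sprintf("primary_query\t%s", primary),
             sprintf("n_abstracts_retrieved\t%d", length(ids)),
             "", "## secondary combination buckets (mutually exclusive)")
  if (nrow(res$buckets) > 0) {
    lines <- c(lines, sprintf("bucket\t%s\t%d", res$buckets$key,
                              res$buckets$n_abstracts))
  } else {
    lines <- c(lines, "bucket\t(none)")
  }
  for (tt in names(res$ranked)) {
    r <- utils::head(res$ranked[[tt]], top_k)
    lines <- c(lines, "", sprintf("## top %s entities (%d in query scope)",
                                  tt, nrow(res$ranked[[tt]])))
    if (nrow(r) > 0) {
      lines <- c(lines, sprintf("%d\t%s\t%s\t%d\t%d\t%s", r$rank,
                                r$canonical_id, r$preferred_name,
                                r$count_in_query, r$total_count,
                                fmt_num(r$score, 8)))
    }
  }
  pairs <- extract_pairs(corpus, ids, "gene", "drug")
  if (nrow(pairs) > 0) pairs <- score_pairs(pairs, corpus, ids)
  lines <- c(lines, "", "## top gene-drug pairs")
  if (nrow(pairs) > 0) {
    p <- utils::head(pairs, top_k)
    lines <- c(lines, sprintf("%s\t%s\t%d\t%s\t%s", p$id_a, p$id_b, p$count,
                              fmt_num(p$mi_query, 6), fmt_num(p$mi_global, 6)))
  }
  triads <- extract_triads(corpus, ids, c("gene", "drug", "disease"))
  lines <- c(lines, "", "## top gene-drug-disease triads")
  if (nrow(triads) > 0) {
    triads <- score_triads(triads, corpus, ids)
    t3 <- utils::head(triads, top_k)
    lines <- c(lines, sprintf("%s\t%s\t%s\t%d\t%s", t3$id_a, t3$id_b,
                              t3$id_c, t3$count, fmt_num(t3$p, 8)))
  }
  if (!is.null(pathways)) {
    ct <- crosstalk(pathways)
    lines <- c(lines, "", sprintf("## crosstalk proteins (%d)", nrow(ct)))
    if (nrow(ct) > 0) {
      c3 <- utils::head(ct, top_k)
      lines <- c(lines, sprintf("%s\t%d\t%s", c3$protein, c3$n_pathways,
                                vapply(c3$pathway_ids, paste, character(1),
                                       collapse = ",")))
    }
  }
  ta <- top_authors(corpus, ids, k = top_k)
  lines <- c(lines, "", "## most frequent authors")
  if (nrow(ta) > 0) {
    lines <- c(lines, sprintf("%s\t%d", ta$author, ta$n_papers))
  }
  cs <- country_stats(corpus, ids)
  lines <- c(lines, "", "## country statistics")
  if (nrow(cs) > 0) {
    lines <- c(lines, sprintf("%s\t%d", cs$country, cs$n_papers))
  }
  if (!is.null(out_file)) writeLines(lines, out_file)
  invisible(lines)
}
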