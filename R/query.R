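#' Parse a two-tier keyword query
#'
#' The primary query is an AND of OR-groups: `","` separates AND groups and
#' `"|"` separates OR alternatives within a group (so
#' `"Glioblastoma|Glioma,EGFR"` requires one of Glioblastoma/Glioma AND
#' EGFR). Secondary keywords are one OR-group per line. Exclusion terms
#' remove any abstract containing them. Terms are literal phrases, matched
#' case-insensitively on word boundaries; whitespace around terms is
#' trimmed.
#'
#' @param primary_text Primary keyword string (required, non-empty).
#' @param secondary_text Secondary keywords, one OR-group per line (may be
#'   empty).
#' @param exclusion_text Exclusion terms separated by `","`, `"|"` or
#'   newlines (may be empty).
#' @return An object of class `query_expression` with elements `primary`
#'   (list of character vectors), `secondary_groups` (list of character
#'   vectors) and `exclusions` (character vector).
#' @examples
#' q <- parse_query("Glioblastoma|Glioma|Brain tumor|Brain cancer",
#'                  "EGFR\nTP53\nErlotinib|Gefitinib")
#' @export
parse_query <- function(primary_text, secondary_text = "",
                        exclusion_text = "") {
  if (is.null(primary_text) || !nzchar(trimws(primary_text))) {
    litnet_stop("primary query must be non-empty")
  }
  primary <- lapply(seq_along(grps <- strsplit(primary_text, ",", fixed = TRUE)[[1]]),
                    function(i) split_or_group(grps[[i]], sprintf("primary group %d", i)))
  if (length(primary) == 0) litnet_stop("primary query must be non-empty")
  secondary <- list()
  if (nzchar(trimws(secondary_text))) {
    lines <- strsplit(secondary_text, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    secondary <- lapply(seq_along(lines), function(i) {
      split_or_group(lines[[i]], sprintf("secondary line %d", i))
    })
  }
  exclusions <- character(0)
  if (nzchar(trimws(exclusion_text))) {
    exclusions <- trimws(strsplit(exclusion_text, "[,|\n]")[[1]])
    exclusions <- exclusions[nzchar(exclusions)]
  }
  structure(list(primary = primary, secondary_groups = secondary,
                 exclusions = exclusions),
            class = "query_expression")
}

split_or_group <- function(text, where) {
  terms <- strsplit(text, "|", fixed = TRUE)[[1]]
  if (length(terms) == 0) litnet_stop("empty term in %s", where)
  terms <- trimws(terms)
  empty <- which(!nzchar(terms))
  if (length(empty) > 0) {
    litnet_stop("empty term at position %d of %s", empty[[1]], where)
  }
  terms
}

#' @export
print.query_expression <- function(x, ...) {
  cat(sprintf("<query_expression> primary: %s\n",
              paste(vapply(x$primary, paste, character(1), collapse = "|"),
                    collapse = " AND ")))
  if (length(x$secondary_groups) > 0) {
    cat(sprintf("  secondary: %s\n",
                paste(vapply(x$secondary_groups, paste, character(1),
                             collapse = "|"), collapse = " ; ")))
  }
  if (length(x$exclusions) > 0) {
    cat(sprintf("  exclude: %s\n", paste(x$exclusions, collapse = ", ")))
  }
  invisible(x)
}

#' Expand query terms with dictionary synonyms
#'
#' Any term that equals (case-insensitively) a synonym of a dictionary
#' entity is replaced by the full synonym set of that entity, so searching
#' for `TP53` also retrieves `p53` and `tumor protein p53`. Terms unknown to
#' the dictionary pass through unchanged. A term matching synonyms of more
#' than one entity expands to the union of their synonym sets and raises a
#' warning naming the ambiguous term.
#'
#' @param terms Character vector (one OR-group).
#' @param dictionary An [entity_dictionary()].
#' @return Character vector of expanded terms (duplicates removed,
#'   case-insensitively, first spelling kept).
#' @export
expand_terms <- function(terms, dictionary) {
  syn <- synonym_table(dictionary)
  out <- character(0)
  for (term in terms) {
    hit_ids <- unique(syn$canonical_id[tolower(syn$synonym) == tolower(term)])
    if (length(hit_ids) == 0) {
      out <- c(out, term)
    } else {
      if (length(hit_ids) > 1) {
        warning(sprintf("term '%s' is ambiguous: matches entities %s",
                        term, paste(sort(hit_ids), collapse = ", ")),
                call. = FALSE)
      }
      out <- c(out, syn$synonym[syn$canonical_id %in% hit_ids])
    }
  }
  out[!duplicated(tolower(out))]
}

# Which abstracts contain the term as a word-boundary, case-insensitive
# phrase? Returns a logical vector over corpus order.
term_hits <- function(texts, term) {
  grepl(boundary_pattern(term), texts, perl = TRUE, ignore.case = TRUE)
}

group_hits <- function(texts, terms) {
  hit <- rep(FALSE, length(texts))
  for (term in terms) hit <- hit | term_hits(texts, term)
  hit
}

#' Run the primary search
#'
#' An abstract matches when every primary AND-group contributes at least one
#' matching term and no exclusion term is present. Exclusions are applied
#' here, before any secondary bucketing.
#'
#' @param corpus An [annotated_corpus()].
#' @param query A [parse_query()] result.
#' @return Character vector of matching abstract ids, in corpus order.
#' @export
search_corpus <- function(corpus, query) {
  texts <- abstract_text(corpus)
  if (length(texts) == 0) return(character(0))
  keep <- rep(TRUE, length(texts))
  for (grp in query$primary) keep <- keep & group_hits(texts, grp)
  for (term in query$exclusions) keep <- keep & !term_hits(texts, term)
  corpus$abstracts$abstract_id[keep]
}

#' Sort retrieved abstracts into mutually exclusive secondary buckets
#'
#' Each retrieved abstract that matches at least one secondary OR-group is
#' assigned to exactly one bucket, keyed by the full set of groups it
#' matches (its maximal matched subset), so the buckets partition the
#' matching abstracts. Abstracts matching no group appear in no bucket;
#' empty buckets are omitted.
#'
#' @param result_ids Abstract ids from [search_corpus()].
#' @param corpus An [annotated_corpus()].
#' @param secondary_groups List of OR-groups (character vectors), typically
#'   after [expand_terms()].
#' @return Data frame with columns `key` (group indices joined by `"+"`),
#'   `n_abstracts`, and list column `abstract_ids`.
#' @export
combination_buckets <- function(result_ids, corpus, secondary_groups) {
  empty <- data.frame(key = character(0), n_abstracts = integer(0),
                      stringsAsFactors = FALSE)
  empty$abstract_ids <- list()
  if (length(secondary_groups) == 0 || length(result_ids) == 0) return(empty)
  unknown <- setdiff(result_ids, corpus$abstracts$abstract_id)
  if (length(unknown) > 0) {
    litnet_stop("result ids not in corpus: %s", paste(unknown, collapse = ", "))
  }
  texts <- abstract_text(corpus)[result_ids]
  hit_mat <- vapply(secondary_groups, function(grp) group_hits(texts, grp),
                    logical(length(texts)))
  hit_mat <- matrix(hit_mat, nrow = length(texts))
  keys <- apply(hit_mat, 1, function(h) paste(which(h), collapse = "+"))
  keep <- nzchar(keys)
  if (!any(keep)) return(empty)
  split_ids <- split(result_ids[keep], keys[keep])
  out <- data.frame(key = names(split_ids),
                    n_abstracts = lengths(split_ids),
                    stringsAsFactors = FALSE)
  out$abstract_ids <- unname(split_ids)
  out <- out[order(out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a bucket report as TSV
#'
#' Columns: `bucket_key`, `n_abstracts`, comma-separated `abstract_ids`.
#'
#' @param buckets Output of [combination_buckets()].
#' @param path Output path.
#' @export
write_bucket_report <- function(buckets, path) {
  df <- data.frame(bucket_key = buckets$key,
                   n_abstracts = buckets$n_abstracts,
                   abstract_ids = vapply(buckets$abstract_ids, paste,
                                         character(1), collapse = ","),
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}
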