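#' Dictionary-based entity tagging
#'
#' Scans every abstract (title + body) for dictionary synonyms and emits one
#' entity mention per match. Matching is deterministic: left-to-right,
#' longest match wins, matches never overlap, and every match must sit on
#' word boundaries (no match inside a longer alphanumeric token, so the
#' synonym `EGFR` does not fire inside `EGFRvIII`). Matching is
#' case-insensitive except for short gene-symbol-like synonyms (no lowercase
#' letters, length at most 4), which match case-sensitively. Ties between
#' equal-length matches at the same position are broken by the
#' lexicographically smallest canonical id.
#'
#' Tagging replaces any mentions already attached to the corpus, so it is
#' idempotent.
#'
#' @param corpus An [annotated_corpus()].
#' @param dictionary An [entity_dictionary()].
#' @return The corpus with mentions and the rebuilt occurrence index.
#' @export
tag_entities <- function(corpus, dictionary) {
  if (nrow(dictionary) == 0) litnet_stop("dictionary is empty")
  syn <- synonym_table(dictionary)
  txt <- abstract_text(corpus)
  if (length(txt) == 0) return(set_mentions(corpus, empty_mentions()))

  # Collect every candidate match of every synonym across all abstracts.
  cand <- vector("list", nrow(syn))
  for (i in seq_len(nrow(syn))) {
    pat <- boundary_pattern(syn$synonym[[i]])
    hits <- gregexpr(pat, txt, perl = TRUE, ignore.case = !syn$case_sensitive[[i]])
    for (j in seq_along(hits)) {
      st <- hits[[j]]
      if (st[[1]] == -1L) next
      ln <- attr(st, "match.length")
      cand[[i]] <- rbind(cand[[i]], data.frame(
        doc = j, start = as.integer(st) - 1L,
        end = as.integer(st) - 1L + as.integer(ln),
        canonical_id = syn$canonical_id[[i]],
        entity_type = syn$entity_type[[i]],
        stringsAsFactors = FALSE))
    }
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0) {
    return(set_mentions(corpus, empty_mentions()))
  }

  kept <- lapply(split(cand, cand$doc), resolve_overlaps)
  kept <- do.call(rbind, kept)
  ids <- corpus$abstracts$abstract_id
  mentions <- data.frame(
    abstract_id = ids[kept$doc],
    canonical_id = kept$canonical_id,
    entity_type = kept$entity_type,
    surface = substr(txt[kept$doc], kept$start + 1L, kept$end),
    start = kept$start, end = kept$end,
    stringsAsFactors = FALSE
  )
  set_mentions(corpus, mentions)
}

# Leftmost-longest non-overlapping resolution: sort by start ascending,
# length descending, canonical id ascending, then greedily accept any
# candidate starting at or after the end of the last accepted match.
resolve_overlaps <- function(cand) {
  ord <- order(cand$start, -(cand$end - cand$start), cand$canonical_id)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  cur_end <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[[i]] >= cur_end) {
      keep[[i]] <- TRUE
      cur_end <- cand$end[[i]]
    }
  }
  cand[keep, , drop = FALSE]
}
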