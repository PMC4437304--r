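#' Evaluate predicted entity mentions against a gold standard
#'
#' Computes true positives, false positives and false negatives between a
#' gold and a predicted mention set, and from them precision
#' `tp / (tp + fp)`, recall `tp / (tp + fn)` and the F-measure
#' `2 * precision * recall / (precision + recall)`, with `0/0` defined as 0.
#' Duplicate identical mentions are collapsed before matching (set
#' semantics, consistent with presence-based corpus indexing).
#'
#' Matching modes:
#' * `exact-span` — a prediction matches a gold mention with identical
#'   `(abstract_id, start, end, entity_type)`.
#' * `overlap` — same abstract and type with intersecting spans; pairing is
#'   one-to-one, greedy left-to-right after sorting both sides by span
#'   start (deterministic).
#' * `canonical-id` — identical `(abstract_id, canonical_id)`; span-free
#'   normalization-level comparison.
#'
#' @param gold,predicted Mention data frames (as in an
#'   [annotated_corpus()] or from [read_mentions()]).
#' @param mode Matching mode.
#' @return An object of class `eval_result` with fields `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f_measure`, `match_mode`.
#' @export
evaluate_ner <- function(gold, predicted,
                         mode = c("exact-span", "overlap", "canonical-id")) {
  mode <- match.arg(mode)
  if (mode == "overlap") {
    counts <- match_overlap(gold, predicted)
  } else {
    key <- function(m) {
      if (mode == "exact-span") {
        paste(m$abstract_id, m$start, m$end, m$entity_type, sep = "\r")
      } else {
        paste(m$abstract_id, m$canonical_id, sep = "\r")
      }
    }
    gk <- unique(key(gold))
    pk <- unique(key(predicted))
    counts <- list(tp = length(intersect(gk, pk)),
                   fp = length(setdiff(pk, gk)),
                   fn = length(setdiff(gk, pk)))
  }
  ratio <- function(num, den) if (den == 0) 0 else num / den
  precision <- ratio(counts$tp, counts$tp + counts$fp)
  recall <- ratio(counts$tp, counts$tp + counts$fn)
  f <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(tp = counts$tp, fp = counts$fp, fn = counts$fn,
                 precision = precision, recall = recall, f_measure = f,
                 match_mode = mode),
            class = "eval_result")
}

# Greedy one-to-one pairing of overlapping spans per (abstract, type),
# both sides sorted by start so the pairing is order-deterministic.
match_overlap <- function(gold, predicted) {
  dedupe <- function(m) {
    k <- paste(m$abstract_id, m$start, m$end, m$entity_type, sep = "\r")
    m[!duplicated(k), , drop = FALSE]
  }
  gold <- dedupe(gold)
  predicted <- dedupe(predicted)
  tp <- 0L
  groups <- unique(rbind(gold[c("abstract_id", "entity_type")],
                         predicted[c("abstract_id", "entity_type")]))
  for (i in seq_len(nrow(groups))) {
    gsub_ <- gold[gold$abstract_id == groups$abstract_id[[i]] &
                    gold$entity_type == groups$entity_type[[i]], , drop = FALSE]
    psub <- predicted[predicted$abstract_id == groups$abstract_id[[i]] &
                        predicted$entity_type == groups$entity_type[[i]], ,
                      drop = FALSE]
    gsub_ <- gsub_[order(gsub_$start, gsub_$end), , drop = FALSE]
    psub <- psub[order(psub$start, psub$end), , drop = FALSE]
    used <- logical(nrow(gsub_))
    for (j in seq_len(nrow(psub))) {
      for (k in seq_len(nrow(gsub_))) {
        if (used[[k]]) next
        if (psub$start[[j]] < gsub_$end[[k]] &&
              gsub_$start[[k]] < psub$end[[j]]) {
          used[[k]] <- TRUE
          tp <- tp + 1L
          break
        }
      }
    }
  }
  list(tp = tp, fp = nrow(predicted) - tp, fn = nrow(gold) - tp)
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result %s> tp=%d fp=%d fn=%d P=%.4f R=%.4f F=%.4f\n",
              x$match_mode, x$tp, x$fp, x$fn, x$precision, x$recall,
              x$f_measure))
  invisible(x)
}

#' Write an evaluation result as a one-line TSV
#'
#' @param result An [evaluate_ner()] result.
#' @param path Output path.
#' @export
write_eval_result <- function(result, path) {
  df <- data.frame(match_mode = result$match_mode, tp = result$tp,
                   fp = result$fp, fn = result$fn,
                   precision = fmt_num(result$precision),
                   recall = fmt_num(result$recall),
                   f_measure = fmt_num(result$f_measure),
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}
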