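# Fixtures built in code, shared across test files.

# A small corpus from raw texts: ids A1, A2, ... titles empty-ish.
mini_corpus <- function(bodies, titles = NULL) {
  n <- length(bodies)
  if (is.null(titles)) titles <- sprintf("Record %d", seq_len(n))
  annotated_corpus(data.frame(
    abstract_id = sprintf("A%d", seq_len(n)),
    title = titles, body = bodies, stringsAsFactors = FALSE))
}

toy_dictionary <- function() {
  entity_dictionary(
    canonical_id = c("G:TP53", "G:EGFR", "P:APOP", "D:ERLO"),
    entity_type = c("gene", "gene", "process", "drug"),
    preferred_name = c("TP53", "EGFR", "apoptosis", "Erlotinib"),
    synonyms = list(c("TP53", "p53", "tumor protein p53"),
                    c("EGFR", "epidermal growth factor receptor"),
                    "apoptosis",
                    c("Erlotinib", "Gefitinib")))
}

# Corpus with known per-abstract entity sets, built by writing each set's
# tokens into the body and attaching gold mentions through the generator-free
# path: sets is a list of character vectors of canonical ids drawn from
# `ents` (data.frame canonical_id, entity_type, token).
corpus_from_sets <- function(sets, ents) {
  bodies <- vapply(sets, function(s) {
    toks <- ents$token[match(s, ents$canonical_id)]
    if (length(toks) == 0) "empty record body" else paste(toks, collapse = " ")
  }, character(1))
  corpus <- mini_corpus(bodies)
  txt <- abstract_text(corpus)
  rows <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (length(s) == 0) return(NULL)
    toks <- ents$token[match(s, ents$canonical_id)]
    pos <- vapply(toks, function(tk) {
      as.integer(regexpr(tk, txt[[i]], fixed = TRUE))
    }, integer(1))
    data.frame(abstract_id = sprintf("A%d", i), canonical_id = s,
               entity_type = ents$entity_type[match(s, ents$canonical_id)],
               surface = toks, start = pos - 1L, end = pos - 1L + nchar(toks),
               stringsAsFactors = FALSE)
  })
  mentions <- do.call(rbind, rows)
  if (is.null(mentions)) return(corpus)
  litnet:::set_mentions(corpus, mentions)
}

fuzz_entities <- function(n_gene = 5, n_drug = 3, n_disease = 2) {
  data.frame(
    canonical_id = c(sprintf("G%02d", seq_len(n_gene)),
                     sprintf("D%02d", seq_len(n_drug)),
                     sprintf("S%02d", seq_len(n_disease))),
    entity_type = c(rep("gene", n_gene), rep("drug", n_drug),
                    rep("disease", n_disease)),
    token = c(sprintf("genea%02d", seq_len(n_gene)),
              sprintf("druga%02d", seq_len(n_drug)),
              sprintf("disea%02d", seq_len(n_disease))),
    stringsAsFactors = FALSE)
}

# Random presence corpus for fuzzing: every entity present per abstract
# with probability p.
fuzz_corpus <- function(seed, n_abstracts = 30, p = 0.3, ents = fuzz_entities()) {
  set.seed(seed)
  sets <- lapply(seq_len(n_abstracts), function(i) {
    ents$canonical_id[stats::runif(nrow(ents)) < p]
  })
  corpus_from_sets(sets, ents)
}

# ---- independent oracles -------------------------------------------------

# Exhaustive hypergeometric enumeration: all C(N, Z) placements of the
# entity-bearing publications among N, query block = first X.
oracle_hyper <- function(N, X, Z, A, tail = "upper") {
  if (Z == 0) {
    overlap <- 0L
  } else {
    subsets <- utils::combn(N, Z)
    overlap <- colSums(subsets <= X)
  }
  if (tail == "point") mean(overlap == A) else mean(overlap >= A)
}

# Brute-force per-abstract cross-product pair counting.
oracle_pairs <- function(corpus, scope_ids, type_a, type_b) {
  m <- corpus$mentions
  m <- m[m$abstract_id %in% scope_ids, ]
  out <- new.env()
  for (id in unique(m$abstract_id)) {
    sub <- m[m$abstract_id == id, ]
    as <- unique(sub$canonical_id[sub$entity_type == type_a])
    bs <- unique(sub$canonical_id[sub$entity_type == type_b])
    for (a in as) for (b in bs) {
      if (a == b) next
      key <- if (type_a == type_b) {
        paste(min(a, b), max(a, b))
      } else paste(a, b)
      if (type_a == type_b && a > b) next
      cur <- out[[key]]
      out[[key]] <- unique(c(cur, id))
    }
  }
  counts <- vapply(ls(out), function(k) length(out[[k]]), integer(1))
  counts[order(names(counts))]
}

oracle_triads <- function(corpus, scope_ids, types) {
  m <- corpus$mentions
  m <- m[m$abstract_id %in% scope_ids, ]
  out <- new.env()
  for (id in unique(m$abstract_id)) {
    sub <- m[m$abstract_id == id, ]
    as <- unique(sub$canonical_id[sub$entity_type == types[1]])
    bs <- unique(sub$canonical_id[sub$entity_type == types[2]])
    cs <- unique(sub$canonical_id[sub$entity_type == types[3]])
    for (a in as) for (b in bs) for (cc in cs) {
      if (a == b || a == cc || b == cc) next
      key <- paste(a, b, cc)
      out[[key]] <- unique(c(out[[key]], id))
    }
  }
  counts <- vapply(ls(out), function(k) length(out[[k]]), integer(1))
  counts[order(names(counts))]
}

# Hand-rolled BFS over an edge table (frontier expansion, no igraph).
oracle_bfs <- function(edges, seed, levels) {
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    a <- edges$protein_a[[i]]; b <- edges$protein_b[[i]]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  dist <- stats::setNames(0L, seed)
  frontier <- seed
  for (lvl in seq_len(levels)) {
    nxt <- character(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (!w %in% names(dist)) {
          dist[[w]] <- lvl
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# Brute-force dictionary tagger: enumerate every synonym at every position,
# keep word-boundary hits, then resolve leftmost-longest/lexicographic.
oracle_tag <- function(corpus, dictionary) {
  syn <- litnet:::synonym_table(dictionary)
  txt <- abstract_text(corpus)
  is_word <- function(ch) grepl("^[[:alnum:]_]$", ch)
  all_rows <- list()
  for (j in seq_along(txt)) {
    text <- txt[[j]]
    nc <- nchar(text)
    cand <- list()
    for (i in seq_len(nrow(syn))) {
      s <- syn$synonym[[i]]
      ls <- nchar(s)
      if (ls > nc) next
      for (pos in seq_len(nc - ls + 1)) {
        piece <- substr(text, pos, pos + ls - 1)
        hit <- if (syn$case_sensitive[[i]]) piece == s
               else tolower(piece) == tolower(s)
        if (!hit) next
        before <- if (pos == 1) "" else substr(text, pos - 1, pos - 1)
        after <- if (pos + ls - 1 == nc) "" else substr(text, pos + ls, pos + ls)
        if (nzchar(before) && is_word(before)) next
        if (nzchar(after) && is_word(after)) next
        cand[[length(cand) + 1]] <- data.frame(
          start = pos - 1L, end = pos - 1L + ls,
          canonical_id = syn$canonical_id[[i]],
          entity_type = syn$entity_type[[i]], stringsAsFactors = FALSE)
      }
    }
    if (length(cand) == 0) next
    cand <- do.call(rbind, cand)
    keep <- list()
    while (nrow(cand) > 0) {
      best <- cand[cand$start == min(cand$start), , drop = FALSE]
      best <- best[(best$end - best$start) == max(best$end - best$start), ,
                   drop = FALSE]
      best <- best[order(best$canonical_id), , drop = FALSE][1, , drop = FALSE]
      keep[[length(keep) + 1]] <- best
      cand <- cand[cand$start >= best$end, , drop = FALSE]
    }
    keep <- do.call(rbind, keep)
    keep$abstract_id <- names(txt)[[j]]
    all_rows[[length(all_rows) + 1]] <- keep
  }
  if (length(all_rows) == 0) {
    return(data.frame(abstract_id = character(0), canonical_id = character(0),
                      start = integer(0), end = integer(0)))
  }
  out <- do.call(rbind, all_rows)
  out[order(out$abstract_id, out$start), c("abstract_id", "canonical_id",
                                           "start", "end")]
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
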