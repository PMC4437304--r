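#' Annotated abstract corpora
#'
#' An annotated corpus bundles abstract records, entity mentions and the
#' entity occurrence index (canonical id to the set of abstracts mentioning
#' it). The index is always the projection of the mention table and is
#' rebuilt whenever mentions change.
#'
#' Mention spans are 0-based, half-open character offsets into the
#' concatenation `title + " " + body` (a single separator character), so a
#' span round-trips unambiguously through the mention TSV format.
#'
#' @param abstracts Data frame with columns `abstract_id`, `title`, `body`,
#'   `affiliation`, `country`, `year` and a list column `authors` (each a
#'   data frame with `surname`, `initials`).
#' @param mentions Optional mention data frame (see [read_mentions()]).
#' @return An object of class `annotated_corpus` with elements `abstracts`,
#'   `mentions` and `index`.
#' @export
annotated_corpus <- function(abstracts, mentions = NULL) {
  stopifnot(is.data.frame(abstracts))
  need <- c("abstract_id", "title", "body")
  missing <- setdiff(need, names(abstracts))
  if (length(missing) > 0) {
    litnet_stop("abstracts table missing column(s): %s",
                paste(missing, collapse = ", "))
  }
  if (anyDuplicated(abstracts$abstract_id)) {
    dup <- abstracts$abstract_id[duplicated(abstracts$abstract_id)]
    pos <- which(abstracts$abstract_id %in% dup)
    litnet_stop("duplicate abstract_id %s at record(s) %s",
                paste(unique(dup), collapse = ", "),
                paste(pos, collapse = ", "))
  }
  if (!"authors" %in% names(abstracts)) {
    abstracts$authors <- replicate(nrow(abstracts), empty_authors(),
                                   simplify = FALSE)
  }
  for (col in c("affiliation", "country")) {
    if (!col %in% names(abstracts)) abstracts[[col]] <- NA_character_
  }
  if (!"year" %in% names(abstracts)) abstracts$year <- NA_integer_
  yr <- abstracts$year[!is.na(abstracts$year)]
  if (any(yr < 1800)) litnet_stop("year before 1800 in abstracts table")
  if (is.null(mentions)) mentions <- empty_mentions()
  corpus <- structure(list(abstracts = abstracts, mentions = empty_mentions(),
                           index = list()),
                      class = "annotated_corpus")
  if (nrow(mentions) > 0) corpus <- set_mentions(corpus, mentions)
  corpus
}

empty_authors <- function() {
  data.frame(surname = character(0), initials = character(0),
             stringsAsFactors = FALSE)
}

empty_mentions <- function() {
  data.frame(abstract_id = character(0), canonical_id = character(0),
             entity_type = character(0), surface = character(0),
             start = integer(0), end = integer(0), stringsAsFactors = FALSE)
}

#' @export
print.annotated_corpus <- function(x, ...) {
  cat(sprintf("<annotated_corpus> %d abstracts, %d mentions, %d indexed entities\n",
              nrow(x$abstracts), nrow(x$mentions), length(x$index)))
  invisible(x)
}

#' Concatenated searchable text of each abstract
#'
#' `title + " " + body`, the coordinate system of all mention spans.
#'
#' @param corpus An [annotated_corpus()].
#' @return Named character vector (names are abstract ids).
#' @export
abstract_text <- function(corpus) {
  txt <- paste(corpus$abstracts$title, corpus$abstracts$body)
  names(txt) <- corpus$abstracts$abstract_id
  txt
}

#' Rebuild the entity occurrence index from the mention table
#'
#' @param mentions A mention data frame.
#' @return Named list: canonical_id -> sorted unique abstract ids.
#' @export
build_index <- function(mentions) {
  if (nrow(mentions) == 0) return(structure(list(), names = character(0)))
  idx <- lapply(split(mentions$abstract_id, mentions$canonical_id),
                function(ids) sort(unique(ids)))
  idx[order(names(idx))]
}

# Attach mentions, validating spans and referenced abstracts, and rebuild
# the index so the stored index always equals its projection.
set_mentions <- function(corpus, mentions) {
  txt <- abstract_text(corpus)
  unknown <- setdiff(mentions$abstract_id, names(txt))
  if (length(unknown) > 0) {
    litnet_stop("mention references unknown abstract_id: %s",
                paste(unique(unknown), collapse = ", "))
  }
  mentions$start <- as.integer(mentions$start)
  mentions$end <- as.integer(mentions$end)
  len <- nchar(txt)[mentions$abstract_id]
  bad <- which(mentions$start < 0 | mentions$end <= mentions$start |
                 mentions$end > len)
  if (length(bad) > 0) {
    litnet_stop("mention span outside text at row(s) %s",
                paste(bad, collapse = ", "))
  }
  at <- substr(txt[mentions$abstract_id], mentions$start + 1L, mentions$end)
  mism <- which(at != mentions$surface)
  if (length(mism) > 0) {
    litnet_stop("mention surface does not equal text at span at row(s) %s",
                paste(mism, collapse = ", "))
  }
  ord <- order(match(mentions$abstract_id, corpus$abstracts$abstract_id),
               mentions$start, mentions$end, mentions$canonical_id)
  mentions <- mentions[ord, , drop = FALSE]
  rownames(mentions) <- NULL
  corpus$mentions <- mentions
  corpus$index <- build_index(mentions)
  corpus
}

#' Read an abstract corpus
#'
#' Two on-disk formats are supported: `medline` (the flat PubMed export with
#' `PMID`, `TI`, `AB`, `AU`, `AD`, `DP` fields and indented continuation
#' lines) and `jsonl` (one JSON record per line with fields `id`, `title`,
#' `text`, `authors`, `affiliation`, `year`). The country of each record is
#' derived from the last comma-separated token of its first affiliation,
#' normalized against a bundled country-name list; unresolvable affiliations
#' leave the country missing.
#'
#' @param path Input file.
#' @param format `"medline"` or `"jsonl"`.
#' @return An [annotated_corpus()] with no mentions.
#' @export
read_corpus <- function(path, format = c("medline", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) litnet_stop("file not found: %s", path)
  abstracts <- switch(format,
    medline = parse_medline(path),
    jsonl = parse_jsonl(path)
  )
  abstracts$country <- affiliation_country(abstracts$affiliation)
  annotated_corpus(abstracts)
}

parse_medline <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  cur <- NULL
  flush <- function(cur, recs) {
    if (!is.null(cur) && length(cur$fields) > 0) recs[[length(recs) + 1]] <- cur
    recs
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) {
      recs <- flush(cur, recs)
      cur <- NULL
      next
    }
    m <- regmatches(ln, regexec("^([A-Z]{1,4}) *- (.*)$", ln))[[1]]
    if (length(m) == 3) {
      if (is.null(cur)) cur <- list(fields = list())
      tag <- m[[2]]
      cur$fields[[length(cur$fields) + 1]] <- list(tag = tag, value = m[[3]])
    } else if (grepl("^\\s+", ln) && !is.null(cur) && length(cur$fields) > 0) {
      k <- length(cur$fields)
      cur$fields[[k]]$value <- paste(cur$fields[[k]]$value, trimws(ln))
    } else {
      litnet_stop("malformed MEDLINE line (record %d): %s",
                  length(recs) + 1L, ln)
    }
  }
  recs <- flush(cur, recs)
  rows <- lapply(seq_along(recs), function(i) {
    f <- recs[[i]]$fields
    tags <- vapply(f, `[[`, character(1), "tag")
    vals <- vapply(f, `[[`, character(1), "value")
    get1 <- function(tag) {
      v <- vals[tags == tag]
      if (length(v) == 0) NA_character_ else v[[1]]
    }
    pmid <- get1("PMID")
    if (is.na(pmid)) litnet_stop("MEDLINE record %d has no PMID", i)
    au <- vals[tags == "AU"]
    dp <- get1("DP")
    year <- if (!is.na(dp) && grepl("[0-9]{4}", dp)) {
      as.integer(regmatches(dp, regexpr("[0-9]{4}", dp)))
    } else NA_integer_
    list(abstract_id = pmid, title = get1("TI") %||% "",
         body = get1("AB"), affiliation = get1("AD"),
         year = year, authors = parse_author_names(au))
  })
  df <- data.frame(
    abstract_id = vapply(rows, `[[`, character(1), "abstract_id"),
    title = vapply(rows, function(r) r$title %||% NA_character_, character(1)),
    body = vapply(rows, function(r) r$body %||% NA_character_, character(1)),
    affiliation = vapply(rows, function(r) r$affiliation %||% NA_character_,
                         character(1)),
    year = vapply(rows, function(r) r$year %||% NA_integer_, integer(1)),
    stringsAsFactors = FALSE
  )
  df$title[is.na(df$title)] <- ""
  df$body[is.na(df$body)] <- ""
  df$authors <- lapply(rows, `[[`, "authors")
  df
}

# PubMed AU convention: surname(s) then trailing initials token.
parse_author_names <- function(au) {
  if (length(au) == 0) return(empty_authors())
  parts <- strsplit(trimws(au), "\\s+")
  data.frame(
    surname = vapply(parts, function(p) {
      if (length(p) > 1) paste(p[-length(p)], collapse = " ") else p[[1]]
    }, character(1)),
    initials = vapply(parts, function(p) {
      if (length(p) > 1) p[[length(p)]] else ""
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

parse_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) {
                      litnet_stop("malformed JSON at record %d: %s", i,
                                  conditionMessage(e))
                    })
    if (is.null(rec$id)) litnet_stop("record %d missing field 'id'", i)
    authors <- if (length(rec$authors) > 0) {
      data.frame(
        surname = vapply(rec$authors, function(a) a$surname %||% "",
                         character(1)),
        initials = vapply(rec$authors, function(a) a$initials %||% "",
                          character(1)),
        stringsAsFactors = FALSE
      )
    } else empty_authors()
    list(abstract_id = as.character(rec$id),
         title = as.character(rec$title %||% ""),
         body = as.character(rec$text %||% ""),
         affiliation = if (is.null(rec$affiliation)) NA_character_
                       else as.character(rec$affiliation),
         year = if (is.null(rec$year)) NA_integer_ else as.integer(rec$year),
         authors = authors)
  })
  df <- data.frame(
    abstract_id = vapply(rows, `[[`, character(1), "abstract_id"),
    title = vapply(rows, `[[`, character(1), "title"),
    body = vapply(rows, `[[`, character(1), "body"),
    affiliation = vapply(rows, `[[`, character(1), "affiliation"),
    year = vapply(rows, `[[`, integer(1), "year"),
    stringsAsFactors = FALSE
  )
  df$authors <- lapply(rows, `[[`, "authors")
  df
}

#' Write a corpus in the line-delimited JSON record format
#'
#' @param corpus An [annotated_corpus()].
#' @param path Output path.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  ab <- corpus$abstracts
  lines <- vapply(seq_len(nrow(ab)), function(i) {
    au <- ab$authors[[i]]
    rec <- list(id = ab$abstract_id[[i]], title = ab$title[[i]],
                text = ab$body[[i]],
                authors = lapply(seq_len(nrow(au)), function(j) {
                  list(surname = au$surname[[j]], initials = au$initials[[j]])
                }))
    if (!is.na(ab$affiliation[[i]])) rec$affiliation <- ab$affiliation[[i]]
    if (!is.na(ab$year[[i]])) rec$year <- ab$year[[i]]
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

country_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "countries.tsv", package = "litnet")
      df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
      cache <<- structure(df$country, names = tolower(df$variant))
    }
    cache
  }
})

affiliation_country <- function(affiliation) {
  cm <- country_map()
  vapply(affiliation, function(a) {
    if (is.na(a) || !nzchar(a)) return(NA_character_)
    last <- trimws(utils::tail(strsplit(a, ",", fixed = TRUE)[[1]], 1))
    last <- sub("\\.\\s*$", "", last)
    # drop an email address appended after the country
    last <- trimws(sub("\\S+@\\S+", "", last))
    unname(cm[tolower(last)]) %||% NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Read entity mentions from TSV and attach them to a corpus
#'
#' The mention dialect is tab-separated with a required header:
#' `abstract_id  start  end  surface  entity_type  canonical_id`, spans
#' 0-based half-open over `title + " " + body`. Every row is validated
#' against the corpus (known abstract, span inside the text, surface equal
#' to the text at the span) and the occurrence index is rebuilt.
#'
#' @param path Mention TSV.
#' @param corpus An [annotated_corpus()].
#' @return The corpus with mentions attached.
#' @export
read_mentions <- function(path, corpus) {
  df <- read_tsv_file(path, c("abstract_id", "start", "end", "surface",
                              "type", "canonical_id"))
  mentions <- data.frame(abstract_id = df$abstract_id,
                         canonical_id = df$canonical_id,
                         entity_type = df$type,
                         surface = df$surface,
                         start = as.integer(df$start),
                         end = as.integer(df$end),
                         stringsAsFactors = FALSE)
  set_mentions(corpus, mentions)
}

#' Write entity mentions to TSV
#'
#' @param corpus An [annotated_corpus()] (or a mention data frame).
#' @param path Output path.
#' @export
write_mentions <- function(corpus, path) {
  m <- if (inherits(corpus, "annotated_corpus")) corpus$mentions else corpus
  out <- m[c("abstract_id", "start", "end", "surface", "entity_type",
             "canonical_id")]
  names(out)[names(out) == "entity_type"] <- "type"
  write_tsv_file(out, path)
}
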