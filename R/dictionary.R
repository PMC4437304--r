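#' Entity dictionaries
#'
#' An entity dictionary maps canonical identifiers to a bio-entity type
#' (`gene`, `drug`, `disease` or `process`), a preferred name, and a set of
#' synonyms. The preferred name is always part of the synonym set. The
#' dictionary drives [tag_entities()] and the synonym expansion of secondary
#' keywords in [expand_terms()].
#'
#' @param canonical_id Character vector of unique canonical identifiers.
#' @param entity_type Character vector of types, one of `"gene"`, `"drug"`,
#'   `"disease"`, `"process"`.
#' @param preferred_name Character vector of preferred names.
#' @param synonyms List of character vectors of synonyms (the preferred name
#'   is added automatically when absent).
#' @return An object of class `entity_dictionary`: a data frame with columns
#'   `canonical_id`, `entity_type`, `preferred_name` and the list column
#'   `synonyms`.
#' @examples
#' d <- entity_dictionary(
#'   canonical_id = c("HGNC:11998", "MESH:D010190"),
#'   entity_type = c("gene", "drug"),
#'   preferred_name = c("TP53", "paclitaxel"),
#'   synonyms = list(c("TP53", "p53", "tumor protein p53"), "paclitaxel")
#' )
#' @export
entity_dictionary <- function(canonical_id, entity_type, preferred_name,
                              synonyms = NULL) {
  canonical_id <- as.character(canonical_id)
  entity_type <- as.character(entity_type)
  preferred_name <- as.character(preferred_name)
  n <- length(canonical_id)
  if (length(entity_type) != n || length(preferred_name) != n) {
    litnet_stop("canonical_id, entity_type and preferred_name must have equal length")
  }
  if (anyDuplicated(canonical_id)) {
    dup <- unique(canonical_id[duplicated(canonical_id)])
    litnet_stop("duplicate canonical_id: %s", paste(dup, collapse = ", "))
  }
  bad <- setdiff(unique(entity_type), c("gene", "drug", "disease", "process"))
  if (length(bad) > 0) {
    litnet_stop("unknown entity_type: %s", paste(bad, collapse = ", "))
  }
  if (is.null(synonyms)) synonyms <- as.list(preferred_name)
  if (length(synonyms) != n) litnet_stop("synonyms must have one element per entry")
  synonyms <- lapply(seq_len(n), function(i) {
    s <- unique(c(preferred_name[[i]], as.character(synonyms[[i]])))
    if (any(!nzchar(s))) litnet_stop("empty synonym for entity %s", canonical_id[[i]])
    s
  })
  out <- data.frame(canonical_id = canonical_id, entity_type = entity_type,
                    preferred_name = preferred_name, stringsAsFactors = FALSE)
  out$synonyms <- synonyms
  class(out) <- c("entity_dictionary", "data.frame")
  out
}

#' Read an entity dictionary from TSV
#'
#' Expects columns `canonical_id`, `entity_type`, `preferred_name`,
#' `synonyms` (pipe-separated).
#'
#' @param path Path to a tab-separated file.
#' @return An [entity_dictionary()].
#' @export
read_dictionary <- function(path) {
  df <- read_tsv_file(path, c("canonical_id", "entity_type", "preferred_name",
                              "synonyms"))
  syns <- strsplit(df$synonyms, "|", fixed = TRUE)
  entity_dictionary(df$canonical_id, df$entity_type, df$preferred_name, syns)
}

#' Write an entity dictionary to TSV
#'
#' @param dictionary An [entity_dictionary()].
#' @param path Output path.
#' @export
write_dictionary <- function(dictionary, path) {
  df <- data.frame(canonical_id = dictionary$canonical_id,
                   entity_type = dictionary$entity_type,
                   preferred_name = dictionary$preferred_name,
                   synonyms = vapply(dictionary$synonyms, paste,
                                     character(1), collapse = "|"),
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}

# Long synonym table used by the tagger and term expansion:
# one row per (synonym, canonical_id), with the case-sensitivity flag.
# Short all-uppercase synonyms (gene-symbol-like, <= 4 characters with no
# lowercase letters) match case-sensitively so that e.g. the gene "WAS"
# never fires on the English word "was"; everything else matches
# case-insensitively.
synonym_table <- function(dictionary) {
  n_syn <- vapply(dictionary$synonyms, length, integer(1))
  syn <- unlist(dictionary$synonyms, use.names = FALSE)
  out <- data.frame(
    synonym = syn,
    canonical_id = rep(dictionary$canonical_id, n_syn),
    entity_type = rep(dictionary$entity_type, n_syn),
    stringsAsFactors = FALSE
  )
  out$case_sensitive <- nchar(out$synonym) <= 4 &
    !grepl("[a-z]", out$synonym) & grepl("[A-Z]", out$synonym)
  out[!duplicated(out[c("synonym", "canonical_id")]), , drop = FALSE]
}
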