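# Internal helpers shared across modules.

litnet_stop <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
regex_escape <- function(x) {
  gsub("([.|()^$*+?{}\\[\\]\\\\])", "\\\\\\1", x, perl = TRUE)
}

# Word-boundary pattern for a literal term. Multi-word terms match as
# contiguous phrases; internal whitespace matches any run of whitespace.
boundary_pattern <- function(term) {
  esc <- regex_escape(term)
  esc <- gsub("\\s+", "\\\\s+", esc)
  paste0("(?<![[:alnum:]_])", esc, "(?![[:alnum:]_])")
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

read_tsv_file <- function(path, required_cols) {
  if (!file.exists(path)) litnet_stop("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    litnet_stop("file %s is missing required column(s): %s",
                path, paste(missing, collapse = ", "))
  }
  df
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Fixed-format number for deterministic, byte-stable reports.
fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
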