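test_that("the two-tier grammar parses OR, AND and secondary lines", {
  q <- parse_query("Glioblastoma|Glioma|Brain tumor|Brain cancer",
                   "EGFR\nTP53\nErlotinib|Gefitinib")
  expect_length(q$primary, 1)
  expect_equal(q$primary[[1]],
               c("Glioblastoma", "Glioma", "Brain tumor", "Brain cancer"))
  expect_length(q$secondary_groups, 3)
  expect_equal(lengths(q$secondary_groups), c(1L, 1L, 2L))

  q2 <- parse_query("glioma,EGFR|HER2", exclusion_text = "mouse, rat")
  expect_length(q2$primary, 2)
  expect_equal(q2$exclusions, c("mouse", "rat"))
})

test_that("empty terms raise a parse error naming the position", {
  expect_error(parse_query("a,,b"), "primary group 2")
  expect_error(parse_query("a||b"), "position 2")
  expect_error(parse_query(""), "non-empty")
})

test_that("terms expand to full synonym sets; unknown terms pass through", {
  dict <- toy_dictionary()
  expect_setequal(expand_terms("TP53", dict),
                  c("TP53", "p53", "tumor protein p53"))
  expect_setequal(expand_terms("p53", dict),
                  c("TP53", "p53", "tumor protein p53"))
  expect_equal(expand_terms("zzz-not-in-dict", dict), "zzz-not-in-dict")
  amb <- entity_dictionary(c("G:A", "G:B"), c("gene", "gene"),
                           c("alpha", "beta"),
                           list(c("alpha", "shared"), c("beta", "shared")))
  expect_warning(res <- expand_terms("shared", amb), "ambiguous")
  expect_setequal(res, c("alpha", "beta", "shared"))
})

test_that("search requires all AND groups and honors exclusions", {
  corpus <- mini_corpus(c("glioma with EGFR", "lung cancer", "glioma in mouse",
                          "EGFR alone", "glioma and EGFR in mouse"))
  q <- parse_query("glioma")
  expect_equal(search_corpus(corpus, q), c("A1", "A3", "A5"))
  q2 <- parse_query("glioma", exclusion_text = "mouse")
  expect_equal(search_corpus(corpus, q2), "A1")
  q3 <- parse_query("glioma,EGFR")
  expect_equal(search_corpus(corpus, q3),
               intersect(search_corpus(corpus, parse_query("glioma")),
                         search_corpus(corpus, parse_query("EGFR"))))
})

test_that("AND search equals set intersection on fuzzed corpora", {
  for (seed in 1:5) {
    set.seed(seed)
    vocab <- c("alpha", "beta", "gamma", "delta")
    bodies <- vapply(1:30, function(i) {
      paste(sample(vocab, sample(1:4, 1)), collapse = " ")
    }, character(1))
    corpus <- mini_corpus(bodies)
    both <- search_corpus(corpus, parse_query("alpha,beta"))
    expect_setequal(both,
                    intersect(search_corpus(corpus, parse_query("alpha")),
                              search_corpus(corpus, parse_query("beta"))))
    # monotonicity: adding an OR alternative never shrinks the result
    narrow <- search_corpus(corpus, parse_query("alpha"))
    wide <- search_corpus(corpus, parse_query("alpha|gamma"))
    expect_true(all(narrow %in% wide))
  }
})

test_that("combination buckets assign each abstract to its maximal subset", {
  corpus <- mini_corpus(c("EGFR and TP53 here", "only EGFR", "neither term"))
  ids <- corpus$abstracts$abstract_id
  buckets <- combination_buckets(ids, corpus, list("EGFR", "TP53"))
  expect_equal(buckets$key, c("1", "1+2"))
  expect_equal(buckets$abstract_ids[buckets$key == "1+2"][[1]], "A1")
  expect_equal(buckets$abstract_ids[buckets$key == "1"][[1]], "A2")
  # A3 matches no group: in no bucket
  expect_false("A3" %in% unlist(buckets$abstract_ids))
})

test_that("buckets partition the matching set (power-set oracle)", {
  for (seed in 1:5) {
    set.seed(seed)
    vocab <- c("kwone", "kwtwo", "kwthree", "filler", "noise")
    bodies <- vapply(1:40, function(i) {
      paste(sample(vocab, sample(1:5, 1)), collapse = " ")
    }, character(1))
    corpus <- mini_corpus(bodies)
    groups <- list("kwone", "kwtwo", "kwthree")
    ids <- corpus$abstracts$abstract_id
    buckets <- combination_buckets(ids, corpus, groups)
    assigned <- unlist(buckets$abstract_ids)
    expect_equal(anyDuplicated(assigned), 0)   # disjoint
    # oracle: per-abstract direct matching against each group
    txt <- abstract_text(corpus)
    match_any <- vapply(seq_along(txt), function(i) {
      any(vapply(groups, function(g) grepl(g, txt[[i]]), logical(1)))
    }, logical(1))
    expect_setequal(assigned, ids[match_any])  # coverage
    # every bucket key is exactly the matched subset of its members
    for (b in seq_len(nrow(buckets))) {
      want <- as.integer(strsplit(buckets$key[[b]], "+", fixed = TRUE)[[1]])
      for (id in buckets$abstract_ids[[b]]) {
        matched <- which(vapply(groups, function(g) grepl(g, txt[[id]]),
                                logical(1)))
        expect_equal(matched, want)
      }
    }
  }
})
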