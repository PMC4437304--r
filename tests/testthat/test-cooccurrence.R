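test_that("pair extraction counts supporting abstracts exactly", {
  ents <- fuzz_entities(n_gene = 1, n_drug = 1)
  corpus <- corpus_from_sets(list(c("G01", "D01"), c("G01", "D01"), "G01"),
                             ents)
  pairs <- extract_pairs(corpus, NULL, "gene", "drug")
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$count, 2)
  expect_equal(pairs$support_ids[[1]], c("A1", "A2"))
  # no drug mentions at all
  nodrug <- corpus_from_sets(list("G01", "G01"), ents)
  expect_equal(nrow(extract_pairs(nodrug, NULL, "gene", "drug")), 0)
})

test_that("triad extraction yields the type-consistent cross-product", {
  ents <- fuzz_entities(n_gene = 2, n_drug = 1, n_disease = 1)
  corpus <- corpus_from_sets(list(c("G01", "D01", "S01"),
                                  c("G01", "D01", "S01"),
                                  c("G01", "D01")), ents)
  triads <- extract_triads(corpus, NULL, c("gene", "drug", "disease"))
  expect_equal(nrow(triads), 1)
  expect_equal(triads$count, 2)
  # two genes, one drug, one disease in a single abstract -> two triads
  multi <- corpus_from_sets(list(c("G01", "G02", "D01", "S01")), ents)
  t2 <- extract_triads(multi, NULL, c("gene", "drug", "disease"))
  expect_equal(nrow(t2), 2)
  expect_setequal(t2$id_a, c("G01", "G02"))
  # no abstract holds all three types
  partial <- corpus_from_sets(list(c("G01", "D01"), c("G01", "S01")), ents)
  expect_equal(nrow(extract_triads(partial, NULL,
                                   c("gene", "drug", "disease"))), 0)
})

test_that("pair and triad counts equal the cross-product oracle on fuzzed corpora", {
  for (seed in 1:8) {
    corpus <- fuzz_corpus(seed, n_abstracts = 40, p = 0.35)
    scope <- corpus$abstracts$abstract_id
    pairs <- extract_pairs(corpus, scope, "gene", "drug")
    got <- stats::setNames(pairs$count, paste(pairs$id_a, pairs$id_b))
    expect_equal(got[order(names(got))], oracle_pairs(corpus, scope,
                                                      "gene", "drug"))
    gg <- extract_pairs(corpus, scope, "gene", "gene")
    got_gg <- stats::setNames(gg$count, paste(gg$id_a, gg$id_b))
    expect_equal(got_gg[order(names(got_gg))],
                 oracle_pairs(corpus, scope, "gene", "gene"))
    triads <- extract_triads(corpus, scope, c("gene", "drug", "disease"))
    got_t <- stats::setNames(triads$count,
                             paste(triads$id_a, triads$id_b, triads$id_c))
    expect_equal(got_t[order(names(got_t))],
                 oracle_triads(corpus, scope, c("gene", "drug", "disease")))
    # monotonicity: triad <= each pair count <= each singleton count
    for (i in seq_len(nrow(triads))) {
      trio <- c(triads$id_a[[i]], triads$id_b[[i]], triads$id_c[[i]])
      pair_counts <- c(
        length(intersect(corpus$index[[trio[1]]], corpus$index[[trio[2]]])),
        length(intersect(corpus$index[[trio[1]]], corpus$index[[trio[3]]])),
        length(intersect(corpus$index[[trio[2]]], corpus$index[[trio[3]]])))
      singles <- lengths(corpus$index[trio])
      expect_true(triads$count[[i]] <= min(pair_counts))
      expect_true(min(pair_counts) <= min(singles))
    }
  }
})

test_that("pair scoring separates query and global contexts", {
  ents <- fuzz_entities(n_gene = 1, n_drug = 1)
  # independence within the 4-abstract query scope: joint 1, marginals 2, n 4
  sets <- list(c("G01", "D01"), c("G01"), c("D01"), character(0))
  corpus <- corpus_from_sets(sets, ents)
  scope <- corpus$abstracts$abstract_id
  pairs <- score_pairs(extract_pairs(corpus, scope, "gene", "drug"),
                       corpus, scope)
  expect_equal(pairs$mi_query, 0)
  expect_equal(pairs$mi_global, 0)
  # pair absent from a context: NA, not an error
  sub <- score_pairs(extract_pairs(corpus, scope, "gene", "drug"),
                     corpus, query_ids = c("A2", "A3"))
  expect_true(is.na(sub$mi_query))
})

test_that("a pair planted at 8x chance attains mi_query near log2(8)", {
  cfg <- generator_config(seed = 19, n_abstracts = 2000, base_prob = 0.1,
                          planted_associations = list(
                            list(members = c("G001", "D001"), lift = 8)))
  gen <- generate_corpus(cfg)
  scope <- gen$corpus$abstracts$abstract_id
  pairs <- score_pairs(extract_pairs(gen$corpus, scope, "gene", "drug"),
                       gen$corpus, scope)
  planted <- pairs[pairs$id_a == "G001" & pairs$id_b == "D001", ]
  expect_equal(planted$mi_query, 3, tolerance = 0.2)
  expect_equal(which.max(pairs$mi_query),
               which(pairs$id_a == "G001" & pairs$id_b == "D001"))
})

test_that("triad hypergeometric collapses to the enumerated 6-abstract case", {
  ents <- fuzz_entities(n_gene = 2, n_drug = 2, n_disease = 2)
  # members 1&2 co-occur in A1-A3; member 3 exactly there; universe 6
  sets <- list(c("G01", "D01", "S01"), c("G01", "D01", "S01"),
               c("G01", "D01", "S01"), c("G02"), c("D02"), c("S02"))
  corpus <- corpus_from_sets(sets, ents)
  triads <- extract_triads(corpus, NULL, c("gene", "drug", "disease"))
  scored <- score_triads(triads, corpus)
  row <- scored[scored$id_a == "G01" & scored$id_b == "D01" &
                  scored$id_c == "S01", ]
  expect_equal(row$p, 0.05, tolerance = 1e-12)
  expect_equal(row$score, -log2(0.05) / 100, tolerance = 1e-12)
  # symmetric split averages three valid probabilities
  sym <- score_triads(triads, corpus, split = "symmetric")
  expect_true(all(sym$p > 0 & sym$p <= 1))
})

test_that("triad p matches the enumeration oracle at independence-scale counts", {
  ents <- fuzz_entities(n_gene = 2, n_drug = 2, n_disease = 2)
  sets <- list(c("G01", "D01", "S01"), c("G01", "D01"), c("S01", "G02"),
               c("D02", "S01"), c("G01", "S02"), c("D01", "S01"))
  corpus <- corpus_from_sets(sets, ents)
  triads <- extract_triads(corpus, NULL, c("gene", "drug", "disease"))
  scored <- score_triads(triads, corpus)
  row <- scored[scored$id_a == "G01" & scored$id_b == "D01" &
                  scored$id_c == "S01", ]
  # X = |{A1,A2}| = 2, Z = |{A1,A3,A4,A6}| = 4, A = 1, N = 6
  expect_equal(row$p, oracle_hyper(6, 2, 4, 1, "upper"), tolerance = 1e-9)
})

test_that("co-occurrence networks carry counts as weights and triad cliques", {
  ents <- fuzz_entities(n_gene = 2, n_drug = 1, n_disease = 1)
  corpus <- corpus_from_sets(rep(list(c("G01", "D01")), 5), ents)
  pairs <- extract_pairs(corpus, NULL, "gene", "drug")
  g <- cooccurrence_network(pairs = pairs)
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 5)
  tri_corpus <- corpus_from_sets(list(c("G01", "D01", "S01")), ents)
  triads <- extract_triads(tri_corpus, NULL, c("gene", "drug", "disease"))
  gt <- cooccurrence_network(triads = triads)
  expect_equal(igraph::vcount(gt), 3)
  expect_equal(igraph::ecount(gt), 3)
  expect_equal(unique(igraph::E(gt)$triad), "G01|D01|S01")
  # node count equals distinct members across records
  both <- cooccurrence_network(pairs = pairs, triads = triads)
  expect_equal(igraph::vcount(both), 3)
})
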