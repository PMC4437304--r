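test_that("contingency tables are built by direct set counting", {
  ents <- fuzz_entities(n_gene = 3, n_drug = 1)
  # universe = abstracts with >= 1 gene; 6 abstracts all carry some gene
  sets <- list(c("G01", "G02"), c("G01", "G03"), c("G02", "G03"),
               c("G01"), c("G02"), c("G03"))
  corpus <- corpus_from_sets(sets, ents)
  # query covers abstracts 1-3; entity G01 occurs in 1, 2, 4
  tab <- build_contingency(c("A1", "A2", "A3"), "G01", corpus, "gene")
  expect_equal(c(tab$A, tab$B, tab$C, tab$D), c(2, 1, 1, 2))
  expect_equal(c(tab$X, tab$Y, tab$N, tab$Z), c(3, 3, 6, 3))
  # entity only inside the query set: C = 0
  tab2 <- build_contingency(c("A1", "A2", "A3"), "G02",
                            corpus_from_sets(list(c("G01", "G02"),
                                                  c("G02"), c("G02"),
                                                  c("G01"), c("G01")), ents),
                            "gene")
  expect_equal(tab2$C, 0)
  expect_error(build_contingency(c("A1"), "NOPE", corpus, "gene"),
               "not present")
})

test_that("hypergeometric probabilities match enumerated placements", {
  # N=4, X=2, Z=2, A=2: 1 of the C(4,2)=6 placements has full overlap
  expect_equal(hypergeometric_p(contingency_table(2, 0, 0, 2), "upper"),
               1 / 6, tolerance = 1e-12)
  # N=6, X=3, Z=3, A=3: C(3,3)C(3,0)/C(6,3) = 1/20
  expect_equal(hypergeometric_p(contingency_table(3, 0, 0, 3), "upper"),
               0.05, tolerance = 1e-12)
  # A=0 upper tail covers the whole support
  expect_equal(hypergeometric_p(contingency_table(0, 3, 2, 4), "upper"), 1)
})

test_that("log-space tails agree with stats::dhyper/phyper and enumeration", {
  set.seed(3)
  for (i in 1:50) {
    N <- sample(2:11, 1)
    X <- sample(0:N, 1)
    Z <- sample(0:N, 1)
    a_range <- max(0, Z - (N - X)):min(X, Z)
    A <- a_range[[sample.int(length(a_range), 1)]]
    tab <- contingency_table(A, X - A, Z - A, N - X - Z + A)
    p_point <- hypergeometric_p(tab, "point")
    p_upper <- hypergeometric_p(tab, "upper")
    expect_equal(p_point, stats::dhyper(A, X, N - X, Z), tolerance = 1e-12)
    expect_equal(p_upper,
                 stats::phyper(A - 1, X, N - X, Z, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(p_upper, oracle_hyper(N, X, Z, A, "upper"),
                 tolerance = 1e-9)
  }
})

test_that("point masses sum to one and the upper tail is monotone in A", {
  for (params in list(c(9, 4, 5), c(12, 6, 6), c(7, 7, 3))) {
    N <- params[1]; X <- params[2]; Z <- params[3]
    a_range <- max(0, Z - (N - X)):min(X, Z)
    pts <- vapply(a_range, function(a) {
      hypergeometric_p(contingency_table(a, X - a, Z - a, N - X - Z + a),
                       "point")
    }, numeric(1))
    expect_equal(sum(pts), 1, tolerance = 1e-9)
    ups <- vapply(a_range, function(a) {
      hypergeometric_p(contingency_table(a, X - a, Z - a, N - X - Z + a),
                       "upper")
    }, numeric(1))
    expect_true(all(diff(ups) <= 1e-12))
  }
})

test_that("association score is the scaled negative log2 probability", {
  expect_equal(association_score(1)$score, 0)
  expect_equal(association_score(2^-100)$score, 1.0)
  expect_equal(association_score(0.05)$score, -log2(0.05) / 100,
               tolerance = 1e-12)
  expect_error(association_score(0), "probability")
  expect_error(association_score(1.5), "probability")
  # strictly decreasing in p
  ps <- sort(stats::runif(10, 1e-6, 1))
  scores <- vapply(ps, function(p) association_score(p)$score, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("mutual information is zero at independence and symmetric", {
  expect_equal(mutual_information(1, 10, 10, 100)$mi, 0)
  expect_equal(mutual_information(10, 10, 10, 100)$mi, log2(10),
               tolerance = 1e-12)
  expect_error(mutual_information(0, 10, 10, 100), "no co-occurrence")
  set.seed(5)
  for (i in 1:20) {
    n_total <- sample(20:200, 1)
    n_x <- sample(1:n_total, 1)
    n_y <- sample(1:n_total, 1)
    n_xy <- sample(1:min(n_x, n_y), 1)
    expect_equal(mutual_information(n_xy, n_x, n_y, n_total)$mi,
                 mutual_information(n_xy, n_y, n_x, n_total)$mi)
    if (n_xy * n_total == n_x * n_y) {
      expect_equal(mutual_information(n_xy, n_x, n_y, n_total)$mi, 0)
    }
  }
})

test_that("entities are ranked by score with deterministic tie-breaking", {
  ents <- fuzz_entities(n_gene = 3, n_drug = 1)
  # G01 and G02 identical occurrence patterns -> identical scores, id order
  sets <- list(c("G01", "G02"), c("G01", "G02"), c("G03"), c("G03"),
               c("G01", "G02", "G03"))
  corpus <- corpus_from_sets(sets, ents)
  ranked <- rank_entities(corpus, c("A1", "A2"), "gene")
  expect_equal(ranked$canonical_id[1:2], c("G01", "G02"))
  expect_equal(ranked$score[[1]], ranked$score[[2]])
  expect_equal(rank_entities(corpus, character(0), "gene")$rank, integer(0))
})
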