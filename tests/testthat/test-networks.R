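ppi_fixture <- function(rows) {
  write_lines_tmp(c("protein_a\tprotein_b\tconfidence", rows), ".tsv")
}

chain_edges <- function() {
  # a-b high, b-c medium, c-d high
  load_ppi_table(ppi_fixture(c("a\tb\t0.9", "b\tc\t0.5", "c\td\t0.8")))
}

pathway_fixture <- function(rows) {
  load_pathways(write_lines_tmp(c("pathway_id\tname\tmembers\tedges", rows),
                                ".tsv"))
}

test_that("PPI loading filters low-confidence rows and validates scores", {
  expect_message(
    edges <- load_ppi_table(ppi_fixture(c("a\tb\t0.9", "b\tc\t0.5",
                                          "c\td\t0.2", "d\te\t0.75"))),
    "dropped 1")
  expect_equal(nrow(edges), 3)
  expect_equal(edges$confidence_class, c("high", "medium", "high"))
  expect_error(load_ppi_table(ppi_fixture("a\tb\t1.4")), "row 1")
  expect_error(load_ppi_table(ppi_fixture("a\ta\t0.9")), "self-interaction")
})

test_that("pathway loading validates edge endpoints against members", {
  pw <- pathway_fixture("P1\tone\ta|b|c\ta>b,b>c")
  expect_equal(pw$members[[1]], c("a", "b", "c"))
  expect_equal(nrow(pw$edges[[1]]), 2)
  expect_error(pathway_fixture("P1\tone\ta|b\ta>z"), "outside member")
  # membership-only pathways carry no internal edges
  pw2 <- pathway_fixture("P2\ttwo\tx|y\t")
  expect_equal(nrow(pw2$edges[[1]]), 0)
})

test_that("empty localization file yields an empty map and unknown tags", {
  path <- write_lines_tmp("protein\tcompartment", ".tsv")
  loc <- load_localization(path)
  expect_length(loc, 0)
  net <- ppi_neighborhood(chain_edges(), "a", 1)
  net <- tag_compartments(net, loc)
  expect_true(all(vapply(net$nodes$compartments, identical, logical(1),
                         "unknown")))
})

test_that("two-level neighborhoods follow hop distance and confidence class", {
  edges <- chain_edges()
  net <- ppi_neighborhood(edges, "a", levels = 2, min_class = "medium")
  expect_setequal(net$nodes$id, c("a", "b", "c"))
  expect_equal(net$nodes$level[match(c("a", "b", "c"), net$nodes$id)],
               c(0L, 1L, 2L))
  expect_equal(nrow(net$edges), 2)
  high <- ppi_neighborhood(edges, "a", levels = 2, min_class = "high")
  expect_setequal(high$nodes$id, c("a", "b"))
  expect_equal(nrow(high$edges), 1)
  one <- ppi_neighborhood(edges, "a", levels = 1)
  expect_setequal(one$nodes$id, c("a", "b"))
  expect_warning(missing_seed <- ppi_neighborhood(edges, "zz", 2), "absent")
  expect_equal(missing_seed$nodes$id, "zz")
})

test_that("neighborhoods equal a hand-rolled BFS on random graphs", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(20:60, 1)
    prot <- sprintf("p%02d", seq_len(n))
    m <- sample(30:120, 1)
    pairs <- t(replicate(m, sample(prot, 2)))
    df <- data.frame(protein_a = pairs[, 1], protein_b = pairs[, 2],
                     confidence = round(stats::runif(m, 0.4, 1), 3),
                     stringsAsFactors = FALSE)
    df <- df[df$protein_a != df$protein_b, ]
    df$confidence_class <- ifelse(df$confidence >= 0.7, "high", "medium")
    seed_prot <- sample(unique(c(df$protein_a, df$protein_b)), 1)
    for (lv in 1:2) {
      net <- ppi_neighborhood(df, seed_prot, levels = lv)
      want <- oracle_bfs(df, seed_prot, lv)
      expect_setequal(net$nodes$id, names(want))
      expect_equal(net$nodes$level,
                   unname(want[net$nodes$id]))
    }
    # high-class node set is a subset of the medium-class node set
    # the seed may lose all its edges under the high-class filter; the
    # resulting seed-only network (with its warning) is valid here
    hi <- suppressWarnings(
      ppi_neighborhood(df[df$confidence_class == "high", ], seed_prot, 2))
    med <- ppi_neighborhood(df, seed_prot, 2)
    expect_true(all(hi$nodes$id %in% c(med$nodes$id, seed_prot)))
  }
})

test_that("pathway overlay adds members, directed edges and memberships", {
  edges <- chain_edges()
  net <- ppi_neighborhood(edges, "a", 1)           # nodes a, b
  pw <- pathway_fixture(c("P1\tone\tb|c\tb>c", "P2\ttwo\tx|y\tx>y"))
  over <- overlay_pathways(net, pw)
  expect_setequal(over$nodes$id, c("a", "b", "c")) # P2 disjoint: not added
  expect_equal(over$nodes$pathway_ids[[match("b", over$nodes$id)]], "P1")
  expect_equal(sum(over$edges$kind == "pathway-directed"), 1)
  # ppi edge and pathway edge over the same pair coexist
  pw_same <- pathway_fixture("P3\tthree\ta|b\ta>b")
  both <- overlay_pathways(ppi_neighborhood(edges, "a", 1), pw_same)
  ab <- both$edges[(both$edges$from == "a" & both$edges$to == "b"), ]
  expect_setequal(ab$kind, c("ppi-undirected", "pathway-directed"))
})

test_that("merging respects the five-protein limit and keeps minimum levels", {
  edges <- chain_edges()
  expect_error(merge_proteins(letters[1:6], edges), "maximum 5")
  # disjoint seeds give a disjoint union
  iso <- load_ppi_table(ppi_fixture(c("a\tb\t0.9", "x\ty\t0.8")))
  net <- merge_proteins(c("a", "x"), iso)
  expect_setequal(net$nodes$id, c("a", "b", "x", "y"))
  # shared neighbor keeps the minimum hop distance over seeds
  net2 <- merge_proteins(c("a", "c"), edges)
  expect_equal(net2$nodes$level[[match("b", net2$nodes$id)]], 1L)
  expect_equal(net2$nodes$level[[match("d", net2$nodes$id)]], 1L)
  # single-seed merge equals neighborhood + overlay composition
  pw <- pathway_fixture("P1\tone\tb|c\tb>c")
  merged <- merge_proteins("a", edges, pw)
  composed <- overlay_pathways(ppi_neighborhood(edges, "a", 2), pw)
  expect_setequal(merged$nodes$id, composed$nodes$id)
  expect_equal(nrow(merged$edges), nrow(composed$edges))
})

test_that("crosstalk reports proteins in two or more pathways, sorted", {
  pw <- pathway_fixture(c("P1\tone\ta|b|c\t", "P2\ttwo\tb|c|d\t",
                          "P3\tthree\tc\t"))
  ct <- crosstalk(pw)
  expect_equal(ct$protein, c("c", "b"))
  expect_equal(ct$n_pathways, c(3L, 2L))
  expect_equal(ct$pathway_ids[[1]], c("P1", "P2", "P3"))
  # disjoint pathways or a single pathway yield nothing
  expect_equal(nrow(crosstalk(pathway_fixture(c("P1\tone\ta|b\t",
                                                "P2\ttwo\tc|d\t")))), 0)
  expect_equal(nrow(crosstalk(pathway_fixture("P1\tone\ta|b\t"))), 0)
  # fuzzed membership counting with total-count conservation
  for (seed in 1:5) {
    set.seed(seed)
    prot <- sprintf("q%02d", 1:15)
    rows <- vapply(1:6, function(i) {
      sprintf("PW%d\tpw%d\t%s\t", i, i,
              paste(sample(prot, sample(3:8, 1)), collapse = "|"))
    }, character(1))
    pws <- pathway_fixture(rows)
    ct <- crosstalk(pws)
    member_counts <- table(unlist(lapply(pws$members, unique)))
    want <- member_counts[member_counts >= 2]
    expect_setequal(ct$protein, names(want))
    expect_equal(sum(ct$n_pathways), sum(want))
  }
})

test_that("expression overlay computes log2 fold-changes and directions", {
  edges <- chain_edges()
  net <- ppi_neighborhood(edges, "a", 2)
  expr <- data.frame(gene = rep(c("a", "b"), each = 4),
                     condition = rep(c("ctl", "ctl", "trt", "trt"), 2),
                     replicate = rep(1:2, 4),
                     value = c(2, 2, 8, 8, 5, 5, 5, 5),
                     stringsAsFactors = FALSE)
  out <- overlay_expression(net, expr, "ctl", "trt", lfc_threshold = 1)
  expect_equal(out$nodes$expr_value[[match("a", out$nodes$id)]], 2)
  expect_equal(out$nodes$expr_direction[[match("a", out$nodes$id)]], "up")
  expect_equal(out$nodes$expr_value[[match("b", out$nodes$id)]], 0)
  expect_equal(out$nodes$expr_direction[[match("b", out$nodes$id)]],
               "unchanged")
  expect_true(is.na(out$nodes$expr_value[[match("c", out$nodes$id)]]))
  bad <- expr; bad$value[[1]] <- 0
  expect_error(overlay_expression(net, bad, "ctl", "trt"), "non-positive")
  expect_error(overlay_expression(net, expr, "ctl", "nope"), "absent")
})

test_that("networks round-trip losslessly through the JSON export", {
  edges <- chain_edges()
  pw <- pathway_fixture("P1\tone\tb|c\tb>c")
  loc <- list(a = c("nucleus", "cytoplasm"), b = "membrane")
  net <- tag_compartments(overlay_pathways(ppi_neighborhood(edges, "a", 2),
                                           pw), loc)
  path <- tempfile(fileext = ".json")
  export_network(net, path, "json")
  back <- read_network_json(path)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
  # empty network: valid documents in every format
  empty <- meta_network()
  for (fmt in c("json", "sif", "graphml")) {
    f <- tempfile()
    expect_silent(export_network(empty, f, fmt))
    expect_true(file.exists(f))
  }
})

test_that("SIF and GraphML exports carry relations and attributes", {
  edges <- chain_edges()
  pw <- pathway_fixture("P1\tone\tb|c\tb>c")
  net <- overlay_pathways(ppi_neighborhood(edges, "a", 2), pw)
  sif <- tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  lines <- readLines(sif)
  expect_length(lines, nrow(net$edges))
  expect_true(any(grepl("\tppi\t", lines)))
  expect_true(any(grepl("\tpathway:P1\t", lines)))
  gml <- tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(g)$name, net$nodes$id)
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_setequal(igraph::E(g)$kind, unique(net$edges$kind))
  expect_error(export_network(net, tempfile(), "bogus"))
})
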