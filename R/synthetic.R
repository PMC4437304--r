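#' Configuration for the synthetic study generator
#'
#' The generator emulates the full input surface of the package — an
#' abstract corpus with planted entity associations, an entity dictionary,
#' a PPI table, pathway definitions, a localization map and an expression
#' table — with parameterized, fully deterministic structure, so every
#' analysis module can be exercised end-to-end without any downloads.
#'
#' Entity presence per abstract is Bernoulli (set semantics, matching the
#' presence-based occurrence index). A planted association of `k` members
#' with lift `L >= 1` is realized by a mixture: with probability `q` all
#' members are forced co-present, otherwise members are drawn independently
#' at reduced rates, with `q` solved so that each member keeps its marginal
#' probability and the joint probability equals `L` times the product of
#' the marginals. The pseudo-member `"QUERY"` stands for the query keyword
#' itself (a plain text token, not a dictionary entity), which lets an
#' association between the query topic and an entity be planted.
#'
#' @param seed Integer seed; the same config and seed give byte-identical
#'   outputs.
#' @param n_abstracts Number of abstracts.
#' @param n_genes,n_drugs,n_diseases,n_processes Entities per type.
#' @param base_prob Per-abstract presence probability of each entity.
#' @param query_term Text token planted as the query topic.
#' @param query_prob Presence probability of the query token.
#' @param planted_associations List of `list(members=, lift=)`; members are
#'   canonical ids or `"QUERY"`, member sets must be disjoint across
#'   plants, lift must be >= 1.
#' @param author_pool,max_authors Author pool size and the maximum authors
#'   per paper.
#' @param countries Character vector the affiliations draw from (`NA`
#'   entries produce papers with no affiliation).
#' @param n_proteins,n_ppi_edges Random PPI graph size.
#' @param n_pathways,pathway_size Pathway collection shape.
#' @param planted_crosstalk List of `list(protein=, n_pathways=)`; each
#'   protein is placed in exactly that many pathways.
#' @param planted_chain Protein ids forced into a high-confidence 2-hop
#'   chain (seed, middle, end).
#' @param planted_lfc List of `list(gene=, lfc=)` noiseless log2
#'   fold-changes planted into the expression table.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_abstracts = 2000L,
                             n_genes = 30L, n_drugs = 12L,
                             n_diseases = 8L, n_processes = 6L,
                             base_prob = 0.08,
                             query_term = "querytopic",
                             query_prob = 0.09,
                             planted_associations = list(
                               list(members = c("QUERY", "G001"), lift = 10),
                               list(members = c("G003", "D002"), lift = 10),
                               list(members = c("G002", "D001", "S001"),
                                    lift = 6)),
                             author_pool = 40L, max_authors = 6L,
                             countries = c("India", "United States",
                                           "Germany", "Japan", NA),
                             n_proteins = 40L, n_ppi_edges = 120L,
                             n_pathways = 8L, pathway_size = 8L,
                             planted_crosstalk = list(
                               list(protein = "PR01", n_pathways = 5L)),
                             planted_chain = c("PR01", "PR02", "PR03"),
                             planted_lfc = list(
                               list(gene = "PR05", lfc = 2))) {
  cfg <- list(seed = as.integer(seed), n_abstracts = as.integer(n_abstracts),
              n_genes = as.integer(n_genes), n_drugs = as.integer(n_drugs),
              n_diseases = as.integer(n_diseases),
              n_processes = as.integer(n_processes),
              base_prob = base_prob, query_term = query_term,
              query_prob = query_prob,
              planted_associations = planted_associations,
              author_pool = as.integer(author_pool),
              max_authors = as.integer(max_authors), countries = countries,
              n_proteins = as.integer(n_proteins),
              n_ppi_edges = as.integer(n_ppi_edges),
              n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size),
              planted_crosstalk = planted_crosstalk,
              planted_chain = planted_chain, planted_lfc = planted_lfc)
  if (cfg$base_prob < 0 || cfg$base_prob > 1 ||
        cfg$query_prob < 0 || cfg$query_prob > 1) {
    litnet_stop("probabilities must lie in [0, 1]")
  }
  planted_members <- unlist(lapply(planted_associations, `[[`, "members"))
  if (anyDuplicated(planted_members)) {
    litnet_stop("planted association member sets must be disjoint")
  }
  structure(cfg, class = "generator_config")
}

synthetic_entities <- function(cfg) {
  mk <- function(prefix, tok, n, type) {
    if (n == 0) return(NULL)
    data.frame(canonical_id = sprintf("%s%03d", prefix, seq_len(n)),
               entity_type = type,
               token = sprintf("%s%03d", tok, seq_len(n)),
               stringsAsFactors = FALSE)
  }
  rbind(mk("G", "genet", cfg$n_genes, "gene"),
        mk("D", "drugt", cfg$n_drugs, "drug"),
        mk("S", "dist", cfg$n_diseases, "disease"),
        mk("P", "proct", cfg$n_processes, "process"))
}

# Mixture weight q for a planted tuple: with probability q all members are
# co-present; otherwise members are independent at rate (p_i - q)/(1 - q),
# which preserves each marginal p_i. q is solved so the joint equals the
# target.
solve_plant_q <- function(p, target) {
  if (target > min(p)) {
    litnet_stop("infeasible joint probability %.4f exceeds a marginal (%.4f)",
                target, min(p))
  }
  f <- function(q) q + (1 - q) * prod((p - q) / (1 - q)) - target
  if (target <= prod(p)) {
    if (abs(target - prod(p)) < 1e-12) return(0)
    litnet_stop("planted lifts below 1 are not supported")
  }
  stats::uniroot(f, c(0, min(p)), tol = 1e-12)$root
}

#' Generate a synthetic annotated corpus and its dictionary
#'
#' Each abstract's entity presence is drawn per entity at its base
#' probability, except planted tuples which are drawn through the mixture
#' described in [generator_config()]. Every present entity's preferred
#' token is written into the abstract body (plus the query token when the
#' query pseudo-member is present), so [tag_entities()] rediscovers the
#' gold mentions exactly. Authors, affiliations and countries are sampled
#' from the configured pools.
#'
#' @param config A [generator_config()].
#' @return List with elements `corpus` (an [annotated_corpus()] carrying
#'   the gold mentions), `dictionary`, `query_term` and `truth` (planted
#'   structure: per-plant mixture weights and target joint probabilities,
#'   and the per-abstract query-token presence).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  ent <- synthetic_entities(config)
  with_seed(config$seed, {
    units <- c(ent$canonical_id, "QUERY")
    probs <- c(rep(config$base_prob, nrow(ent)), config$query_prob)
    names(probs) <- units
    plants <- lapply(config$planted_associations, function(pl) {
      members <- pl$members
      missing <- setdiff(members, units)
      if (length(missing) > 0) {
        litnet_stop("planted member(s) unknown: %s",
                    paste(missing, collapse = ", "))
      }
      if (pl$lift < 1) litnet_stop("planted lifts below 1 are not supported")
      p <- probs[members]
      target <- pl$lift * prod(p)
      q <- solve_plant_q(p, target)
      list(members = members, lift = pl$lift, target = target, q = q,
           rate = (p - q) / (1 - q))
    })
    planted_units <- unlist(lapply(plants, `[[`, "members"))
    free_units <- setdiff(units, planted_units)

    n <- config$n_abstracts
    present <- matrix(FALSE, nrow = n, ncol = length(units),
                      dimnames = list(NULL, units))
    for (u in free_units) present[, u] <- stats::runif(n) < probs[[u]]
    for (pl in plants) {
      force_all <- stats::runif(n) < pl$q
      for (m in pl$members) {
        indep <- stats::runif(n) < pl$rate[[m]]
        present[, m] <- force_all | (!force_all & indep)
      }
    }

    pool <- data.frame(
      surname = sprintf("Author%02d", seq_len(config$author_pool)),
      initials = paste0(sample(LETTERS, config$author_pool, replace = TRUE),
                        sample(LETTERS, config$author_pool, replace = TRUE)),
      stringsAsFactors = FALSE)
    n_auth <- sample.int(config$max_authors, n, replace = TRUE)
    country_pick <- sample(seq_along(config$countries), n, replace = TRUE)

    ids <- sprintf("SYN%05d", seq_len(n))
    titles <- sprintf("Synthetic record %05d", seq_len(n))
    tokens_by_unit <- c(ent$token, config$query_term)
    names(tokens_by_unit) <- units
    bodies <- vapply(seq_len(n), function(i) {
      toks <- tokens_by_unit[present[i, ]]
      if (length(toks) == 0) {
        "An observational note without tagged terms."
      } else {
        sprintf("This study examines %s in a controlled setting.",
                paste(toks, collapse = " and "))
      }
    }, character(1))
    affil <- vapply(seq_len(n), function(i) {
      ctry <- config$countries[[country_pick[[i]]]]
      if (is.na(ctry)) NA_character_
      else sprintf("Unit %d, Institute of Systems Biology, %s.",
                   1L + (i %% 7L), ctry)
    }, character(1))
    authors <- lapply(seq_len(n), function(i) {
      idx <- sample.int(config$author_pool, n_auth[[i]])
      pool[idx, , drop = FALSE]
    })
    abstracts <- data.frame(abstract_id = ids, title = titles, body = bodies,
                            affiliation = affil,
                            year = 1990L + (seq_len(n) %% 30L),
                            stringsAsFactors = FALSE)
    abstracts$authors <- authors
    abstracts$country <- affiliation_country(affil)

    texts <- paste(titles, bodies)
    mention_rows <- lapply(seq_len(n), function(i) {
      here <- ent$canonical_id[present[i, ent$canonical_id]]
      if (length(here) == 0) return(NULL)
      toks <- tokens_by_unit[here]
      pos <- vapply(toks, function(tk) {
        as.integer(regexpr(tk, texts[[i]], fixed = TRUE))
      }, integer(1))
      data.frame(abstract_id = ids[[i]], canonical_id = here,
                 entity_type = ent$entity_type[match(here, ent$canonical_id)],
                 surface = unname(toks), start = pos - 1L,
                 end = pos - 1L + nchar(toks), stringsAsFactors = FALSE)
    })
    mentions <- do.call(rbind, mention_rows)
    if (is.null(mentions)) mentions <- empty_mentions()
    corpus <- annotated_corpus(abstracts, mentions)

    dictionary <- entity_dictionary(
      ent$canonical_id, ent$entity_type, ent$token,
      synonyms = lapply(ent$token, function(tk) c(tk, paste0(tk, "alt"))))

    list(corpus = corpus, dictionary = dictionary,
         query_term = config$query_term,
         truth = list(plants = plants,
                      query_present = unname(present[, "QUERY"])))
  })
}

#' Generate synthetic network-side inputs
#'
#' Writes the PPI, pathway, localization and expression TSVs consumed by
#' [load_ppi_table()] and friends into `dir`. The PPI graph is a random
#' graph with the configured edge count and uniform confidences on
#' `[0.4, 1]` (both confidence classes populated); the configured chain is
#' forced in at high confidence so a 2-hop neighborhood from its first
#' protein reaches its end. Planted crosstalk proteins are placed in
#' exactly their configured number of pathways; planted expression genes
#' get a noiseless log2 fold-change.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if needed).
#' @return List with `paths` (named file paths) and `truth` (planted
#'   crosstalk, chain and fold-changes).
#' @export
generate_networks <- function(config, dir = tempfile("litnet-net-")) {
  stopifnot(inherits(config, "generator_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pc in config$planted_crosstalk) {
    if (pc$n_pathways > config$n_pathways) {
      litnet_stop("planted crosstalk for %s needs %d pathways but only %d exist",
                  pc$protein, pc$n_pathways, config$n_pathways)
    }
  }
  with_seed(config$seed + 1L, {
    proteins <- sprintf("PR%02d", seq_len(config$n_proteins))
    all_pairs <- utils::combn(proteins, 2)
    chain <- config$planted_chain
    chain_edges <- if (length(chain) >= 2) {
      cbind(chain[-length(chain)], chain[-1])
    } else matrix(character(0), ncol = 2)
    pick <- sample.int(ncol(all_pairs), config$n_ppi_edges)
    ppi <- data.frame(protein_a = all_pairs[1, pick],
                      protein_b = all_pairs[2, pick],
                      confidence = round(stats::runif(length(pick), 0.4, 1), 3),
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(chain_edges))) {
      dup <- (ppi$protein_a == chain_edges[i, 1] &
                ppi$protein_b == chain_edges[i, 2]) |
             (ppi$protein_a == chain_edges[i, 2] &
                ppi$protein_b == chain_edges[i, 1])
      ppi <- ppi[!dup, , drop = FALSE]
      ppi <- rbind(ppi, data.frame(protein_a = chain_edges[i, 1],
                                   protein_b = chain_edges[i, 2],
                                   confidence = 0.9,
                                   stringsAsFactors = FALSE))
    }
    # make sure both confidence classes are populated
    ppi$confidence[[1]] <- max(ppi$confidence[[1]], 0.95)
    ppi$confidence[[2]] <- min(max(ppi$confidence[[2]], 0.4), 0.55)

    planted_prot <- vapply(config$planted_crosstalk, `[[`, character(1),
                           "protein")
    free_prot <- setdiff(proteins, planted_prot)
    pathways <- lapply(seq_len(config$n_pathways), function(i) {
      sort(sample(free_prot, min(config$pathway_size, length(free_prot))))
    })
    for (pc in config$planted_crosstalk) {
      for (i in seq_len(pc$n_pathways)) {
        pathways[[i]] <- sort(unique(c(pathways[[i]], pc$protein)))
      }
    }
    pw_edges <- vapply(pathways, function(m) {
      if (length(m) < 3) return("")
      paste(sprintf("%s>%s", m[1:2], m[2:3]), collapse = ",")
    }, character(1))
    pw_df <- data.frame(pathway_id = sprintf("PW%02d",
                                             seq_len(config$n_pathways)),
                        name = sprintf("Synthetic pathway %02d",
                                       seq_len(config$n_pathways)),
                        members = vapply(pathways, paste, character(1),
                                         collapse = "|"),
                        edges = pw_edges, stringsAsFactors = FALSE)

    compartments <- c("nucleus", "cytoplasm", "membrane", "mitochondrion",
                      "extracellular")
    n_loc <- max(config$n_proteins - 3L, 0L)
    loc_df <- data.frame(protein = proteins[seq_len(n_loc)],
                         compartment = sample(compartments, n_loc,
                                              replace = TRUE),
                         stringsAsFactors = FALSE)

    planted_lfc_genes <- vapply(config$planted_lfc, `[[`, character(1),
                                "gene")
    base_expr <- stats::runif(config$n_proteins, 5, 50)
    expr_rows <- list()
    for (i in seq_along(proteins)) {
      g <- proteins[[i]]
      pl <- Filter(function(x) x$gene == g, config$planted_lfc)
      for (rep_i in 1:3) {
        a_val <- if (length(pl) > 0) base_expr[[i]]
                 else base_expr[[i]] * 2^stats::rnorm(1, 0, 0.1)
        b_val <- if (length(pl) > 0) base_expr[[i]] * 2^pl[[1]]$lfc
                 else base_expr[[i]] * 2^stats::rnorm(1, 0, 0.1)
        expr_rows[[length(expr_rows) + 1]] <- data.frame(
          gene = g, condition = c("control", "treated"),
          replicate = rep_i, value = round(c(a_val, b_val), 6),
          stringsAsFactors = FALSE)
      }
    }
    expr_df <- do.call(rbind, expr_rows)

    paths <- list(ppi = file.path(dir, "ppi.tsv"),
                  pathways = file.path(dir, "pathways.tsv"),
                  localization = file.path(dir, "localization.tsv"),
                  expression = file.path(dir, "expression.tsv"))
    write_tsv_file(ppi, paths$ppi)
    write_tsv_file(pw_df, paths$pathways)
    write_tsv_file(loc_df, paths$localization)
    write_tsv_file(expr_df, paths$expression)
    list(paths = paths,
         truth = list(planted_crosstalk = config$planted_crosstalk,
                      planted_chain = chain,
                      planted_lfc = config$planted_lfc))
  })
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits the corpus (JSONL), gold mentions (TSV), dictionary (TSV) and the
#' four network-side TSVs into one directory — exactly the dialects the
#' reader modules consume.
#'
#' @param config A [generator_config()].
#' @param dir Output directory.
#' @return Named list of all file paths plus the generation `truth`.
#' @export
simulate_bundle <- function(config, dir = tempfile("litnet-bundle-")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_corpus(config)
  nets <- generate_networks(config, dir)
  paths <- list(corpus = file.path(dir, "corpus.jsonl"),
                mentions = file.path(dir, "mentions.tsv"),
                dictionary = file.path(dir, "dictionary.tsv"))
  write_corpus_jsonl(gen$corpus, paths$corpus)
  write_mentions(gen$corpus, paths$mentions)
  write_dictionary(gen$dictionary, paths$dictionary)
  c(paths, nets$paths,
    list(query_term = gen$query_term,
         truth = c(gen$truth, nets$truth)))
}
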