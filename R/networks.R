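#' Meta-interaction networks
#'
#' A meta-network mixes undirected protein-protein interaction (PPI) edges
#' with directed pathway edges over a shared, annotated protein node set.
#' Node annotations: subcellular `compartments`, `pathway_ids`, an optional
#' expression overlay (`expr_value`, `expr_direction`) and `level`, the hop
#' distance from the seed protein (NA for nodes added by a pathway
#' overlay). A PPI edge and a pathway edge between the same protein pair
#' coexist as distinct edge records.
#'
#' @param nodes Data frame with column `id` (and optionally `level`).
#' @param edges Data frame with columns `from`, `to`, `kind` and the
#'   kind-specific attributes `confidence`, `confidence_class`,
#'   `pathway_id`.
#' @return An object of class `meta_network`.
#' @export
meta_network <- function(nodes = NULL, edges = NULL) {
  if (is.null(nodes)) {
    nodes <- data.frame(id = character(0), stringsAsFactors = FALSE)
  }
  if (!"level" %in% names(nodes)) {
    nodes$level <- rep(NA_integer_, nrow(nodes))
  }
  if (!"compartments" %in% names(nodes)) {
    nodes$compartments <- replicate(nrow(nodes), character(0), simplify = FALSE)
  }
  if (!"pathway_ids" %in% names(nodes)) {
    nodes$pathway_ids <- replicate(nrow(nodes), character(0), simplify = FALSE)
  }
  if (!"expr_value" %in% names(nodes)) {
    nodes$expr_value <- rep(NA_real_, nrow(nodes))
  }
  if (!"expr_direction" %in% names(nodes)) {
    nodes$expr_direction <- rep(NA_character_, nrow(nodes))
  }
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        kind = character(0), stringsAsFactors = FALSE)
  }
  if (!"confidence" %in% names(edges)) {
    edges$confidence <- rep(NA_real_, nrow(edges))
  }
  for (col in c("confidence_class", "pathway_id")) {
    if (!col %in% names(edges)) edges[[col]] <- rep(NA_character_, nrow(edges))
  }
  bad <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(bad) > 0) {
    litnet_stop("edge endpoint(s) not in node set: %s",
                paste(unique(bad), collapse = ", "))
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "meta_network")
}

#' @export
print.meta_network <- function(x, ...) {
  cat(sprintf("<meta_network> %d nodes, %d edges (%d ppi, %d pathway)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$kind == "ppi-undirected"),
              sum(x$edges$kind == "pathway-directed")))
  invisible(x)
}

confidence_class <- function(confidence) {
  ifelse(confidence >= 0.7, "high", "medium")
}

#' Load a PPI edge table
#'
#' TSV with header `protein_a`, `protein_b`, `confidence` (STRING-style
#' score scaled to `[0, 1]`). Edges are stratified into the high
#' (`confidence >= 0.7`) and medium (`0.4 <= confidence < 0.7`) classes;
#' rows below 0.4 are dropped (a message reports the count) and never
#' stored.
#'
#' @param path TSV path.
#' @return Data frame of edges with `confidence_class` attached.
#' @export
load_ppi_table <- function(path) {
  df <- read_tsv_file(path, c("protein_a", "protein_b", "confidence"))
  conf <- suppressWarnings(as.numeric(df$confidence))
  bad <- which(is.na(conf) | conf < 0 | conf > 1)
  if (length(bad) > 0) {
    litnet_stop("confidence outside [0, 1] at row %d of %s", bad[[1]], path)
  }
  self <- which(df$protein_a == df$protein_b)
  if (length(self) > 0) {
    litnet_stop("self-interaction at row %d of %s", self[[1]], path)
  }
  keep <- conf >= 0.4
  if (any(!keep)) {
    message(sprintf("load_ppi_table: dropped %d edge(s) below confidence 0.4",
                    sum(!keep)))
  }
  out <- data.frame(protein_a = df$protein_a[keep],
                    protein_b = df$protein_b[keep],
                    confidence = conf[keep], stringsAsFactors = FALSE)
  out$confidence_class <- confidence_class(out$confidence)
  out
}

#' Load pathway definitions
#'
#' TSV with header `pathway_id`, `name`, `members` (pipe-separated protein
#' ids) and optional `edges` (comma-separated `source>target` pairs, both
#' endpoints must be members). Pathways supplied without internal edges are
#' treated as membership-only.
#'
#' @param path TSV path.
#' @return Data frame with list columns `members` and `edges` (each edge
#'   table has columns `from`, `to`).
#' @export
load_pathways <- function(path) {
  df <- read_tsv_file(path, c("pathway_id", "name", "members"))
  members <- strsplit(df$members, "|", fixed = TRUE)
  if (any(lengths(members) == 0)) {
    litnet_stop("pathway with empty member set at row %d",
                which(lengths(members) == 0)[[1]])
  }
  edges <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    spec <- if ("edges" %in% names(df)) df$edges[[i]] else ""
    if (is.na(spec) || !nzchar(spec)) {
      edges[[i]] <- data.frame(from = character(0), to = character(0),
                               stringsAsFactors = FALSE)
      next
    }
    pairs <- strsplit(strsplit(spec, ",", fixed = TRUE)[[1]], ">", fixed = TRUE)
    if (any(lengths(pairs) != 2)) {
      litnet_stop("malformed pathway edge spec at row %d: %s", i, spec)
    }
    e <- data.frame(from = vapply(pairs, `[[`, character(1), 1),
                    to = vapply(pairs, `[[`, character(1), 2),
                    stringsAsFactors = FALSE)
    outside <- setdiff(c(e$from, e$to), members[[i]])
    if (length(outside) > 0) {
      litnet_stop("pathway %s edge endpoint(s) outside member set: %s",
                  df$pathway_id[[i]], paste(outside, collapse = ", "))
    }
    edges[[i]] <- e
  }
  out <- df[c("pathway_id", "name")]
  out$members <- members
  out$edges <- edges
  out
}

#' Load a protein-to-compartment localization map
#'
#' TSV with header `protein`, `compartment`; a protein may appear on several
#' rows (multiple compartments).
#'
#' @param path TSV path.
#' @return Named list: protein -> character vector of compartments.
#' @export
load_localization <- function(path) {
  df <- read_tsv_file(path, c("protein", "compartment"))
  if (nrow(df) == 0) return(structure(list(), names = character(0)))
  lapply(split(df$compartment, df$protein), function(x) sort(unique(x)))
}

#' Load an expression table
#'
#' TSV with header `gene`, `condition`, `replicate`, `value`.
#'
#' @param path TSV path.
#' @return Data frame with numeric `value`.
#' @export
load_expression <- function(path) {
  df <- read_tsv_file(path, c("gene", "condition", "replicate", "value"))
  df$value <- suppressWarnings(as.numeric(df$value))
  if (anyNA(df$value)) {
    litnet_stop("non-numeric expression value at row %d",
                which(is.na(df$value))[[1]])
  }
  df
}

#' Breadth-first PPI neighborhood of a seed protein
#'
#' Collects every protein within `levels` hops of the seed through edges of
#' the requested confidence class or better (`min_class = "medium"` uses
#' both classes; `"high"` uses only high-confidence edges), then keeps all
#' qualifying edges among the included proteins. `level` records the hop
#' distance; two levels means direct interactors plus interactors of
#' interactors.
#'
#' @param edges PPI edge table from [load_ppi_table()].
#' @param seed Seed protein id.
#' @param levels 1 or 2.
#' @param min_class `"medium"` or `"high"`.
#' @return A [meta_network()] with PPI edges only.
#' @export
ppi_neighborhood <- function(edges, seed, levels = 2,
                             min_class = c("medium", "high")) {
  min_class <- match.arg(min_class)
  if (!levels %in% c(1, 2)) litnet_stop("levels must be 1 or 2")
  if (min_class == "high") {
    edges <- edges[edges$confidence_class == "high", , drop = FALSE]
  }
  verts <- unique(c(edges$protein_a, edges$protein_b))
  if (!seed %in% verts) {
    warning(sprintf("seed '%s' absent from the PPI table", seed),
            call. = FALSE)
    return(meta_network(
      nodes = data.frame(id = seed, level = 0L, stringsAsFactors = FALSE)))
  }
  g <- igraph::graph_from_data_frame(
    edges[c("protein_a", "protein_b")], directed = FALSE,
    vertices = data.frame(id = verts))
  d <- igraph::distances(g, v = seed)[1, ]
  keep <- names(d)[is.finite(d) & d <= levels]
  lev <- as.integer(d[keep])
  sel <- edges$protein_a %in% keep & edges$protein_b %in% keep
  e <- edges[sel, , drop = FALSE]
  meta_network(
    nodes = data.frame(id = keep, level = lev, stringsAsFactors = FALSE),
    edges = data.frame(from = e$protein_a, to = e$protein_b,
                       kind = if (nrow(e)) "ppi-undirected" else character(0),
                       confidence = e$confidence,
                       confidence_class = e$confidence_class,
                       stringsAsFactors = FALSE))
}

#' Tag network nodes with subcellular compartments
#'
#' Proteins missing from the localization map are tagged `"unknown"`.
#' Re-tagging is idempotent.
#'
#' @param net A [meta_network()].
#' @param localization Map from [load_localization()].
#' @return The tagged network.
#' @export
tag_compartments <- function(net, localization) {
  net$nodes$compartments <- lapply(net$nodes$id, function(id) {
    localization[[id]] %||% "unknown"
  })
  net
}

#' Overlay pathways onto a network
#'
#' Every pathway (optionally filtered by id) whose member set intersects
#' the current node set is attached in full: missing members are added as
#' nodes (level unset), internal pathway edges are added as directed
#' `pathway-directed` edge records (distinct from any coexisting PPI edge),
#' and each member node accumulates the pathway id. With
#' `members_only = TRUE` no new nodes are added; only edges and memberships
#' among existing nodes.
#'
#' @param net A [meta_network()].
#' @param pathways From [load_pathways()].
#' @param include Optional character vector of pathway ids to consider.
#' @param members_only Restrict the overlay to nodes already present.
#' @return The overlaid network.
#' @export
overlay_pathways <- function(net, pathways, include = NULL,
                             members_only = FALSE) {
  for (i in seq_len(nrow(pathways))) {
    pid <- pathways$pathway_id[[i]]
    if (!is.null(include) && !pid %in% include) next
    members <- pathways$members[[i]]
    if (length(intersect(members, net$nodes$id)) == 0) next
    if (!members_only) {
      new_ids <- setdiff(members, net$nodes$id)
      if (length(new_ids) > 0) {
        add <- data.frame(id = new_ids, level = NA_integer_,
                          stringsAsFactors = FALSE)
        add$compartments <- replicate(length(new_ids), character(0),
                                      simplify = FALSE)
        add$pathway_ids <- replicate(length(new_ids), character(0),
                                     simplify = FALSE)
        add$expr_value <- NA_real_
        add$expr_direction <- NA_character_
        net$nodes <- rbind(net$nodes, add[names(net$nodes)])
      }
    }
    tag <- net$nodes$id %in% members
    net$nodes$pathway_ids[tag] <- lapply(net$nodes$pathway_ids[tag],
                                         function(p) sort(unique(c(p, pid))))
    pe <- pathways$edges[[i]]
    if (nrow(pe) > 0) {
      keep <- pe$from %in% net$nodes$id & pe$to %in% net$nodes$id
      pe <- pe[keep, , drop = FALSE]
      if (nrow(pe) > 0) {
        add_e <- data.frame(from = pe$from, to = pe$to,
                            kind = "pathway-directed",
                            confidence = NA_real_,
                            confidence_class = NA_character_,
                            pathway_id = pid, stringsAsFactors = FALSE)
        net$edges <- rbind(net$edges, add_e[names(net$edges)])
      }
    }
  }
  rownames(net$nodes) <- NULL
  rownames(net$edges) <- NULL
  net
}

#' Merge the neighborhoods and pathways of up to five proteins
#'
#' Builds the per-seed PPI neighborhoods, takes their union (a shared
#' neighbor keeps the minimum hop distance over seeds), then overlays
#' pathways over the union and tags compartments. At most five seed
#' proteins may be merged.
#'
#' @param protein_ids 1 to 5 seed protein ids.
#' @param edges PPI edge table from [load_ppi_table()].
#' @param pathways Optional pathway table from [load_pathways()].
#' @param localization Optional map from [load_localization()].
#' @param levels,min_class Passed to [ppi_neighborhood()].
#' @return A [meta_network()].
#' @export
merge_proteins <- function(protein_ids, edges, pathways = NULL,
                           localization = NULL, levels = 2,
                           min_class = "medium") {
  if (length(protein_ids) < 1 || length(protein_ids) > 5) {
    litnet_stop("between 1 and 5 proteins can be merged (maximum 5 proteins); got %d",
                length(protein_ids))
  }
  nets <- lapply(protein_ids, function(p) {
    ppi_neighborhood(edges, p, levels = levels, min_class = min_class)
  })
  nodes <- do.call(rbind, lapply(nets, function(n) n$nodes[c("id", "level")]))
  lev <- vapply(split(nodes$level, nodes$id), function(l) {
    if (all(is.na(l))) NA_integer_ else min(l, na.rm = TRUE)
  }, integer(1))
  node_df <- data.frame(id = names(lev), level = unname(lev),
                        stringsAsFactors = FALSE)
  edge_df <- do.call(rbind, lapply(nets, function(n) n$edges))
  if (!is.null(edge_df) && nrow(edge_df) > 0) {
    a <- pmin(edge_df$from, edge_df$to)
    b <- pmax(edge_df$from, edge_df$to)
    edge_df <- edge_df[!duplicated(paste(a, b, edge_df$kind, sep = "\r")), ,
                       drop = FALSE]
  }
  net <- meta_network(node_df, edge_df)
  if (!is.null(pathways)) net <- overlay_pathways(net, pathways)
  if (!is.null(localization)) net <- tag_compartments(net, localization)
  net
}

#' Crosstalk proteins across a pathway collection
#'
#' A crosstalk protein belongs to two or more pathways and thereby connects
#' them in the meta-network. Results are sorted by the number of pathways
#' descending, then protein id.
#'
#' @param pathways From [load_pathways()].
#' @param restrict_to Optional protein id set to restrict the scan to.
#' @return Data frame with `protein`, `n_pathways` and list column
#'   `pathway_ids`.
#' @export
crosstalk <- function(pathways, restrict_to = NULL) {
  long <- data.frame(
    protein = unlist(pathways$members, use.names = FALSE),
    pathway_id = rep(pathways$pathway_id, lengths(pathways$members)),
    stringsAsFactors = FALSE)
  long <- long[!duplicated(long), , drop = FALSE]
  if (!is.null(restrict_to)) {
    long <- long[long$protein %in% restrict_to, , drop = FALSE]
  }
  empty <- data.frame(protein = character(0), n_pathways = integer(0),
                      stringsAsFactors = FALSE)
  empty$pathway_ids <- list()
  if (nrow(long) == 0) return(empty)
  byp <- lapply(split(long$pathway_id, long$protein), function(x) sort(unique(x)))
  byp <- byp[lengths(byp) >= 2]
  if (length(byp) == 0) return(empty)
  out <- data.frame(protein = names(byp), n_pathways = lengths(byp),
                    stringsAsFactors = FALSE)
  out$pathway_ids <- unname(byp)
  out <- out[order(-out$n_pathways, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlay differential expression onto a network
#'
#' For every node with data in both conditions the overlay stores
#' `log2(mean(condition_b) / mean(condition_a))` and a direction call:
#' `up` when the log2 fold-change is at or above the threshold, `down` at
#' or below its negation, otherwise `unchanged`. Nodes without data are
#' left unannotated. Expression values must be positive (the log is
#' undefined otherwise).
#'
#' @param net A [meta_network()].
#' @param expression From [load_expression()].
#' @param condition_a,condition_b Condition labels (fold-change is b over a).
#' @param lfc_threshold Positive log2 fold-change threshold.
#' @return The annotated network.
#' @export
overlay_expression <- function(net, expression, condition_a, condition_b,
                               lfc_threshold = 1) {
  if (lfc_threshold <= 0) litnet_stop("lfc_threshold must be > 0")
  for (cond in c(condition_a, condition_b)) {
    if (!cond %in% expression$condition) {
      litnet_stop("condition '%s' absent from expression table", cond)
    }
  }
  if (any(expression$value <= 0)) {
    litnet_stop("non-positive expression value at row %d (log2 undefined)",
                which(expression$value <= 0)[[1]])
  }
  mean_by <- function(cond) {
    sub <- expression[expression$condition == cond, , drop = FALSE]
    vapply(split(sub$value, sub$gene), mean, numeric(1))
  }
  ma <- mean_by(condition_a)
  mb <- mean_by(condition_b)
  genes <- intersect(names(ma), names(mb))
  for (i in seq_len(nrow(net$nodes))) {
    id <- net$nodes$id[[i]]
    if (!id %in% genes) next
    val <- log2(mb[[id]] / ma[[id]])
    net$nodes$expr_value[[i]] <- val
    net$nodes$expr_direction[[i]] <-
      if (val >= lfc_threshold) "up"
      else if (val <= -lfc_threshold) "down"
      else "unchanged"
  }
  net
}
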