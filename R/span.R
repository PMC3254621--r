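#' @title Cross-locus network prioritization (SPAN)
#' @description
#' Given a high-confidence protein network and two disjoint candidate
#' protein sets (the gene products of the two linked chromosomal windows),
#' SPAN asks whether specific proteins, and specific interactions, connect
#' the two sets more often than expected under a null model that conserves
#' every protein's number of connections.  The null is sampled by
#' degree-preserving double-edge swaps of the full network; empirical
#' p-values use the `(r + 1) / (N + 1)` pseudocount estimator and are
#' FDR-adjusted (Benjamini-Hochberg) separately for the node and edge
#' families.
#' @name span_network
NULL

#' Candidate protein sets
#'
#' @param set_a,set_b character vectors of protein ids; must be disjoint.
#' @return a `candidate_sets` list.
#' @export
candidate_sets <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (length(intersect(set_a, set_b)))
    stop("candidate sets must be disjoint")
  structure(list(set_a = set_a, set_b = set_b), class = "candidate_sets")
}

#' Cross-locus bipartite subgraph
#'
#' Extracts the edges with one endpoint in each candidate set; within-set
#' edges are excluded.
#'
#' @param ppin a `ppin`.
#' @param sets a `candidate_sets`.
#' @return the cross-locus edge rows of `ppin$edges`.
#' @export
cross_locus_subgraph <- function(ppin, sets) {
  e <- ppin$edges
  a1 <- e$protein1 %in% sets$set_a; b1 <- e$protein1 %in% sets$set_b
  a2 <- e$protein2 %in% sets$set_a; b2 <- e$protein2 %in% sets$set_b
  out <- e[(a1 & b2) | (b1 & a2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Degree-preserving network randomization
#'
#' Rewires the network by double-edge swaps: repeatedly two edges are
#' picked and their endpoints exchanged, rejecting swaps that would create
#' a self-loop or duplicate edge, so that every node keeps exactly its
#' original degree and the graph stays simple.  `swaps_per_edge * n_edges`
#' swap trials are attempted (via igraph's `keeping_degseq` rewiring).
#' Graphs admitting no valid swap (e.g. a triangle) are returned
#' unchanged.
#'
#' @param ppin a `ppin` with at least 2 edges.
#' @param swaps_per_edge swap trials per edge (default 10).
#' @param seed integer seed.
#' @return a `ppin` with the same degree sequence; edge evidence scores
#'   are carried over by edge slot and are not meaningful for the
#'   randomized topology.
#' @export
randomize_network <- function(ppin, swaps_per_edge = 10, seed = 1L) {
  if (nrow(ppin$edges) < 2L) stop("need at least 2 edges to randomize")
  g <- igraph::graph_from_data_frame(
    ppin$edges[, c("protein1", "protein2")], directed = FALSE,
    vertices = ppin$nodes)
  withr::with_seed(as.integer(seed), {
    g2 <- .rewire_graph(g, swaps_per_edge)
  })
  el <- igraph::as_edgelist(g2, names = TRUE)
  edges <- ppin$edges
  edges$protein1 <- el[, 1]
  edges$protein2 <- el[, 2]
  out <- new_ppin(edges)
  out$nodes <- ppin$nodes
  out
}

.rewire_graph <- function(g, swaps_per_edge) {
  niter <- max(1L, as.integer(swaps_per_edge * igraph::ecount(g)))
  igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = niter))
}

# Shared Monte-Carlo engine: counts, over n_rand degree-preserving
# randomizations of the full network, how often each candidate protein's
# cross-locus degree reaches its observed value and how often each
# observed cross-locus edge re-occurs.
.span_randomize <- function(ppin, sets, n_rand, swaps_per_edge, seed) {
  if (n_rand < 10L) stop("`n_rand` must be at least 10")
  prots <- c(sets$set_a, sets$set_b)
  side <- c(rep("a", length(sets$set_a)), rep("b", length(sets$set_b)))
  obs_edges <- cross_locus_subgraph(ppin, sets)
  obs_key <- paste(obs_edges$protein1, obs_edges$protein2, sep = "\r")
  cross_deg <- function(edges) {
    a1 <- edges$protein1 %in% sets$set_a; b1 <- edges$protein1 %in% sets$set_b
    a2 <- edges$protein2 %in% sets$set_a; b2 <- edges$protein2 %in% sets$set_b
    cross <- (a1 & b2) | (b1 & a2)
    ends <- c(edges$protein1[cross], edges$protein2[cross])
    tab <- table(factor(ends, levels = prots))
    as.integer(tab)
  }
  observed <- cross_deg(ppin$edges)
  node_hits <- integer(length(prots))
  edge_hits <- integer(length(obs_key))

  g <- igraph::graph_from_data_frame(
    ppin$edges[, c("protein1", "protein2")], directed = FALSE,
    vertices = ppin$nodes)
  withr::with_seed(as.integer(seed), {
    for (k in seq_len(n_rand)) {
      gk <- .rewire_graph(g, swaps_per_edge)
      el <- igraph::as_edgelist(gk, names = TRUE)
      lo <- pmin(el[, 1], el[, 2]); hi <- pmax(el[, 1], el[, 2])
      ek <- data.frame(protein1 = lo, protein2 = hi,
                       stringsAsFactors = FALSE)
      cd <- cross_deg(ek)
      node_hits <- node_hits + as.integer(cd >= observed)
      if (length(obs_key))
        edge_hits <- edge_hits +
          as.integer(obs_key %in% paste(lo, hi, sep = "\r"))
    }
  })
  list(proteins = prots, side = side, observed = observed,
       node_hits = node_hits, obs_edges = obs_edges,
       edge_hits = edge_hits, n_rand = as.integer(n_rand))
}

#' Node-level SPAN p-values
#'
#' For each candidate protein, the observed cross-locus degree (its number
#' of interactions with the opposite set) is compared with its cross-locus
#' degree in `n_rand` degree-preserving randomizations of the full
#' network: `p = (r + 1) / (n_rand + 1)` where `r` counts randomizations
#' with cross-locus degree at least the observed value.  Proteins absent
#' from the network (or with no cross-locus edge) have `p = 1`.
#'
#' @param ppin a `ppin`.
#' @param sets a `candidate_sets`.
#' @param n_rand number of randomizations (>= 10).
#' @param swaps_per_edge swap trials per edge per randomization.
#' @param seed integer seed.
#' @return data frame `protein`, `set`, `observed_cross_degree`,
#'   `p_value`.
#' @export
node_priority <- function(ppin, sets, n_rand = 1000, swaps_per_edge = 10,
                          seed = 1L) {
  rz <- .span_randomize(ppin, sets, n_rand, swaps_per_edge, seed)
  data.frame(protein = rz$proteins, set = rz$side,
             observed_cross_degree = rz$observed,
             p_value = (rz$node_hits + 1) / (rz$n_rand + 1),
             stringsAsFactors = FALSE)
}

#' Edge-level SPAN p-values
#'
#' The extension of the node metric to single interactions: for each
#' observed cross-locus edge, `p = (r + 1) / (n_rand + 1)` where `r`
#' counts randomizations in which that specific edge re-occurs.  A small p
#' marks an interaction unlikely to arise under the degree-preserving
#' null.
#'
#' @inheritParams node_priority
#' @return data frame `protein_a`, `protein_b`, `observed`, `p_value`.
#' @export
edge_priority <- function(ppin, sets, n_rand = 1000, swaps_per_edge = 10,
                          seed = 1L) {
  rz <- .span_randomize(ppin, sets, n_rand, swaps_per_edge, seed)
  data.frame(protein_a = rz$obs_edges$protein1,
             protein_b = rz$obs_edges$protein2,
             observed = rep(TRUE, length(rz$edge_hits)),
             p_value = (rz$edge_hits + 1) / (rz$n_rand + 1),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate correction:
#' `q_i = min over j with p_(j) >= p_(i) of (m p_(j) / j)`, capped at 1.
#' Node and edge p-value families are adjusted separately by the callers.
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @return q-values in the input order (empty in, empty out).
#' @export
fdr_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Full SPAN prioritization with FDR tiers
#'
#' Runs one set of degree-preserving randomizations, derives node- and
#' edge-level p-values, FDR-adjusts each family separately, and assigns
#' display tiers: `strong` (q below `fdr_strong`), `weak` (q below
#' `fdr_weak`) and `background`.  The headline subnetwork contains the
#' cross-locus edges that are strong at the edge level *and* have both
#' endpoints strong at the node level.
#'
#' @inheritParams node_priority
#' @param fdr_strong strong-tier FDR cutoff (default 1e-4).
#' @param fdr_weak weak-tier FDR cutoff (default 0.5).
#' @return object of class `span_prioritization`: `nodes` and `edges`
#'   data frames (with `q_value` and `tier`), `headline` (the
#'   strong-by-both-families edge set), `n_rand`, `seed`.
#' @export
prioritize <- function(ppin, sets, fdr_strong = 1e-4, fdr_weak = 0.5,
                       n_rand = 1000, swaps_per_edge = 10, seed = 1L) {
  stopifnot(fdr_strong > 0, fdr_weak > 0, fdr_strong <= fdr_weak)
  rz <- .span_randomize(ppin, sets, n_rand, swaps_per_edge, seed)
  tier_of <- function(q) ifelse(q < fdr_strong, "strong",
                                ifelse(q < fdr_weak, "weak", "background"))
  nodes <- data.frame(protein = rz$proteins, set = rz$side,
                      observed_cross_degree = rz$observed,
                      p_value = (rz$node_hits + 1) / (rz$n_rand + 1),
                      stringsAsFactors = FALSE)
  nodes$q_value <- fdr_adjust(nodes$p_value)
  nodes$tier <- tier_of(nodes$q_value)
  edges <- data.frame(protein_a = rz$obs_edges$protein1,
                      protein_b = rz$obs_edges$protein2,
                      observed = rep(TRUE, length(rz$edge_hits)),
                      p_value = (rz$edge_hits + 1) / (rz$n_rand + 1),
                      stringsAsFactors = FALSE)
  edges$q_value <- fdr_adjust(edges$p_value)
  edges$tier <- if (nrow(edges)) tier_of(edges$q_value) else character(0)
  nq <- stats::setNames(nodes$q_value, nodes$protein)
  headline <- edges[nrow(edges) > 0 & edges$tier == "strong" &
                      nq[edges$protein_a] < fdr_strong &
                      nq[edges$protein_b] < fdr_strong, , drop = FALSE]
  rownames(headline) <- NULL
  structure(list(nodes = nodes, edges = edges, headline = headline,
                 fdr_strong = fdr_strong, fdr_weak = fdr_weak,
                 n_rand = rz$n_rand, seed = as.integer(seed)),
            class = "span_prioritization")
}

#' @export
print.span_prioritization <- function(x, ...) {
  cat(sprintf(
    "SPAN prioritization: %d candidate proteins, %d cross-locus edges, %d randomizations\n",
    nrow(x$nodes), nrow(x$edges), x$n_rand))
  cat(sprintf("headline (q < %g at node and edge level): %d edge(s)\n",
              x$fdr_strong, nrow(x$headline)))
  invisible(x)
}

#' Write a prioritized subnetwork as SIF
#'
#' Simple interaction format: one `protein_a pp protein_b` line per edge.
#'
#' @param edges data frame with `protein_a`, `protein_b`.
#' @param path output file.
#' @param comment optional `# `-prefixed header line.
#' @return `path`, invisibly.
#' @export
write_sif <- function(edges, path, comment = NULL) {
  lines <- c(if (!is.null(comment)) paste0("# ", comment),
             if (nrow(edges)) paste(edges$protein_a, "pp", edges$protein_b))
  writeLines(lines, path)
  invisible(path)
}

#' Write the tiered subnetwork as GraphML
#'
#' Exports all scored cross-locus edges and their endpoint nodes with tier
#' and q-value attributes (Cytoscape-compatible).
#'
#' @param result a `span_prioritization`.
#' @param path output file.
#' @param seed_info optional string stored as a graph attribute.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(result, path, seed_info = NULL) {
  nodes <- result$nodes
  edges <- result$edges
  if (nrow(edges) == 0L) {
    vdf <- nodes[, c("protein", "set", "q_value", "tier")]
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(vdf$protein, set = vdf$set,
                       q_value = vdf$q_value, tier = vdf$tier)
  } else {
    used <- unique(c(edges$protein_a, edges$protein_b))
    vdf <- nodes[nodes$protein %in% used,
                 c("protein", "set", "q_value", "tier")]
    names(vdf)[1] <- "name"
    g <- igraph::graph_from_data_frame(
      edges[, c("protein_a", "protein_b", "q_value", "tier")],
      directed = FALSE, vertices = vdf)
  }
  if (!is.null(seed_info))
    g <- igraph::set_graph_attr(g, "provenance", seed_info)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write prioritization tables
#'
#' @param result a `span_prioritization`.
#' @param node_path,edge_path output TSV files.
#' @param comment optional `# `-prefixed header line for both files.
#' @return invisibly, the two paths.
#' @export
write_prioritization <- function(result, node_path, edge_path,
                                 comment = NULL) {
  wr <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(comment)) writeLines(paste0("# ", comment), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(result$nodes, node_path)
  wr(result$edges, edge_path)
  invisible(c(node_path, edge_path))
}
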