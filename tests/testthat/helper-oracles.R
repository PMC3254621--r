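# Shared fixtures and independent oracles for the test suite.

# Build a minimal map: k markers per chromosome, at the given cM spacing.
toy_map <- function(n_chr = 1, k = 4, spacing_cM = 5, cm_per_mb = 0.5) {
  pieces <- lapply(seq_len(n_chr), function(ch) {
    pos_cM <- seq_len(k) * spacing_cM
    data.frame(marker = sprintf("t%02dm%02d", ch, seq_len(k)),
               chr = as.character(ch), pos_cM = pos_cM,
               pos_bp = as.integer(round(pos_cM / cm_per_mb * 1e6)),
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, pieces)
  class(map) <- c("genetic_map", "data.frame")
  map
}

# Build a cross directly from an integer genotype matrix (1/2/3/NA).
toy_cross <- function(geno, phenotype = NULL, map = NULL, origin = NULL) {
  geno <- as.matrix(geno)
  if (is.null(map)) map <- toy_map(1, ncol(geno))
  new_cross(map, geno, phenotype,
            mouse_ids = sprintf("m%02d", seq_len(nrow(geno))),
            origin = origin, check_parental = FALSE)
}

# Independent least-squares oracle for the single-marker scan: explicit
# class-mean fit on complete cases via lm().
lm_scan1_oracle <- function(geno_col, y) {
  ok <- !is.na(geno_col)
  g <- factor(geno_col[ok]); yy <- y[ok]
  n <- sum(ok)
  if (n == 0 || nlevels(g) < 2) return(0)
  rss0 <- sum((yy - mean(yy))^2)
  rss1 <- deviance(stats::lm(yy ~ g))
  if (rss1 <= 1e-12 * max(sum(yy^2), 1)) return(Inf)
  (n / 2) * log10(rss0 / rss1)
}

# Independent oracle for the pair scan: builds the full (cell means) and
# additive design matrices explicitly and solves the normal equations.
lm_scan2_oracle <- function(ga, gb, y) {
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]; yy <- y[ok]
  n <- length(yy)
  cell <- droplevels(interaction(factor(ga, levels = 1:3),
                                 factor(gb, levels = 1:3)))
  if (n == 0 || nlevels(cell) < 2)
    return(list(lod_full = 0, lod_add = 0, lod_int = 0))
  rss0 <- sum((yy - mean(yy))^2)
  Xf <- stats::model.matrix(~ 0 + cell)
  bf <- qr.coef(qr(Xf), yy); bf[is.na(bf)] <- 0
  rssf <- sum((yy - Xf %*% bf)^2)
  Xa <- stats::model.matrix(~ factor(ga, levels = 1:3) +
                              factor(gb, levels = 1:3))
  qa <- qr(Xa)
  ba <- qr.coef(qa, yy); ba[is.na(ba)] <- 0
  rssa <- sum((yy - Xa %*% ba)^2)
  tol <- 1e-12 * max(sum(yy^2), 1)
  lf <- if (rssf <= tol) Inf else (n / 2) * log10(rss0 / rssf)
  la <- if (rssa <= tol) Inf else (n / 2) * log10(rss0 / rssa)
  li <- if (rssf <= tol) {
    if (rssa <= tol) 0 else NA_real_
  } else (n / 2) * log10(rssa / rssf)
  list(lod_full = lf, lod_add = la, lod_int = li)
}

# absolute-tolerance comparison that also matches NA/Inf patterns
expect_close <- function(actual, expected, tol = 1e-9) {
  if (length(expected) == 1L && (is.na(expected) || is.infinite(expected))) {
    testthat::expect_identical(is.na(actual), is.na(expected))
    testthat::expect_identical(is.infinite(actual), is.infinite(expected))
  } else {
    testthat::expect_lt(max(abs(actual - expected)), tol)
  }
}

# A STRING-dialect edge record with given endpoints/scores.
string_edge <- function(p1, p2, combined = 900L, experimental = 500L,
                        fusion = 0L, database = 0L, textmining = 0L) {
  data.frame(protein1 = p1, protein2 = p2, neighborhood = 0L,
             fusion = fusion, cooccurence = 0L, coexpression = 0L,
             experimental = experimental, database = database,
             textmining = textmining, combined_score = combined,
             stringsAsFactors = FALSE)
}

toy_ppin <- function(p1, p2, ...) new_ppin(string_edge(p1, p2, ...))

# Exhaustive enumeration of all labelled simple graphs sharing the degree
# sequence of the given edge set (nodes = character vector).  Returns a
# list of canonical edge-key vectors, one per graph.
enum_degree_graphs <- function(nodes, edges) {
  m <- nrow(edges)
  deg0 <- table(factor(c(edges[[1]], edges[[2]]), levels = nodes))
  pairs <- t(utils::combn(nodes, 2))
  sel <- utils::combn(nrow(pairs), m)
  out <- list()
  for (c in seq_len(ncol(sel))) {
    sub <- pairs[sel[, c], , drop = FALSE]
    deg <- table(factor(c(sub[, 1], sub[, 2]), levels = nodes))
    if (all(deg == deg0))
      out[[length(out) + 1L]] <-
        sort(paste(pmin(sub[, 1], sub[, 2]), pmax(sub[, 1], sub[, 2])))
  }
  out
}

# Exact null probabilities from the enumeration: for each protein, the
# probability of cross-locus degree >= observed; for each observed cross
# edge, the probability the edge occurs.
enum_span_pvalues <- function(nodes, edges, set_a, set_b) {
  graphs <- enum_degree_graphs(nodes, edges)
  prots <- c(set_a, set_b)
  cross_deg <- function(keys) {
    sub <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
    cr <- (sub[, 1] %in% set_a & sub[, 2] %in% set_b) |
      (sub[, 1] %in% set_b & sub[, 2] %in% set_a)
    table(factor(c(sub[cr, 1], sub[cr, 2]), levels = prots))
  }
  obs_key <- {
    cr <- (edges[[1]] %in% set_a & edges[[2]] %in% set_b) |
      (edges[[1]] %in% set_b & edges[[2]] %in% set_a)
    paste(pmin(edges[[1]][cr], edges[[2]][cr]),
          pmax(edges[[1]][cr], edges[[2]][cr]))
  }
  obs <- cross_deg(sort(paste(pmin(edges[[1]], edges[[2]]),
                              pmax(edges[[1]], edges[[2]]))))
  node_p <- sapply(seq_along(prots), function(i)
    mean(vapply(graphs, function(g) cross_deg(g)[i] >= obs[i], logical(1))))
  edge_p <- sapply(obs_key, function(k)
    mean(vapply(graphs, function(g) k %in% g, logical(1))))
  list(node = stats::setNames(node_p, prots),
       edge = stats::setNames(edge_p, obs_key), n_graphs = length(graphs))
}
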