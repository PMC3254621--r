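#' @title Protein-protein interaction networks
#' @description
#' A `ppin` is a simple undirected graph whose edges carry per-channel
#' STRING-style evidence scores (integers on the 0--1000 scale) and a
#' combined score.  Edges are stored canonically with
#' `protein1 < protein2` and no duplicates or self-loops.
#' @name ppin
NULL

STRING_CHANNELS <- c("neighborhood", "fusion", "cooccurence", "coexpression",
                     "experimental", "database", "textmining")
STRING_COLS <- c("protein1", "protein2", STRING_CHANNELS, "combined_score")

#' Construct a ppin from an edge table
#'
#' Canonicalises endpoint order, merges duplicate A-B/B-A records by
#' taking the elementwise maximum of their scores, and drops self-loops.
#'
#' @param edges data frame with the STRING detailed-links columns
#'   (`protein1`, `protein2`, the seven evidence channels,
#'   `combined_score`).
#' @return an object of class `ppin` with elements `edges` and `nodes`.
#' @export
new_ppin <- function(edges) {
  miss <- setdiff(STRING_COLS, names(edges))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  edges <- edges[, STRING_COLS, drop = FALSE]
  edges <- edges[edges$protein1 != edges$protein2, , drop = FALSE]
  swap <- edges$protein1 > edges$protein2
  if (any(swap)) {
    tmp <- edges$protein1[swap]
    edges$protein1[swap] <- edges$protein2[swap]
    edges$protein2[swap] <- tmp
  }
  scores <- c(STRING_CHANNELS, "combined_score")
  bad <- vapply(scores, function(cn)
    any(edges[[cn]] < 0 | edges[[cn]] > 1000, na.rm = TRUE), logical(1))
  if (any(bad)) stop("scores must lie in [0, 1000]")
  key <- paste(edges$protein1, edges$protein2, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- lapply(scores, function(cn)
      as.integer(tapply(edges[[cn]], key, max)))
    ks <- sort(unique(key))
    parts <- do.call(rbind, strsplit(ks, "\r", fixed = TRUE))
    edges <- data.frame(protein1 = parts[, 1], protein2 = parts[, 2],
                        stringsAsFactors = FALSE)
    for (i in seq_along(scores)) edges[[scores[i]]] <- agg[[i]]
  }
  edges <- edges[order(edges$protein1, edges$protein2), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$protein1, edges$protein2)))),
            class = "ppin")
}

#' @export
print.ppin <- function(x, ...) {
  cat(sprintf("ppin: %d proteins, %d interactions\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read STRING detailed-links records
#'
#' Parses the detailed-links dialect: a header line followed by
#' whitespace- (space or tab) separated records of two protein ids, seven
#' per-channel scores and a combined score, all integers on the 0--1000
#' scale.  Malformed records are skipped with a counted warning; a file
#' whose header does not match the dialect is an error.
#'
#' @param path input file.
#' @return data frame of raw edge records (not yet filtered or merged).
#' @export
read_string_edges <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("empty STRING file")
  fields <- strsplit(trimws(lines), "[ \t]+")
  hdr <- fields[[1]]
  if (length(hdr) != 10L || hdr[1] != "protein1")
    stop("not a STRING detailed-links file (unexpected header)")
  body <- fields[-1]
  ok <- vapply(body, function(f) {
    length(f) == 10L && !anyNA(suppressWarnings(as.integer(f[3:10])))
  }, logical(1))
  if (any(!ok))
    warning(sum(!ok), " malformed record(s) skipped")
  body <- body[ok]
  if (length(body) == 0L)
    return(stats::setNames(
      data.frame(character(), character(), integer(), integer(), integer(),
                 integer(), integer(), integer(), integer(), integer(),
                 stringsAsFactors = FALSE), STRING_COLS))
  m <- do.call(rbind, body)
  out <- data.frame(protein1 = m[, 1], protein2 = m[, 2],
                    stringsAsFactors = FALSE)
  for (i in 3:10) out[[STRING_COLS[i]]] <- as.integer(m[, i])
  out
}

#' Write a ppin in STRING detailed-links format
#'
#' @param ppin a `ppin`.
#' @param path output file.
#' @param sep field separator (STRING uses a single space).
#' @param comment optional `# `-prefixed header line.
#' @return `path`, invisibly.
#' @export
write_string_edges <- function(ppin, path, sep = " ", comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(ppin$edges, con, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter STRING edges to a high-confidence network
#'
#' Retains an interaction iff its combined score strictly exceeds
#' `min_combined` and at least one of the required evidence channels has a
#' positive score.  The defaults (combined > 800 with fusion,
#' experimental or database evidence) remove purely literature-derived
#' (text-mining) interactions.  Duplicate A-B/B-A records are merged.
#' The operation is idempotent.
#'
#' @param raw_edges data frame of STRING records (see
#'   [read_string_edges()]) or a `ppin`.
#' @param min_combined strict lower bound on the combined score.
#' @param required_channels channel names, at least one of which must be
#'   positive.
#' @return a filtered `ppin`.
#' @export
filter_string_edges <- function(raw_edges, min_combined = 800,
                                required_channels = c("fusion",
                                                      "experimental",
                                                      "database")) {
  if (inherits(raw_edges, "ppin")) raw_edges <- raw_edges$edges
  bad <- setdiff(required_channels, STRING_CHANNELS)
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  keep <- raw_edges$combined_score > min_combined
  chan <- Reduce(`|`, lapply(required_channels,
                             function(cn) raw_edges[[cn]] > 0))
  new_ppin(raw_edges[keep & chan, , drop = FALSE])
}

# decode linear index of an unordered pair (i < j) over n nodes,
# column-major over the strict upper triangle
.pair_decode <- function(lin, n) {
  # cumulative pairs before column j: (j-1)(j-2)/2
  j <- ceiling((1 + sqrt(1 + 8 * lin)) / 2 - 1e-9)
  off <- lin - (j - 1) * (j - 2) / 2
  cbind(i = as.integer(off), j = as.integer(j))
}

.pair_encode <- function(i, j, n) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (hi - 1) * (hi - 2) / 2 + lo
}

#' Simulate a protein interaction network
#'
#' Generates a simple undirected graph containing every planted edge, with
#' the remaining edges sampled either uniformly over node pairs
#' (`degree_skew = 0`, an Erdos-Renyi G(n, m) background) or by
#' preferential attachment with endpoint weights `(degree + 1)^degree_skew`.
#' Every edge is annotated with a combined score above 800 and a positive
#' experimental evidence channel so that the default high-confidence
#' filter retains the whole network.
#'
#' @param n_nodes number of nodes (ignored if `node_ids` given).
#' @param n_edges total number of edges, planted edges included.
#' @param planted_edges optional 2-column matrix (or list of pairs) of
#'   node ids whose edges are guaranteed present.
#' @param degree_skew non-negative preferential-attachment strength.
#' @param seed integer seed.
#' @param node_ids optional explicit node id vector.
#' @return a `ppin`.
#' @export
simulate_ppin <- function(n_nodes, n_edges, planted_edges = NULL,
                          degree_skew = 0, seed = 1L, node_ids = NULL) {
  if (is.null(node_ids)) node_ids <- sprintf("P%04d", seq_len(n_nodes))
  n <- length(node_ids)
  max_edges <- n * (n - 1) / 2
  if (n_edges > max_edges) stop("infeasible edge count for ", n, " nodes")
  if (degree_skew < 0) stop("`degree_skew` must be non-negative")
  planted <- NULL
  if (!is.null(planted_edges)) {
    if (is.list(planted_edges) && !is.data.frame(planted_edges))
      planted_edges <- do.call(rbind, planted_edges)
    planted <- as.matrix(planted_edges)
    pi1 <- match(planted[, 1], node_ids)
    pi2 <- match(planted[, 2], node_ids)
    if (anyNA(pi1) || anyNA(pi2))
      stop("planted edges must reference known nodes")
    if (any(pi1 == pi2)) stop("planted self-loops are not allowed")
    plin <- .pair_encode(pi1, pi2, n)
    if (anyDuplicated(plin)) stop("planted pairs must be distinct")
    if (n_edges < length(plin))
      stop("`n_edges` must be at least the number of planted edges")
  } else plin <- numeric(0)

  n_extra <- n_edges - length(plin)
  withr::with_seed(as.integer(seed), {
    if (n_extra > 0) {
      if (degree_skew == 0) {
        pool <- setdiff(seq_len(max_edges), plin)
        extra <- sample(pool, n_extra)
        lin <- c(plin, extra)
      } else {
        deg <- numeric(n)
        taken <- new.env(hash = TRUE, size = n_edges * 2L)
        ij0 <- .pair_decode(plin, n)
        for (t in seq_along(plin)) {
          assign(as.character(plin[t]), TRUE, envir = taken)
          deg[ij0[t, 1]] <- deg[ij0[t, 1]] + 1
          deg[ij0[t, 2]] <- deg[ij0[t, 2]] + 1
        }
        lin <- plin
        while (length(lin) < n_edges) {
          w <- (deg + 1)^degree_skew
          u <- sample.int(n, 1L, prob = w)
          v <- sample.int(n, 1L, prob = w)
          if (u == v) next
          key <- as.character(.pair_encode(u, v, n))
          if (exists(key, envir = taken, inherits = FALSE)) next
          assign(key, TRUE, envir = taken)
          deg[u] <- deg[u] + 1; deg[v] <- deg[v] + 1
          lin <- c(lin, .pair_encode(u, v, n))
        }
      }
    } else lin <- plin
    m <- length(lin)
    combined <- sample(801:1000, m, replace = TRUE)
    experimental <- sample(200:1000, m, replace = TRUE)
    database <- sample(c(rep(0L, 3), 300:900), m, replace = TRUE)
    textmining <- sample(0:1000, m, replace = TRUE)
  })
  ij <- .pair_decode(lin, n)
  edges <- data.frame(
    protein1 = node_ids[ij[, 1]], protein2 = node_ids[ij[, 2]],
    neighborhood = 0L, fusion = 0L, cooccurence = 0L, coexpression = 0L,
    experimental = as.integer(experimental), database = as.integer(database),
    textmining = as.integer(textmining),
    combined_score = as.integer(combined), stringsAsFactors = FALSE)
  ppin <- new_ppin(edges)
  # isolated nodes are kept so node-level records can report them
  ppin$nodes <- sort(unique(c(node_ids, ppin$nodes)))
  ppin
}
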