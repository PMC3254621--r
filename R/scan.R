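#' @title Marker-regression genome scans
#' @description
#' Single-QTL and two-dimensional two-QTL genome scans by marker
#' regression on typed genotypes.  For a model M fitted by least squares
#' on the complete cases of a marker (or marker pair),
#' `LOD = (n/2) * log10(RSS0 / RSS_M)` where `RSS0` is the residual sum of
#' squares under the grand mean.  The two-QTL scan fits a full model (one
#' mean per observed cell of the 3x3 joint-genotype table) and an additive
#' model (mean + marker-a effects + marker-b effects, at most 5 free
#' parameters); the interaction LOD is `lod_full - lod_add`.
#' @name qtl_scan
NULL

# 0/1 indicator matrices for the three genotype classes plus the observed
# mask, for the selected mice.
.geno_indicators <- function(geno) {
  G <- lapply(1:3, function(r) {
    m <- (geno == r)
    m[is.na(m)] <- FALSE
    storage.mode(m) <- "double"
    m
  })
  list(G = G, obs = G[[1]] + G[[2]] + G[[3]])
}

.scan_rows <- function(cross, include_parental) {
  if (include_parental) seq_along(cross$mouse_ids)
  else which(cross$origin == "F2")
}

# Upper-triangle (i <= j) index bookkeeping for the 5x5 additive-model
# quadratic form.
.UT5 <- which(upper.tri(diag(5), diag = TRUE))
.UT5_IJ <- which(upper.tri(diag(5), diag = TRUE), arr.ind = TRUE)

#' Precompute pair-scan structures
#'
#' Computes, once per cross, everything in the two-QTL scan that does not
#' depend on the phenotype: joint genotype-class counts for every marker
#' pair, the valid-pair mask, and the pseudo-inverse of each pair's
#' additive-model normal matrix (stored entrywise as marker-by-marker
#' matrices so that permutation replicates reduce to dense matrix algebra).
#' Reused across phenotype permutations.
#'
#' @param cross a `cross_data` with phenotype set.
#' @param exclude_adjacent_cM same-chromosome pairs closer than this many
#'   cM are dropped from the scan (0 = scan all pairs).
#' @param include_parental include the parental-average rows.
#' @return an opaque list consumed by [scan_two()] and
#'   [permutation_thresholds()].
#' @keywords internal
scan2_precompute <- function(cross, exclude_adjacent_cM = 0,
                             include_parental = TRUE) {
  rows <- .scan_rows(cross, include_parental)
  geno <- cross$geno[rows, , drop = FALSE]
  ind <- .geno_indicators(geno)
  M <- ncol(geno)
  Nrs <- vector("list", 9L)
  for (r in 1:3) for (s in 1:3)
    Nrs[[(r - 1L) * 3L + s]] <- crossprod(ind$G[[r]], ind$G[[s]])
  N <- Reduce(`+`, Nrs)
  nclass <- Reduce(`+`, lapply(Nrs, function(x) (x > 0) + 0))
  invNrs <- lapply(Nrs, function(x) { z <- 1 / x; z[x == 0] <- 0; z })
  invN <- 1 / N; invN[N == 0] <- 0

  scanned <- upper.tri(N)
  if (exclude_adjacent_cM > 0) {
    same_chr <- outer(cross$map$chr, cross$map$chr, `==`)
    dcm <- abs(outer(cross$map$pos_cM, cross$map$pos_cM, `-`))
    scanned <- scanned & !(same_chr & dcm < exclude_adjacent_cM)
  }
  valid <- scanned & nclass >= 2

  # additive-model X'X entries, assembled per valid pair from count
  # marginals; dummy coding with class AA as baseline
  a2 <- Nrs[[4]] + Nrs[[5]] + Nrs[[6]]   # marker-a class AB count
  a3 <- Nrs[[7]] + Nrs[[8]] + Nrs[[9]]   # marker-a class BB count
  b2 <- Nrs[[2]] + Nrs[[5]] + Nrs[[8]]   # marker-b class AB count
  b3 <- Nrs[[3]] + Nrs[[6]] + Nrs[[9]]   # marker-b class BB count
  lin <- which(valid)
  sc <- cbind(n = N[lin], a2 = a2[lin], a3 = a3[lin],
              b2 = b2[lin], b3 = b3[lin],
              n22 = Nrs[[5]][lin], n23 = Nrs[[6]][lin],
              n32 = Nrs[[8]][lin], n33 = Nrs[[9]][lin])
  kv <- matrix(0, length(lin), 15L)
  xtx <- matrix(0, 5L, 5L)
  for (t in seq_len(nrow(sc))) {
    v <- sc[t, ]
    xtx[] <- c(v[1], v[2], v[3], v[4], v[5],
               v[2], v[2], 0,    v[6], v[7],
               v[3], 0,    v[3], v[8], v[9],
               v[4], v[6], v[8], v[4], 0,
               v[5], v[7], v[9], 0,    v[5])
    kv[t, ] <- MASS::ginv(xtx)[.UT5]
  }
  Kmats <- lapply(seq_len(15L), function(k) {
    m <- matrix(NA_real_, M, M); m[lin] <- kv[, k]; m
  })

  # chromosome-pair blocks of the valid pairs, for the interaction
  # summary statistic (see .chrpair_mi)
  ijv <- arrayInd(lin, dim(N))
  block <- paste(cross$map$chr[ijv[, 1]], cross$map$chr[ijv[, 2]],
                 sep = "\r")
  list(rows = rows, map = cross$map, ind = ind, Nrs = Nrs, invNrs = invNrs,
       N = N, invN = invN, nclass = nclass, scanned = scanned,
       valid = valid, K = Kmats, M = M, lin_valid = lin,
       blocks = split(seq_along(lin), block))
}

# Interaction LOD of a chromosome pair, the convention of standard
# two-QTL mapping software: the maximum full LOD over the pair's
# two-locus surface minus the maximum additive LOD over the same
# surface, maximized separately.  `lf`/`la` are the full/additive LODs
# of the valid pairs (in lin_valid order); infinite values are excluded.
.chrpair_mi <- function(lf, la, blocks) {
  mx <- function(v) {
    v <- v[is.finite(v)]
    if (length(v)) max(v) else -Inf
  }
  vapply(blocks, function(ix) mx(lf[ix]) - mx(la[ix]), numeric(1))
}

# Phenotype-dependent part of the pair scan.  Returns M x M matrices of
# lod_full, lod_add, lod_int plus RSS diagnostics; entries outside the
# valid mask are NA.
.scan2_core <- function(pre, y) {
  G <- pre$ind$G
  Gy <- lapply(G, function(g) g * y)
  S <- vector("list", 9L)
  for (r in 1:3) for (s in 1:3)
    S[[(r - 1L) * 3L + s]] <- crossprod(Gy[[r]], G[[s]])
  T2 <- crossprod(pre$ind$obs * (y * y), pre$ind$obs)
  SSfull <- Reduce(`+`, Map(function(s, iv) s * s * iv, S, pre$invNrs))
  Sy <- Reduce(`+`, S)
  RSS0 <- T2 - Sy * Sy * pre$invN
  RSSf <- pmax(T2 - SSfull, 0)

  v <- list(
    Sy,
    S[[4]] + S[[5]] + S[[6]],   # sum of y over marker-a AB cells
    S[[7]] + S[[8]] + S[[9]],   # marker-a BB
    S[[2]] + S[[5]] + S[[8]],   # marker-b AB
    S[[3]] + S[[6]] + S[[9]]    # marker-b BB
  )
  quad <- 0
  for (k in seq_len(15L)) {
    i <- .UT5_IJ[k, 1]; j <- .UT5_IJ[k, 2]
    w <- if (i == j) 1 else 2
    quad <- quad + w * pre$K[[k]] * v[[i]] * v[[j]]
  }
  RSSa <- pmax(pmin(T2 - quad, RSS0), RSSf)

  tol <- 1e-12 * pmax(T2, 1)
  degenerate <- RSS0 <= tol          # constant phenotype on complete cases
  perfect <- RSSf <= tol & !degenerate
  perfect_add <- RSSa <= tol & !degenerate

  half_n <- pre$N / 2
  lod_full <- half_n * log10(RSS0 / RSSf)
  lod_add <- half_n * log10(RSS0 / pmax(RSSa, tol))
  lod_int <- half_n * log10(RSSa / RSSf)
  lod_full[perfect] <- Inf
  lod_int[perfect] <- NA_real_
  # additive model itself perfect: no interaction evidence at all
  lod_add[perfect_add] <- Inf
  lod_int[perfect & perfect_add] <- 0
  lod_full[degenerate] <- 0; lod_add[degenerate] <- 0
  lod_int[degenerate] <- 0
  lod_full[!pre$valid] <- NA; lod_add[!pre$valid] <- NA
  lod_int[!pre$valid] <- NA

  list(lod_full = lod_full, lod_add = lod_add, lod_int = lod_int,
       perfect = perfect)
}

# Per-marker single-QTL statistics for one phenotype vector.
.scan1_core <- function(ind1, y) {
  Sr <- lapply(ind1$G, function(g) as.numeric(crossprod(g, y)))
  nr <- lapply(ind1$G, colSums)
  T2 <- as.numeric(crossprod(ind1$obs, y * y))
  nm <- colSums(ind1$obs)
  SS1 <- Reduce(`+`, Map(function(s, n) ifelse(n > 0, s^2 / n, 0), Sr, nr))
  Sy <- Reduce(`+`, Sr)
  RSS0 <- T2 - ifelse(nm > 0, Sy^2 / nm, 0)
  RSS1 <- pmax(T2 - SS1, 0)
  nclass <- Reduce(`+`, lapply(nr, function(n) (n > 0) + 0L))
  tol <- 1e-12 * pmax(T2, 1)
  lod <- (nm / 2) * log10(RSS0 / RSS1)
  lod[RSS1 <= tol & RSS0 > tol] <- Inf
  lod[RSS0 <= tol] <- 0
  lod[nclass < 2] <- 0
  lod[nm == 0] <- 0
  list(lod = lod, n_used = nm, n_classes = nclass)
}

#' Single-QTL genome scan
#'
#' Fits, at every marker, the three-genotype-class means model against the
#' grand mean on the complete cases for that marker and reports the LOD
#' score.  Markers at which fewer than two genotype classes are observed
#' get LOD 0 with a flag (and a warning); markers with a perfect fit
#' (zero residual) are flagged `perfect_fit` with `lod = Inf`.
#'
#' @param cross a `cross_data` with phenotype set.
#' @param include_parental include the parental-average rows (default, as
#'   in a 117-row analysis of 115 F2 plus two strain averages).
#' @return a data frame of class `scan1_result` with columns `marker`,
#'   `chr`, `pos_cM`, `lod`, `n_used`, `n_classes`, `flag`.
#' @export
scan_one <- function(cross, include_parental = TRUE) {
  if (is.null(cross$phenotype)) stop("phenotype must be set")
  rows <- .scan_rows(cross, include_parental)
  y <- cross$phenotype[rows]
  if (length(unique(y)) < 2)
    stop("phenotype must take at least two distinct values")
  ind1 <- .geno_indicators(cross$geno[rows, , drop = FALSE])
  st <- .scan1_core(ind1, y)
  flag <- rep("ok", length(st$lod))
  flag[st$n_classes < 2] <- "too_few_classes"
  flag[st$n_used == 0] <- "all_missing"
  flag[is.infinite(st$lod)] <- "perfect_fit"
  if (any(flag == "too_few_classes" | flag == "all_missing"))
    warning(sum(flag %in% c("too_few_classes", "all_missing")),
            " marker(s) with <2 observed genotype classes; lod set to 0")
  out <- data.frame(marker = cross$map$marker, chr = cross$map$chr,
                    pos_cM = cross$map$pos_cM, lod = st$lod,
                    n_used = as.integer(st$n_used),
                    n_classes = as.integer(st$n_classes),
                    flag = flag, stringsAsFactors = FALSE)
  class(out) <- c("scan1_result", "data.frame")
  out
}

#' Two-dimensional two-QTL genome scan
#'
#' Scans every unordered pair of distinct markers (optionally excluding
#' same-chromosome pairs closer than `exclude_adjacent_cM`), fitting on the
#' pair's complete cases a full model (one mean per observed cell of the
#' 3x3 joint-genotype table; empty cells contribute no parameters) and an
#' additive model (mean plus marker-a and marker-b main effects).  Reports
#' `lod_full`, `lod_add` and their difference `lod_int`, the epistasis
#' signal.  Pairs with fewer than two observed joint classes are flagged
#' with all LODs 0; a zero full-model residual is flagged `perfect_fit`
#' (`lod_full = Inf`, `lod_int = NA`).
#'
#' @inheritParams scan2_precompute
#' @param pre optional precomputed structure from [scan2_precompute()].
#' @return a data frame of class `scan2_result` with one row per scanned
#'   pair: `marker_a`, `marker_b`, chromosome/position columns,
#'   `lod_full`, `lod_add`, `lod_int`, `n_used`, `n_classes`, `flag`.
#' @export
scan_two <- function(cross, exclude_adjacent_cM = 0,
                     include_parental = TRUE, pre = NULL) {
  if (is.null(cross$phenotype)) stop("phenotype must be set")
  if (is.null(pre))
    pre <- scan2_precompute(cross, exclude_adjacent_cM, include_parental)
  y <- cross$phenotype[pre$rows]
  if (length(unique(y)) < 2)
    stop("phenotype must take at least two distinct values")
  cl <- .scan2_core(pre, y)

  lin <- which(pre$scanned)
  ij <- arrayInd(lin, dim(pre$N))
  a <- ij[, 1]; b <- ij[, 2]
  map <- pre$map
  ok <- pre$valid[lin]
  lf <- ifelse(ok, cl$lod_full[lin], 0)
  la <- ifelse(ok, cl$lod_add[lin], 0)
  li <- ifelse(ok, cl$lod_int[lin], 0)
  flag <- rep("ok", length(lin))
  flag[!ok] <- "too_few_classes"
  flag[ok & cl$perfect[lin]] <- "perfect_fit"
  out <- data.frame(
    marker_a = map$marker[a], marker_b = map$marker[b],
    chr_a = map$chr[a], chr_b = map$chr[b],
    pos_a = map$pos_cM[a], pos_b = map$pos_cM[b],
    lod_full = lf, lod_add = la, lod_int = li,
    n_used = as.integer(pre$N[lin]),
    n_classes = as.integer(pre$nclass[lin]),
    flag = flag, stringsAsFactors = FALSE)
  class(out) <- c("scan2_result", "data.frame")
  out
}

#' Genome-wide permutation thresholds
#'
#' Estimates the genome-wide null distribution of the maximum scan
#' statistic by permuting the phenotype vector uniformly among all mice
#' while keeping genotypes fixed.  For each permutation the genome-wide
#' maximum of the chosen statistic is recorded; the threshold is the
#' empirical `1 - alpha` quantile of these maxima
#' (linear-interpolation quantile, type 7).  Markers or pairs with an
#' infinite (perfect-fit) LOD are excluded from the maxima.
#'
#' For `statistic = "max_1d"` the per-permutation statistic is the
#' maximum single-QTL LOD over markers.  For `statistic = "max_int"` it
#' is the maximum over chromosome pairs of the pair's interaction LOD,
#' defined -- as in standard two-QTL mapping software -- as the maximum
#' full LOD over the chromosome pair's two-locus surface minus the
#' maximum additive LOD over the same surface, the two maxima taken
#' separately (see [chrpair_interaction()]).  Observed scans are
#' compared with the threshold on the same statistic.
#'
#' @param cross a `cross_data` with phenotype set.
#' @param n_perm number of permutations (>= 10).
#' @param alpha genome-wide significance level in `(0, 1]`.
#' @param seed integer seed; identical seeds give identical thresholds.
#' @param statistic `"max_int"` (two-QTL interaction LOD) or `"max_1d"`
#'   (single-QTL LOD).
#' @param exclude_adjacent_cM,include_parental as in [scan_two()].
#' @param pre optional precomputed structure from [scan2_precompute()]
#'   (used only for `statistic = "max_int"`).
#' @return an object of class `perm_thresholds` with fields `alpha`,
#'   `n_perm`, `statistic`, `threshold_1d`, `threshold_int`, `maxima`,
#'   `seed`.
#' @export
permutation_thresholds <- function(cross, n_perm = 1000, alpha = 0.05,
                                   seed = 1L,
                                   statistic = c("max_int", "max_1d"),
                                   exclude_adjacent_cM = 0,
                                   include_parental = TRUE, pre = NULL) {
  statistic <- match.arg(statistic)
  if (!(alpha > 0 && alpha <= 1)) stop("`alpha` must lie in (0, 1]")
  n_perm <- as.integer(n_perm)
  if (n_perm < 10L) stop("`n_perm` must be at least 10")
  if (is.null(cross$phenotype)) stop("phenotype must be set")

  if (statistic == "max_int") {
    if (is.null(pre))
      pre <- scan2_precompute(cross, exclude_adjacent_cM, include_parental)
    rows <- pre$rows
  } else {
    rows <- .scan_rows(cross, include_parental)
    ind1 <- .geno_indicators(cross$geno[rows, , drop = FALSE])
  }
  y <- cross$phenotype[rows]
  n <- length(y)
  maxima <- numeric(n_perm)
  withr::with_seed(as.integer(seed), {
    for (p in seq_len(n_perm)) {
      yp <- y[sample.int(n)]
      if (statistic == "max_int") {
        cl <- .scan2_core(pre, yp)
        mi <- .chrpair_mi(cl$lod_full[pre$lin_valid],
                          cl$lod_add[pre$lin_valid], pre$blocks)
        vals <- mi[is.finite(mi)]
      } else {
        l1 <- .scan1_core(ind1, yp)$lod
        vals <- l1[is.finite(l1)]
      }
      maxima[p] <- if (length(vals)) max(vals) else 0
    }
  })
  thr <- as.numeric(stats::quantile(maxima, 1 - alpha, type = 7,
                                    names = FALSE))
  structure(list(
    alpha = alpha, n_perm = n_perm, statistic = statistic,
    threshold_1d = if (statistic == "max_1d") thr else NA_real_,
    threshold_int = if (statistic == "max_int") thr else NA_real_,
    maxima = maxima, seed = as.integer(seed)), class = "perm_thresholds")
}

#' @export
print.perm_thresholds <- function(x, ...) {
  thr <- if (x$statistic == "max_int") x$threshold_int else x$threshold_1d
  cat(sprintf(
    "permutation threshold (%s): %.3f at alpha = %g (%d permutations)\n",
    x$statistic, thr, x$alpha, x$n_perm))
  invisible(x)
}

#' Chromosome-pair interaction LOD summary
#'
#' Summarises a two-QTL scan at the chromosome-pair level using the
#' convention of standard two-QTL mapping software: for each pair of
#' chromosomes, `lod_int = max(lod_full) - max(lod_add)` over the pair's
#' two-locus surface, the maxima taken separately (infinite perfect-fit
#' LODs excluded).  This is the statistic against which the genome-wide
#' interaction permutation threshold is calibrated.
#'
#' @param result a `scan2_result` from [scan_two()].
#' @return data frame with one row per chromosome pair: `chr_a`,
#'   `chr_b`, `lod_full_max`, `lod_add_max`, `lod_int`, sorted by
#'   decreasing `lod_int`.
#' @export
chrpair_interaction <- function(result) {
  ok <- result$flag != "too_few_classes"
  df <- result[ok, , drop = FALSE]
  key <- paste(df$chr_a, df$chr_b, sep = "\r")
  mx <- function(v) {
    v <- v[is.finite(v)]
    if (length(v)) max(v) else -Inf
  }
  lf <- tapply(df$lod_full, key, mx)
  la <- tapply(df$lod_add, key, mx)
  parts <- do.call(rbind, strsplit(names(lf), "\r", fixed = TRUE))
  out <- data.frame(chr_a = parts[, 1], chr_b = parts[, 2],
                    lod_full_max = as.numeric(lf),
                    lod_add_max = as.numeric(la),
                    lod_int = as.numeric(lf) - as.numeric(la),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$lod_int), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank marker pairs by interaction LOD
#'
#' Sorts a two-QTL scan by decreasing pointwise interaction LOD (flagged
#' pairs with undefined `lod_int` last), breaking ties lexicographically
#' by `(chr_a, pos_a, chr_b, pos_b)`.  Each pair is marked significant
#' when the interaction LOD of its chromosome pair (see
#' [chrpair_interaction()], the statistic the permutation threshold is
#' calibrated on) exceeds the threshold.
#'
#' @param result a `scan2_result` from [scan_two()].
#' @param thresholds a `perm_thresholds` computed with
#'   `statistic = "max_int"`.
#' @return the scan rows sorted, with columns `lod_int_chrpair` and
#'   logical `significant` appended.
#' @export
peak_pair <- function(result, thresholds) {
  if (nrow(result) == 0L) {
    result$lod_int_chrpair <- numeric(0)
    result$significant <- logical(0)
    return(result)
  }
  thr <- thresholds$threshold_int
  if (is.na(thr)) stop("thresholds must be computed for statistic max_int")
  chr_key <- function(ch) {
    k <- suppressWarnings(as.numeric(ch))
    ifelse(is.na(k), rank(ch), k)
  }
  cp <- chrpair_interaction(result)
  cpv <- stats::setNames(cp$lod_int, paste(cp$chr_a, cp$chr_b, sep = "\r"))
  li <- result$lod_int
  li_sort <- ifelse(result$flag == "perfect_fit", -Inf, li)
  ord <- order(-li_sort, chr_key(result$chr_a), result$pos_a,
               chr_key(result$chr_b), result$pos_b)
  out <- result[ord, , drop = FALSE]
  out$lod_int_chrpair <-
    as.numeric(cpv[paste(out$chr_a, out$chr_b, sep = "\r")])
  out$significant <- !is.na(out$lod_int_chrpair) &
    is.finite(out$lod_int_chrpair) & out$flag != "too_few_classes" &
    out$lod_int_chrpair > thr
  rownames(out) <- NULL
  out
}
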