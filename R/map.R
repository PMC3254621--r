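#' Approximate mouse autosome lengths
#'
#' Physical lengths of the 19 mouse autosomes in megabases (rounded to the
#' nearest Mb, GRCm38 scale).  These lengths drive the proportional
#' allocation of markers in [make_map()] and provide chromosome bounds for
#' interval clamping.
#'
#' @param n_autosomes number of autosomes to return (1--19).
#' @return named numeric vector of lengths in base pairs; names are
#'   chromosome identifiers `"1"`..`"19"`.
#' @export
mouse_chrom_lengths_bp <- function(n_autosomes = 19L) {
  stopifnot(n_autosomes >= 1L, n_autosomes <= 19L)
  mb <- c(195, 182, 160, 157, 152, 150, 145, 130, 124, 131,
          122, 120, 121, 125, 104, 98, 95, 91, 61)
  out <- mb[seq_len(n_autosomes)] * 1e6
  names(out) <- as.character(seq_len(n_autosomes))
  out
}

# Largest-remainder allocation of n items proportional to weights,
# guaranteeing at least one item per class.  Deterministic (ties by index).
allocate_proportional <- function(n, weights) {
  k <- length(weights)
  stopifnot(n >= k, all(weights > 0))
  quota <- n * weights / sum(weights)
  alloc <- pmax(1L, floor(quota))
  # repair the total while keeping every class at >= 1
  while (sum(alloc) < n) {
    rem <- quota - alloc
    i <- which.max(rem)
    alloc[i] <- alloc[i] + 1L
  }
  while (sum(alloc) > n) {
    rem <- quota - alloc
    cand <- which(alloc > 1L)
    i <- cand[which.min(rem[cand])]
    alloc[i] <- alloc[i] - 1L
  }
  as.integer(alloc)
}

#' Build a synthetic SNP marker map
#'
#' Lays out `n_markers_total` markers over `n_autosomes` autosomes,
#' allocating markers to chromosomes proportionally to their physical
#' lengths (largest-remainder rule, at least one marker per chromosome) and
#' spacing them uniformly at `spacing_mb` megabases.  Genetic positions are
#' derived from physical positions with a constant recombination rate:
#' `pos_cM = pos_bp * cm_per_mb * 1e-6`.
#'
#' The defaults emulate a genome-wide mouse SNP panel of 384 markers over
#' the 19 autosomes.  The default spacing of 6.5 Mb is approximately the
#' total autosomal length divided by 384.
#'
#' @param n_autosomes number of autosomes (1--19).
#' @param n_markers_total total number of markers; must be at least
#'   `n_autosomes`.
#' @param spacing_mb uniform physical spacing between adjacent markers, Mb.
#' @param cm_per_mb constant genetic-to-physical rate (cM per Mb); the
#'   mouse genome-wide average is about 0.5.
#' @param seed accepted for interface uniformity with the other
#'   generators; the map construction is fully deterministic.
#' @return a `genetic_map`: data frame with columns `marker`, `chr`
#'   (character), `pos_cM`, `pos_bp`, ordered by chromosome then position.
#' @examples
#' map <- make_map(n_autosomes = 2, n_markers_total = 10, spacing_mb = 5)
#' table(map$chr)
#' @export
make_map <- function(n_autosomes = 19L, n_markers_total = 384L,
                     spacing_mb = 6.5, cm_per_mb = 0.5, seed = 1L) {
  if (!is.numeric(spacing_mb) || length(spacing_mb) != 1L || spacing_mb <= 0)
    stop("`spacing_mb` must be a positive scalar")
  if (!is.numeric(cm_per_mb) || length(cm_per_mb) != 1L || cm_per_mb <= 0)
    stop("`cm_per_mb` must be a positive scalar")
  n_autosomes <- as.integer(n_autosomes)
  n_markers_total <- as.integer(n_markers_total)
  if (n_autosomes < 1L) stop("`n_autosomes` must be positive")
  if (n_markers_total < n_autosomes)
    stop("`n_markers_total` must be at least `n_autosomes`")

  lens <- mouse_chrom_lengths_bp(min(n_autosomes, 19L))
  if (n_autosomes > 19L) stop("at most 19 autosomes are supported")
  alloc <- allocate_proportional(n_markers_total, lens)

  pieces <- lapply(seq_len(n_autosomes), function(ch) {
    k <- alloc[ch]
    idx <- seq_len(k)
    pos_bp <- as.integer(round(idx * spacing_mb * 1e6))
    data.frame(
      marker = sprintf("c%02dm%03d", ch, idx),
      chr = as.character(ch),
      pos_cM = pos_bp * cm_per_mb * 1e-6,
      pos_bp = pos_bp,
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, pieces)
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  validate_genetic_map(map)
  map
}

#' Validate a genetic map
#'
#' Checks the structural invariants of a marker map: unique marker ids and,
#' within every chromosome, strictly increasing genetic and physical
#' positions.
#'
#' @param map a `genetic_map` or data frame with columns `marker`, `chr`,
#'   `pos_cM`, `pos_bp`.
#' @return the map, invisibly; errors on violation.
#' @export
validate_genetic_map <- function(map) {
  need <- c("marker", "chr", "pos_cM", "pos_bp")
  if (!all(need %in% names(map)))
    stop("map must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(map$marker))
    stop("marker ids must be unique genome-wide")
  if (any(map$pos_cM < 0) || any(map$pos_bp <= 0))
    stop("positions must be non-negative (cM) and positive (bp)")
  for (ch in unique(map$chr)) {
    sub <- map[map$chr == ch, , drop = FALSE]
    if (nrow(sub) > 1L) {
      if (any(diff(sub$pos_cM) <= 0) || any(diff(sub$pos_bp) <= 0))
        stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  invisible(map)
}

#' Haldane map function
#'
#' Converts a genetic distance in centimorgans to a recombination fraction
#' under the no-interference (Haldane) model:
#' `r = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param d_cM genetic distance(s) in cM.
#' @return recombination fraction(s) in `[0, 0.5)`.
#' @export
haldane_r <- function(d_cM) {
  stopifnot(all(d_cM >= 0))
  (1 - exp(-2 * d_cM / 100)) / 2
}
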