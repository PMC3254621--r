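#' @title Haplotype windows around interacting loci
#' @description
#' After the two-QTL scan identifies a pair of interacting markers, the
#' linked region at each locus is delimited from the haplotypes of the
#' high-responder animals: the mice homozygous AA at both peak markers.
#' The locus is taken to extend throughout the contiguous run of markers
#' at which no crossover is observed in any of those mice, then extended
#' by a physical flank (default 1 Mb) to capture distal regulatory
#' elements, and finally mapped to the genes it overlaps.
#' @name locus_windows
NULL

#' Select high-responder double-homozygous mice
#'
#' Returns the mice whose genotype is AA at both peak markers (missing
#' genotypes do not qualify).  Parental-average rows are included by
#' default; the all-AA `parental_A` row always qualifies.
#'
#' @param cross a `cross_data`.
#' @param marker_a,marker_b peak marker ids.
#' @param include_parental include parental-average rows.
#' @return character vector of mouse ids (possibly empty, with a warning).
#' @export
select_high_responders <- function(cross, marker_a, marker_b,
                                   include_parental = TRUE) {
  ia <- match(marker_a, cross$map$marker)
  ib <- match(marker_b, cross$map$marker)
  if (is.na(ia) || is.na(ib)) stop("peak markers must exist in the map")
  rows <- .scan_rows(cross, include_parental)
  g <- cross$geno[rows, , drop = FALSE]
  sel <- !is.na(g[, ia]) & !is.na(g[, ib]) & g[, ia] == 1L & g[, ib] == 1L
  ids <- cross$mouse_ids[rows][sel]
  if (length(ids) == 0L)
    warning("no mouse is homozygous AA at both peak markers")
  ids
}

#' Non-recombinant haplotype span
#'
#' Finds the maximal contiguous run of markers on a chromosome, containing
#' the peak marker, at which every selected mouse carries the AA genotype.
#' A missing genotype is compatible with the run (a crossover must be
#' observed to delimit the span); an observed AB or BB genotype in any
#' selected mouse terminates it.
#'
#' @param cross a `cross_data`.
#' @param mice character ids of the selected (high-responder) mice.
#' @param chromosome chromosome carrying the peak marker.
#' @param peak_marker marker id of the linkage peak; every selected mouse
#'   must be observed AA there.
#' @return character vector `c(first_marker, last_marker)` delimiting the
#'   span (marker ids, in map order).
#' @export
nonrecombinant_span <- function(cross, mice, chromosome, peak_marker) {
  if (length(mice) == 0L) stop("mouse subset must be non-empty")
  ridx <- match(mice, cross$mouse_ids)
  if (anyNA(ridx)) stop("unknown mouse id(s)")
  on_chr <- which(cross$map$chr == chromosome)
  if (length(on_chr) == 0L) stop("chromosome not in map")
  peak_pos <- match(peak_marker, cross$map$marker[on_chr])
  if (is.na(peak_pos))
    stop("peak marker must lie on the stated chromosome")
  g <- cross$geno[ridx, on_chr, drop = FALSE]
  if (!all(!is.na(g[, peak_pos]) & g[, peak_pos] == 1L))
    stop("contract violation: selected mice must all be AA at the peak marker")
  compatible <- apply(g, 2L, function(col) all(is.na(col) | col == 1L))
  lo <- peak_pos
  while (lo > 1L && compatible[lo - 1L]) lo <- lo - 1L
  hi <- peak_pos
  while (hi < length(on_chr) && compatible[hi + 1L]) hi <- hi + 1L
  cross$map$marker[on_chr][c(lo, hi)]
}

#' Extend a marker span into a genomic interval
#'
#' Converts a marker-delimited span into physical coordinates and extends
#' it by `flank_bp` (default 1 Mb) to account for distal regulatory
#' elements, clamping to the chromosome bounds.  In `one_sided` mode only
#' the telomeric (high-coordinate) end is extended.
#'
#' @param span character vector `c(first_marker, last_marker)`.
#' @param map a `genetic_map` containing both markers on one chromosome.
#' @param flank_bp non-negative extension in bp.
#' @param chrom_length_bp chromosome length for clamping; defaults to the
#'   built-in mouse autosome length when the chromosome is `"1"`..`"19"`.
#' @param one_sided extend only the telomeric end.
#' @return a `genomic_interval`: list with `chromosome`, `start_bp`,
#'   `end_bp` (1-based inclusive), `anchor_markers`, `provenance`.
#' @export
extend_interval <- function(span, map, flank_bp = 1e6,
                            chrom_length_bp = NULL, one_sided = FALSE) {
  stopifnot(length(span) == 2L, flank_bp >= 0)
  i <- match(span, map$marker)
  if (anyNA(i)) stop("span markers must exist in the map")
  if (map$chr[i[1]] != map$chr[i[2]])
    stop("span markers must lie on one chromosome")
  chrom <- map$chr[i[1]]
  lo <- min(map$pos_bp[i]); hi <- max(map$pos_bp[i])
  if (is.null(chrom_length_bp)) {
    lens <- mouse_chrom_lengths_bp()
    chrom_length_bp <- if (chrom %in% names(lens)) lens[[chrom]]
      else max(map$pos_bp[map$chr == chrom]) + flank_bp
  }
  start_bp <- if (one_sided) lo else max(1, lo - flank_bp)
  end_bp <- min(chrom_length_bp, hi + flank_bp)
  structure(list(
    chromosome = chrom, start_bp = as.numeric(start_bp),
    end_bp = as.numeric(end_bp),
    anchor_markers = c(map$marker[min(i)], map$marker[max(i)]),
    provenance = sprintf("non-recombinant span %s-%s %s %g bp",
                         span[1], span[2],
                         if (one_sided) "plus telomeric flank" else "plus flank",
                         flank_bp)),
    class = "genomic_interval")
}

#' Genes overlapping an interval
#'
#' Returns the annotation records whose span overlaps the interval by at
#' least 1 bp (any-overlap rule, strand ignored), deduplicated by gene id
#' and sorted by start coordinate.  Overlap is computed with
#' GenomicRanges.
#'
#' @param annotation data frame with columns `gene_id`, `symbol`,
#'   `chromosome`, `start_bp`, `end_bp` (1-based inclusive).
#' @param interval a `genomic_interval`.
#' @return the overlapping annotation rows (possibly zero rows; a warning
#'   is issued if the chromosome is absent from the annotation).
#' @export
genes_in_interval <- function(annotation, interval) {
  empty <- annotation[0, , drop = FALSE]
  if (nrow(annotation) == 0L) return(empty)
  if (!interval$chromosome %in% annotation$chromosome) {
    warning("chromosome ", interval$chromosome, " absent from annotation")
    return(empty)
  }
  gr_ann <- GenomicRanges::GRanges(
    annotation$chromosome,
    IRanges::IRanges(annotation$start_bp, annotation$end_bp))
  gr_int <- GenomicRanges::GRanges(
    interval$chromosome,
    IRanges::IRanges(interval$start_bp, interval$end_bp))
  hits <- S4Vectors::queryHits(GenomicRanges::findOverlaps(gr_ann, gr_int))
  out <- annotation[sort(unique(hits)), , drop = FALSE]
  out <- out[!duplicated(out$gene_id), , drop = FALSE]
  out <- out[order(out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a gene annotation
#'
#' Reads gene records either from BED (0-based half-open; converted to
#' 1-based inclusive coordinates on read, via rtracklayer) or from a
#' 1-based TSV with header columns `gene_id`, `symbol`, `chromosome`,
#' `start_bp`, `end_bp`.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"bed"` or `"tsv"`.
#' @return annotation data frame (1-based inclusive coordinates).
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    ann <- data.frame(
      gene_id = gr$name, symbol = gr$name,
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start_bp = GenomicRanges::start(gr),
      end_bp = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  } else {
    ann <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "#",
                             colClasses = c(chromosome = "character"))
  }
  if (anyDuplicated(ann$gene_id)) stop("gene ids must be unique")
  if (any(ann$start_bp > ann$end_bp)) stop("gene start must not exceed end")
  ann
}

#' Write a gene annotation
#'
#' Writes either BED (converting back to 0-based half-open, via
#' rtracklayer) or the 1-based TSV dialect.
#'
#' @param annotation annotation data frame (1-based inclusive).
#' @param path output file.
#' @param format `"bed"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annotation, path,
                                  format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    gr <- GenomicRanges::GRanges(
      annotation$chromosome,
      IRanges::IRanges(annotation$start_bp, annotation$end_bp),
      name = annotation$gene_id)
    rtracklayer::export(gr, path, format = "BED")
  } else {
    utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Generate a synthetic gene annotation along a map
#'
#' Tiles genes along every chromosome of the map at a regular spacing,
#' with seeded gene lengths, and guarantees a gene overlapping each
#' position in `anchor_bp` (used to plant genes at linkage peaks).
#'
#' @param map a `genetic_map`.
#' @param spacing_bp distance between consecutive gene starts.
#' @param length_range min/max gene length in bp.
#' @param anchor_bp optional data frame (`chromosome`, `pos_bp`, `gene_id`)
#'   of guaranteed genes centred on the given positions.
#' @param seed integer seed.
#' @return annotation data frame (`gene_id`, `symbol`, `chromosome`,
#'   `start_bp`, `end_bp`).
#' @export
make_annotation <- function(map, spacing_bp = 2e6,
                            length_range = c(2e4, 2e5),
                            anchor_bp = NULL, seed = 1L) {
  stopifnot(spacing_bp > 0)
  pieces <- list()
  withr::with_seed(as.integer(seed), {
    for (ch in unique(map$chr)) {
      span_end <- max(map$pos_bp[map$chr == ch])
      starts <- seq(1e5, span_end, by = spacing_bp)
      lens <- round(stats::runif(length(starts), length_range[1],
                                 length_range[2]))
      pieces[[ch]] <- data.frame(
        gene_id = sprintf("G%s_%03d", ch, seq_along(starts)),
        symbol = sprintf("Gene%s.%03d", ch, seq_along(starts)),
        chromosome = ch, start_bp = starts,
        end_bp = starts + lens, stringsAsFactors = FALSE)
    }
  })
  ann <- do.call(rbind, pieces)
  if (!is.null(anchor_bp)) {
    anch <- data.frame(
      gene_id = anchor_bp$gene_id, symbol = anchor_bp$gene_id,
      chromosome = as.character(anchor_bp$chromosome),
      start_bp = pmax(1, anchor_bp$pos_bp - 5e4),
      end_bp = anchor_bp$pos_bp + 5e4, stringsAsFactors = FALSE)
    ann <- rbind(ann, anch)
  }
  rownames(ann) <- NULL
  ann
}

#' One-to-one gene-to-protein identifier mapping
#'
#' Builds the mapping table linking annotation gene ids to opaque protein
#' ids; genes without a protein product can be simulated by dropping a
#' seeded fraction (mirroring the exclusion of ESTs, predicted genes and
#' microRNAs from a real identifier space).
#'
#' @param annotation annotation data frame.
#' @param drop_rate fraction of genes left unmapped.
#' @param seed integer seed.
#' @return data frame with columns `gene_id`, `protein_id`.
#' @export
make_gene_protein_map <- function(annotation, drop_rate = 0, seed = 1L) {
  stopifnot(drop_rate >= 0, drop_rate < 1)
  keep <- rep(TRUE, nrow(annotation))
  if (drop_rate > 0)
    withr::with_seed(as.integer(seed),
                     keep <- stats::runif(nrow(annotation)) >= drop_rate)
  data.frame(gene_id = annotation$gene_id[keep],
             protein_id = paste0("PR_", annotation$gene_id[keep]),
             stringsAsFactors = FALSE)
}
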