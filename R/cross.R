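#' @title F2 cross container
#' @description Genotype codes are stored internally as integers
#'   (1 = AA, 2 = AB, 3 = BB, NA = missing), where A denotes the
#'   high-responder founder strain (A/J) and B the low-responder strain
#'   (C57BL/6J).
#' @name cross_data
NULL

GENO_LEVELS <- c("AA", "AB", "BB")
MISSING_CODE <- "-"

#' Construct a cross_data object
#'
#' Bundles a marker map, a mouse-by-marker genotype matrix, an optional
#' phenotype vector (airway responsiveness, one positive value per mouse),
#' mouse identifiers and per-mouse origin labels (`F2`, `parental_A`,
#' `parental_B`).
#'
#' @param map a `genetic_map` (see [make_map()]).
#' @param geno integer matrix, mice in rows, markers in columns; entries
#'   1/2/3/NA for AA/AB/BB/missing.
#' @param phenotype optional numeric vector of positive values, one per
#'   mouse.
#' @param mouse_ids unique character ids; defaults to `F2_001`, ...
#' @param origin per-mouse labels in `F2`, `parental_A`, `parental_B`.
#' @param check_parental verify that parental rows are pure AA / BB.
#' @return an object of class `cross_data`.
#' @export
new_cross <- function(map, geno, phenotype = NULL, mouse_ids = NULL,
                      origin = NULL, check_parental = TRUE) {
  validate_genetic_map(map)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n <- nrow(geno)
  if (ncol(geno) != nrow(map))
    stop("genotype matrix must have one column per map marker")
  if (is.null(mouse_ids)) mouse_ids <- sprintf("F2_%03d", seq_len(n))
  if (is.null(origin)) origin <- rep("F2", n)
  dimnames(geno) <- list(mouse_ids, map$marker)
  cross <- structure(
    list(map = map, geno = geno, phenotype = phenotype,
         mouse_ids = mouse_ids, origin = origin),
    class = "cross_data"
  )
  validate_cross(cross, check_parental = check_parental)
  cross
}

#' Validate a cross_data object
#'
#' @param cross a `cross_data`.
#' @param check_parental if `TRUE`, require parental_A rows to be AA at
#'   every marker and parental_B rows BB at every marker.  Constructors use
#'   this; deliberately perturbed fixtures (see
#'   [inject_missing_and_errors()]) are validated structurally only.
#' @return the cross, invisibly.
#' @export
validate_cross <- function(cross, check_parental = TRUE) {
  with(cross, {
    n <- length(mouse_ids)
    if (anyDuplicated(mouse_ids)) stop("mouse ids must be unique")
    if (nrow(geno) != n || length(origin) != n)
      stop("genotype rows, ids and origin labels must align")
    if (ncol(geno) != nrow(map))
      stop("genotype matrix dimensions must match the map")
    bad <- !(geno %in% c(1L, 2L, 3L)) & !is.na(geno)
    if (any(bad)) stop("genotype codes must be 1 (AA), 2 (AB), 3 (BB) or NA")
    if (!all(origin %in% c("F2", "parental_A", "parental_B")))
      stop("origin labels must be F2, parental_A or parental_B")
    if (!is.null(phenotype)) {
      if (length(phenotype) != n)
        stop("phenotype length must equal the number of mice")
      if (any(!is.finite(phenotype)) || any(phenotype <= 0))
        stop("phenotype values must be finite and positive")
    }
    if (check_parental) {
      pa <- origin == "parental_A"
      pb <- origin == "parental_B"
      if (any(pa) && !isTRUE(all(geno[pa, , drop = FALSE] == 1L)))
        stop("parental_A rows must be AA at every marker")
      if (any(pb) && !isTRUE(all(geno[pb, , drop = FALSE] == 3L)))
        stop("parental_B rows must be BB at every marker")
    }
  })
  invisible(cross)
}

#' @export
print.cross_data <- function(x, ...) {
  cat(sprintf(
    "F2 cross: %d mice (%d F2, %d parental) x %d markers on %d chromosome(s)\n",
    length(x$mouse_ids), sum(x$origin == "F2"),
    sum(x$origin != "F2"), ncol(x$geno), length(unique(x$map$chr))))
  cat(if (is.null(x$phenotype)) "phenotype: unset\n"
      else sprintf("phenotype: set (mean %.3g)\n", mean(x$phenotype)))
  invisible(x)
}

#' Append one average mouse per parental strain
#'
#' Adds two rows to an F2 cross: a `parental_A` mouse that is AA at every
#' marker and a `parental_B` mouse that is BB at every marker.  These rows
#' stand in for the strain averages so that each parental strain
#' contributes exactly one observation to the genome scans.  Their
#' phenotypes are assigned by [simulate_phenotype()] as the corresponding
#' model means.
#'
#' @param cross a `cross_data` without parental rows.
#' @return a `cross_data` with two additional rows.
#' @export
add_parental_averages <- function(cross) {
  if (any(cross$origin != "F2"))
    stop("cross already contains parental rows")
  m <- ncol(cross$geno)
  geno <- rbind(cross$geno, rep(1L, m), rep(3L, m))
  ids <- c(cross$mouse_ids, "parental_A", "parental_B")
  origin <- c(cross$origin, "parental_A", "parental_B")
  phen <- if (is.null(cross$phenotype)) NULL else
    c(cross$phenotype, NA_real_, NA_real_)
  if (!is.null(phen)) stop("add parental rows before simulating phenotypes")
  new_cross(cross$map, geno, NULL, ids, origin)
}

#' Write a cross to CSV
#'
#' Writes the standard comma-separated cross layout: the first header row
#' carries the phenotype/covariate column names followed by marker ids, the
#' second row the chromosome of each marker (blank for non-marker columns),
#' the third row the cM position; data rows follow with the phenotype in
#' the first column, then mouse id and origin, then genotype codes
#' `AA`/`AB`/`BB` with missing values written as `-`.
#'
#' @param cross a `cross_data` with phenotype set (use `NA` rows otherwise).
#' @param path output file.
#' @param comment optional `# `-prefixed header line (e.g. seed provenance).
#' @return `path`, invisibly.
#' @export
write_cross_csv <- function(cross, path, comment = NULL) {
  map <- cross$map
  gchar <- matrix(GENO_LEVELS[cross$geno], nrow = nrow(cross$geno))
  gchar[is.na(gchar)] <- MISSING_CODE
  phen <- if (is.null(cross$phenotype))
    rep("", length(cross$mouse_ids)) else format(cross$phenotype, digits = 15)
  header1 <- c("ar", "id", "origin", map$marker)
  header2 <- c("", "", "", map$chr)
  header3 <- c("", "", "", format(map$pos_cM, digits = 15))
  body <- cbind(phen, cross$mouse_ids, cross$origin, gchar)
  lines <- c(
    if (!is.null(comment)) paste0("# ", comment),
    paste(header1, collapse = ","),
    paste(header2, collapse = ","),
    paste(header3, collapse = ","),
    apply(body, 1L, paste, collapse = ",")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a cross from CSV
#'
#' Reads the layout written by [write_cross_csv()].  Columns whose
#' chromosome row is blank are treated as phenotype/covariate columns; a
#' column named `ar` is the phenotype, `id` and `origin` are recognised if
#' present.  Physical marker positions are taken from a companion
#' tab-separated file (see [write_marker_positions()]); if absent, bp
#' positions are reconstructed from cM assuming `cm_per_mb`.
#'
#' @param path cross CSV file.
#' @param bp_path optional marker position TSV (`marker`, `chr`, `pos_bp`).
#' @param cm_per_mb fallback rate for reconstructing bp from cM.
#' @return a `cross_data`.
#' @export
read_cross_csv <- function(path, bp_path = NULL, cm_per_mb = 0.5) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  cells <- strsplit(lines, ",", fixed = TRUE)
  hdr <- cells[[1]]
  chrrow <- cells[[2]]
  cmrow <- cells[[3]]
  length(chrrow) <- length(hdr); length(cmrow) <- length(hdr)
  chrrow[is.na(chrrow)] <- ""; cmrow[is.na(cmrow)] <- ""
  is_marker <- chrrow != ""
  markers <- hdr[is_marker]
  body <- do.call(rbind, lapply(cells[-(1:3)], function(x) {
    length(x) <- length(hdr); x
  }))
  pheno_cols <- which(!is_marker)
  ar_col <- pheno_cols[hdr[pheno_cols] == "ar"]
  id_col <- pheno_cols[hdr[pheno_cols] == "id"]
  or_col <- pheno_cols[hdr[pheno_cols] == "origin"]
  phen <- if (length(ar_col)) suppressWarnings(as.numeric(body[, ar_col])) else NULL
  ids <- if (length(id_col)) body[, id_col] else NULL
  origin <- if (length(or_col)) body[, or_col] else NULL
  gchar <- body[, is_marker, drop = FALSE]
  geno <- matrix(match(gchar, GENO_LEVELS), nrow = nrow(gchar))

  pos_cM <- as.numeric(cmrow[is_marker])
  if (!is.null(bp_path)) {
    bp <- utils::read.table(bp_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "#")
    pos_bp <- bp$pos_bp[match(markers, bp$marker)]
    if (anyNA(pos_bp)) stop("marker position file does not cover all markers")
  } else {
    pos_bp <- as.integer(round(pos_cM / cm_per_mb * 1e6))
  }
  map <- data.frame(marker = markers, chr = chrrow[is_marker],
                    pos_cM = pos_cM, pos_bp = pos_bp,
                    stringsAsFactors = FALSE)
  class(map) <- c("genetic_map", "data.frame")
  if (!is.null(phen) && all(is.na(phen))) phen <- NULL
  # structural validation only: files may carry deliberately perturbed
  # fixtures whose parental rows are no longer pure
  new_cross(map, geno, phen, ids, origin, check_parental = FALSE)
}

#' Write marker physical positions
#'
#' Companion TSV to the cross CSV carrying the physical coordinate of each
#' marker: columns `marker`, `chr`, `pos_bp`.
#'
#' @param map a `genetic_map`.
#' @param path output file.
#' @param comment optional `# `-prefixed header line.
#' @return `path`, invisibly.
#' @export
write_marker_positions <- function(map, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(map[, c("marker", "chr", "pos_bp")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
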