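# The worked haplotype example: six high-responder animals genotyped at
# four consecutive chromosome-11 markers around the linkage peak.  One
# animal is heterozygous at the proximal flanking marker and another is
# homozygous B at the distal one, so the non-recombinant span is the two
# middle markers.
table2_fixture <- function() {
  map <- data.frame(
    marker = c("rs13480836", "rs3659787", "rs13480853", "rs6398304"),
    chr = "11",
    pos_cM = c(30, 31.5, 33, 34.5),
    pos_bp = c(60e6, 63e6, 66e6, 69e6),
    stringsAsFactors = FALSE)
  class(map) <- c("genetic_map", "data.frame")
  geno <- matrix(1L, 6, 4,
                 dimnames = list(sprintf("mouse%d", 1:6), map$marker))
  geno[3, "rs13480836"] <- 2L   # AB
  geno[5, "rs6398304"] <- 3L    # BB
  new_cross(map, geno, mouse_ids = rownames(geno), check_parental = FALSE)
}

test_that("the printed six-animal haplotypes delimit the expected span", {
  cross <- table2_fixture()
  span <- nonrecombinant_span(cross, cross$mouse_ids, "11", "rs13480853")
  expect_equal(span, c("rs3659787", "rs13480853"))
})

test_that("no observed crossover extends the span to the whole chromosome", {
  cross <- table2_fixture()
  cross$geno[] <- 1L
  span <- nonrecombinant_span(cross, cross$mouse_ids, "11", "rs13480853")
  expect_equal(span, c("rs13480836", "rs6398304"))
})

test_that("missing genotypes do not break the run; observed crossovers do", {
  cross <- table2_fixture()
  cross$geno[2, "rs13480836"] <- NA_integer_
  span <- nonrecombinant_span(cross, cross$mouse_ids, "11", "rs13480853")
  # mouse 3 is still AB at the proximal marker
  expect_equal(span, c("rs3659787", "rs13480853"))
  cross$geno[3, "rs13480836"] <- NA_integer_
  span <- nonrecombinant_span(cross, cross$mouse_ids, "11", "rs13480853")
  expect_equal(span, c("rs13480836", "rs13480853"))
})

test_that("a non-AA peak genotype violates the subset contract", {
  cross <- table2_fixture()
  cross$geno[1, "rs13480853"] <- 2L
  expect_error(
    nonrecombinant_span(cross, cross$mouse_ids, "11", "rs13480853"),
    "contract")
})

test_that("span equals the brute-force maximal run on random fixtures", {
  brute <- function(g, peak) {
    comp <- apply(g, 2, function(col) all(is.na(col) | col == 1L))
    runs <- rle(comp)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    k <- which(runs$values & starts <= peak & ends >= peak)
    c(starts[k], ends[k])
  }
  map <- toy_map(1, 6)
  set.seed(99)
  for (rep in 1:300) {
    n_mice <- sample(1:4, 1)
    g <- matrix(sample(c(1L, 1L, 1L, 2L, 3L, NA), n_mice * 6,
                       replace = TRUE), n_mice, 6)
    peak <- sample(1:6, 1)
    g[, peak] <- 1L
    cross <- toy_cross(g, map = map)
    span <- nonrecombinant_span(cross, cross$mouse_ids, "1",
                                map$marker[peak])
    expect_equal(match(span, map$marker), brute(g, peak))
  }
})

test_that("widening the mouse subset never widens the span", {
  map <- toy_map(1, 6)
  set.seed(7)
  g <- matrix(sample(c(1L, 1L, 2L, 3L), 4 * 6, replace = TRUE), 4, 6)
  g[, 3] <- 1L
  cross <- toy_cross(g, map = map)
  idx_of <- function(span) match(span, map$marker)
  s_all <- idx_of(nonrecombinant_span(cross, cross$mouse_ids, "1",
                                      map$marker[3]))
  for (k in 1:3) {
    s_sub <- idx_of(nonrecombinant_span(cross, cross$mouse_ids[1:k], "1",
                                        map$marker[3]))
    expect_lte(s_sub[1], s_all[1])
    expect_gte(s_sub[2], s_all[2])
  }
})

test_that("interval extension is clamped, monotone and identity at zero flank", {
  map <- data.frame(marker = c("a", "b"), chr = "11",
                    pos_cM = c(2.5, 4.5), pos_bp = c(5e6, 9e6),
                    stringsAsFactors = FALSE)
  class(map) <- c("genetic_map", "data.frame")
  iv <- extend_interval(c("a", "b"), map, flank_bp = 1e6)
  expect_equal(c(iv$start_bp, iv$end_bp), c(4e6, 10e6))

  map$pos_bp <- c(5e5, 9e6)
  iv <- extend_interval(c("a", "b"), map, flank_bp = 1e6)
  expect_equal(iv$start_bp, 1)

  iv0 <- extend_interval(c("a", "b"), map, flank_bp = 0)
  expect_equal(c(iv0$start_bp, iv0$end_bp), c(5e5, 9e6))

  # monotone in the flank; one-sided mode leaves the start untouched
  iv2 <- extend_interval(c("a", "b"), map, flank_bp = 2e6)
  expect_lte(iv2$start_bp, iv$start_bp)
  expect_gte(iv2$end_bp, iv$end_bp)
  iv1s <- extend_interval(c("a", "b"), map, flank_bp = 1e6,
                          one_sided = TRUE)
  expect_equal(iv1s$start_bp, 5e5)
  expect_equal(iv1s$end_bp, 1e7)

  # clamped to the chromosome length
  ivc <- extend_interval(c("a", "b"), map, flank_bp = 1e9)
  expect_equal(ivc$end_bp, unname(mouse_chrom_lengths_bp()[["11"]]))
})

test_that("gene overlap matches a linear-scan oracle and boundary rule", {
  interval <- structure(list(chromosome = "2", start_bp = 100, end_bp = 200),
                        class = "genomic_interval")
  expect_equal(nrow(genes_in_interval(
    data.frame(gene_id = character(), symbol = character(),
               chromosome = character(), start_bp = numeric(),
               end_bp = numeric()), interval)), 0L)

  set.seed(5)
  ann <- data.frame(
    gene_id = sprintf("g%02d", 1:10), symbol = sprintf("s%02d", 1:10),
    chromosome = c(rep("2", 8), "3", "3"),
    start_bp = c(10, 50, 90, 150, 199, 200, 250, 300, 120, 160),
    stringsAsFactors = FALSE)
  ann$end_bp <- ann$start_bp + c(30, 45, 15, 20, 2, 40, 10, 5, 30, 10)
  hits <- genes_in_interval(ann, interval)
  oracle <- ann$gene_id[ann$chromosome == "2" &
                          ann$start_bp <= 200 & ann$end_bp >= 100]
  expect_setequal(hits$gene_id, oracle)
  # gene starting exactly at the interval end overlaps by 1 bp
  expect_true("g06" %in% hits$gene_id)
  expect_false(is.unsorted(hits$start_bp))

  expect_warning(
    out <- genes_in_interval(ann, structure(
      list(chromosome = "7", start_bp = 1, end_bp = 10),
      class = "genomic_interval")), "absent")
  expect_equal(nrow(out), 0L)
})

test_that("annotation survives BED and TSV round-trips including non-ASCII", {
  ann <- data.frame(gene_id = c("g1", "g2"), symbol = c("Alpha", "Génβ"),
                    chromosome = c("11", "18"), start_bp = c(100L, 5000L),
                    end_bp = c(900L, 5100L), stringsAsFactors = FALSE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_gene_annotation(ann, tsv, format = "tsv")
  expect_equal(read_gene_annotation(tsv), ann)

  bed <- withr::local_tempfile(fileext = ".bed")
  write_gene_annotation(ann, bed, format = "bed")
  # BED is 0-based half-open on disk; coordinates must round-trip
  raw <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(raw$V2, ann$start_bp - 1L)
  expect_equal(raw$V3, ann$end_bp)
  back <- read_gene_annotation(bed)
  expect_equal(back$start_bp, ann$start_bp)
  expect_equal(back$end_bp, ann$end_bp)
  expect_equal(back$gene_id, ann$gene_id)
})

test_that("high-responder selection follows genotype and origin rules", {
  map <- toy_map(2, 2, spacing_cM = 40)
  cr <- add_parental_averages(simulate_f2(map, 60, seed = 17))
  ids <- select_high_responders(cr, "t01m01", "t02m01")
  expect_true("parental_A" %in% ids)
  expect_false("parental_B" %in% ids)
  g <- cr$geno
  manual <- cr$mouse_ids[g[, "t01m01"] == 1L & g[, "t02m01"] == 1L]
  expect_setequal(ids, manual)
  # no qualifying mouse -> empty with warning
  cr2 <- cr
  cr2$geno[, "t01m01"] <- 3L
  cr2$origin[] <- "F2"
  expect_warning(none <- select_high_responders(cr2, "t01m01", "t02m01"),
                 "no mouse")
  expect_length(none, 0L)
})
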