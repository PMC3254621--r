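#' @title End-to-end pipeline
#' @description
#' Orchestrates the full inference chain: simulate (or load) an F2 cross,
#' run single- and two-QTL scans with permutation thresholds, delimit the
#' non-recombinant windows around the top interacting pair, map them to
#' gene lists and candidate protein sets, filter the interaction network
#' and prioritize cross-locus interactions.  All randomness flows from a
#' single configuration seed via per-stage derived seeds (`seed + stage
#' index`), so identical configurations yield byte-identical artifacts.
#' @name pipeline_cli
NULL

.PIPELINE_DEFAULTS <- list(
  mode = "simulate",
  # input paths (load mode)
  cross_csv = "", markers_tsv = "", annotation_tsv = "", ppin_tsv = "",
  gene_protein_tsv = "",
  # simulation parameters
  n_f2 = 115, n_autosomes = 19, n_markers = 384, spacing_mb = 6.5,
  cm_per_mb = 0.5, baseline_mean = 1, effect_ratio = 2, noise_sd = 0.25,
  locus_a_marker = "", locus_b_marker = "",
  gene_spacing_bp = 2e6, ppin_edges_per_node = 1.5,
  # scan options
  n_perm = 1000, alpha = 0.05, include_parental = TRUE,
  exclude_adjacent_cM = 0,
  # window options
  flank_bp = 1e6, one_sided = FALSE,
  # network options
  min_combined = 800, channels = "fusion,experimental,database",
  n_rand = 1000, swaps_per_edge = 10, fdr_strong = 1e-4, fdr_weak = 0.5,
  seed = 1
)

#' Pipeline configuration
#'
#' Builds a validated configuration from named overrides of the defaults.
#' Unknown keys are an error (fail-fast).
#'
#' @param ... named overrides of the default keys (see
#'   `qtlspan:::.PIPELINE_DEFAULTS`).
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("configuration overrides must be named")
  unknown <- setdiff(names(over), names(.PIPELINE_DEFAULTS))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- .PIPELINE_DEFAULTS
  for (k in names(over)) {
    template <- cfg[[k]]
    v <- over[[k]]
    cfg[[k]] <- if (is.numeric(template)) as.numeric(v)
      else if (is.logical(template)) as.logical(v)
      else as.character(v)
  }
  if (!cfg$mode %in% c("simulate", "load"))
    stop("mode must be 'simulate' or 'load'")
  structure(cfg, class = "pipeline_config")
}

#' Read a flat key = value configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments are
#' ignored.  Unknown keys are errors.
#'
#' @param path configuration file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z][A-Za-z0-9_]*)\\s*=\\s*(.*)$",
                                  lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3L]
  if (length(bad)) stop("malformed config line(s): ",
                        paste(bad, collapse = "; "))
  vals <- stats::setNames(lapply(kv, `[`, 3L),
                          vapply(kv, `[`, character(1), 2L))
  do.call(pipeline_config, vals)
}

# stable hash of the configuration (md5 of its canonical text rendering)
config_hash <- function(cfg) {
  txt <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

.stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                  stage, sprintf(fmt, ...)))
}

# Default planted loci: the middle marker of chromosomes 11 and 18 when
# present, else of the last two chromosomes of the map.
.default_loci <- function(map) {
  chrs <- unique(map$chr)
  pick <- function(ch) {
    idx <- which(map$chr == ch)
    map$marker[idx[ceiling(length(idx) / 2)]]
  }
  cha <- if ("11" %in% chrs) "11" else chrs[max(1L, length(chrs) - 1L)]
  chb <- if ("18" %in% chrs && cha != "18") "18" else chrs[length(chrs)]
  if (cha == chb) stop("need at least two chromosomes to plant a pair")
  c(pick(cha), pick(chb))
}

# Build the default synthetic scenario: cross with a planted epistatic
# pair, gene annotation with genes anchored at the planted peaks, a 1:1
# gene->protein map, and a background network with a planted cross-locus
# edge between the two peak-gene proteins plus hub-attached decoy edges.
.simulate_scenario <- function(cfg) {
  seed <- as.integer(cfg$seed)
  map <- make_map(cfg$n_autosomes, cfg$n_markers, cfg$spacing_mb,
                  cfg$cm_per_mb, seed = seed)
  loci <- c(cfg$locus_a_marker, cfg$locus_b_marker)
  if (!nzchar(loci[1]) || !nzchar(loci[2])) loci <- .default_loci(map)
  ia <- match(loci, map$marker)
  if (anyNA(ia)) stop("planted loci must exist in the map")

  cross <- simulate_f2(map, cfg$n_f2, seed = seed + 1L)
  cross <- add_parental_averages(cross)
  model <- pheno_model(cfg$baseline_mean, cfg$effect_ratio, cfg$noise_sd,
                       loci[1], loci[2])
  cross <- simulate_phenotype(cross, model, seed = seed + 2L)

  # genes guaranteed at the peaks (and at one flanking marker each, as
  # decoy candidates inside the expected windows)
  flank_marker <- function(i) {
    ch <- map$chr[i]
    j <- which(map$chr == ch)
    cand <- j[j != i]
    cand[which.min(abs(map$pos_bp[cand] - map$pos_bp[i]))]
  }
  anchors <- data.frame(
    chromosome = map$chr[c(ia, flank_marker(ia[1]), flank_marker(ia[2]))],
    pos_bp = map$pos_bp[c(ia, flank_marker(ia[1]), flank_marker(ia[2]))],
    gene_id = c("Gpeak_a", "Gpeak_b", "Gdecoy_a", "Gdecoy_b"),
    stringsAsFactors = FALSE)
  ann <- make_annotation(map, spacing_bp = cfg$gene_spacing_bp,
                         anchor_bp = anchors, seed = seed + 3L)
  gp <- make_gene_protein_map(ann)

  prot <- stats::setNames(gp$protein_id, gp$gene_id)
  planted <- rbind(
    c(prot[["Gpeak_a"]], prot[["Gpeak_b"]]),
    c(prot[["Gdecoy_a"]], prot[["Gdecoy_b"]]))
  # boost the decoy endpoints' degrees so the planted peak edge is the
  # one with the lowest occurrence probability under the null
  avail <- setdiff(gp$protein_id, c(planted))
  k <- min(5L, floor(length(avail) / 2))
  if (k > 0)
    planted <- rbind(planted,
                     cbind(prot[["Gdecoy_a"]], avail[seq_len(k)]),
                     cbind(prot[["Gdecoy_b"]], avail[k + seq_len(k)]))
  n_nodes <- nrow(gp)
  n_edges <- min(n_nodes * (n_nodes - 1) / 2,
                 max(nrow(planted) + 1L,
                     round(cfg$ppin_edges_per_node * n_nodes)))
  ppin <- simulate_ppin(n_nodes, n_edges, planted_edges = planted,
                        degree_skew = 1, seed = seed + 4L,
                        node_ids = gp$protein_id)
  list(cross = cross, annotation = ann, gene_protein = gp, ppin = ppin,
       planted_loci = loci,
       planted_edge = sort(c(prot[["Gpeak_a"]], prot[["Gpeak_b"]])))
}

.load_scenario <- function(cfg) {
  for (key in c("cross_csv", "annotation_tsv", "ppin_tsv",
                "gene_protein_tsv")) {
    if (!nzchar(cfg[[key]])) stop("load mode requires ", key)
    if (!file.exists(cfg[[key]])) stop("missing input file: ", cfg[[key]])
  }
  cross <- read_cross_csv(cfg$cross_csv,
                          bp_path = if (nzchar(cfg$markers_tsv))
                            cfg$markers_tsv else NULL,
                          cm_per_mb = cfg$cm_per_mb)
  ann <- read_gene_annotation(cfg$annotation_tsv)
  gp <- utils::read.table(cfg$gene_protein_tsv, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  raw <- read_string_edges(cfg$ppin_tsv)
  list(cross = cross, annotation = ann, gene_protein = gp, raw_edges = raw,
       planted_loci = NULL, planted_edge = NULL)
}

#' Run the full pipeline
#'
#' Executes the stages in order (simulate/load, single-QTL scan, two-QTL
#' scan, permutation thresholds, peak pair, haplotype windows, gene lists,
#' network filtering, SPAN prioritization) and writes every artifact plus
#' a human-readable and a machine-readable report to `out_dir`.  A failing
#' stage stops the run with a stage-named error; artifacts written by
#' earlier stages remain on disk.
#'
#' @param config a `pipeline_config` (see [pipeline_config()]).
#' @param out_dir output directory (created if needed).
#' @param quiet suppress stage log messages.
#' @return the report list, invisibly.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- if (quiet) function(...) invisible() else .stage_log
  seed <- as.integer(config$seed)
  hash <- config_hash(config)
  stamp <- sprintf("qtlspan seed=%d config=%s", seed, hash)
  art <- function(name) file.path(out_dir, name)
  fail <- function(stage, e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)

  # -- stage: data ----------------------------------------------------
  scen <- tryCatch(
    if (config$mode == "simulate") .simulate_scenario(config)
    else .load_scenario(config),
    error = function(e) fail("data", e))
  cross <- scen$cross
  log("data", "%d mice x %d markers", length(cross$mouse_ids),
      ncol(cross$geno))
  write_cross_csv(cross, art("cross.csv"), comment = stamp)
  write_marker_positions(cross$map, art("markers.tsv"), comment = stamp)
  write_gene_annotation(scen$annotation, art("annotation.tsv"))
  utils::write.table(scen$gene_protein, art("gene_protein.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # -- stage: network filter -----------------------------------------
  chans <- strsplit(config$channels, ",", fixed = TRUE)[[1]]
  ppin <- tryCatch({
    if (!is.null(scen$ppin))
      filter_string_edges(scen$ppin, config$min_combined, chans)
    else filter_string_edges(scen$raw_edges, config$min_combined, chans)
  }, error = function(e) fail("network_filter", e))
  log("network_filter", "%d proteins, %d high-confidence edges",
      length(ppin$nodes), nrow(ppin$edges))
  write_string_edges(ppin, art("ppin_filtered.tsv"), sep = "\t",
                     comment = stamp)

  # -- stage: scans ---------------------------------------------------
  s1 <- tryCatch(
    suppressWarnings(scan_one(cross, config$include_parental)),
    error = function(e) fail("scan1", e))
  .write_tsv <- function(df, path) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste0("# ", stamp), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  .write_tsv(s1, art("scan1.tsv"))
  pre <- tryCatch(
    scan2_precompute(cross, config$exclude_adjacent_cM,
                     config$include_parental),
    error = function(e) fail("scan2", e))
  s2 <- tryCatch(scan_two(cross, pre = pre),
                 error = function(e) fail("scan2", e))
  .write_tsv(s2, art("scan2.tsv"))
  log("scan2", "%d marker pairs scanned", nrow(s2))

  thr <- tryCatch(
    permutation_thresholds(cross, config$n_perm, config$alpha,
                           seed = seed + 5L, statistic = "max_int",
                           pre = pre),
    error = function(e) fail("permtest", e))
  .write_tsv(data.frame(perm = seq_along(thr$maxima),
                        max_lod_int = thr$maxima), art("perm_maxima.tsv"))
  log("permtest", "alpha=%g threshold=%.3f (%d permutations)",
      config$alpha, thr$threshold_int, thr$n_perm)

  peaks <- peak_pair(s2, thr)
  .write_tsv(utils::head(peaks, 50L), art("peaks.tsv"))
  top <- peaks[1, ]
  log("peaks", "top pair %s x %s lod_int=%.2f significant=%s",
      top$marker_a, top$marker_b, top$lod_int, top$significant)

  # -- stage: windows -------------------------------------------------
  windows <- tryCatch({
    hi <- select_high_responders(cross, top$marker_a, top$marker_b,
                                 config$include_parental)
    lapply(c(a = top$marker_a, b = top$marker_b), function(mk) {
      ch <- cross$map$chr[match(mk, cross$map$marker)]
      span <- nonrecombinant_span(cross, hi, ch, mk)
      extend_interval(span, cross$map, config$flank_bp,
                      one_sided = config$one_sided)
    })
  }, error = function(e) fail("windows", e))
  hi <- select_high_responders(cross, top$marker_a, top$marker_b,
                               config$include_parental)
  wdf <- do.call(rbind, lapply(names(windows), function(nm) {
    w <- windows[[nm]]
    data.frame(locus = nm, chromosome = w$chromosome,
               start_bp = w$start_bp, end_bp = w$end_bp,
               first_marker = w$anchor_markers[1],
               last_marker = w$anchor_markers[2],
               stringsAsFactors = FALSE)
  }))
  .write_tsv(wdf, art("windows.tsv"))
  log("windows", "%d high responders; windows %s:%.0f-%.0f and %s:%.0f-%.0f",
      length(hi), wdf$chromosome[1], wdf$start_bp[1], wdf$end_bp[1],
      wdf$chromosome[2], wdf$start_bp[2], wdf$end_bp[2])

  # -- stage: gene lists ---------------------------------------------
  genes <- tryCatch(
    lapply(windows, function(w) genes_in_interval(scen$annotation, w)),
    error = function(e) fail("genes", e))
  .write_tsv(genes$a, art("genes_locus_a.tsv"))
  .write_tsv(genes$b, art("genes_locus_b.tsv"))
  log("genes", "%d genes in window a, %d in window b",
      nrow(genes$a), nrow(genes$b))

  # -- stage: prioritization -----------------------------------------
  gp <- scen$gene_protein
  to_prot <- function(g) {
    p <- gp$protein_id[match(g$gene_id, gp$gene_id)]
    n_un <- sum(is.na(p))
    if (n_un) log("prioritize", "WARN %d unmapped gene(s) dropped", n_un)
    unique(p[!is.na(p)])
  }
  pr <- tryCatch({
    sets <- candidate_sets(to_prot(genes$a), to_prot(genes$b))
    prioritize(ppin, sets, config$fdr_strong, config$fdr_weak,
               config$n_rand, config$swaps_per_edge, seed = seed + 6L)
  }, error = function(e) fail("prioritize", e))
  write_prioritization(pr, art("prioritization_nodes.tsv"),
                       art("prioritization_edges.tsv"), comment = stamp)
  write_sif(pr$edges, art("subnetwork.sif"), comment = stamp)
  write_graphml(pr, art("subnetwork.graphml"), seed_info = stamp)
  log("prioritize", "%d cross-locus edges, %d headline", nrow(pr$edges),
      nrow(pr$headline))

  report <- write_report(
    list(seed = seed, config_hash = hash, config = unclass(config),
         n_mice = length(cross$mouse_ids),
         n_f2 = sum(cross$origin == "F2"),
         n_markers = ncol(cross$geno),
         n_pairs_scanned = nrow(s2),
         n_perm = thr$n_perm, alpha = config$alpha,
         threshold_int = thr$threshold_int,
         top_pair = list(marker_a = top$marker_a, marker_b = top$marker_b,
                         chr_a = top$chr_a, chr_b = top$chr_b,
                         lod_int = top$lod_int,
                         significant = top$significant),
         n_high_responders = length(hi),
         windows = wdf,
         n_genes_a = nrow(genes$a), n_genes_b = nrow(genes$b),
         n_ppin_nodes = length(ppin$nodes),
         n_ppin_edges = nrow(ppin$edges),
         n_cross_edges = nrow(pr$edges),
         n_headline_edges = nrow(pr$headline),
         top_edge = if (nrow(pr$edges)) {
           i <- which.min(pr$edges$q_value)
           list(protein_a = pr$edges$protein_a[i],
                protein_b = pr$edges$protein_b[i],
                q_value = pr$edges$q_value[i])
         } else NULL,
         planted_loci = scen$planted_loci,
         planted_edge = scen$planted_edge),
    out_dir)
  invisible(report)
}

#' Write the run report
#'
#' Emits `report.json` (machine-readable) and `report.txt`
#' (human-readable per-stage counts: mice, markers, permutations, high
#' responders, genes per window, edges after filtering, headline
#' subnetwork size).  Byte-identical across reruns of the same seeded
#' configuration.
#'
#' @param stages named list of stage outputs (see [run_pipeline()]).
#' @param out_dir output directory.
#' @return the stages list, invisibly.
#' @export
write_report <- function(stages, out_dir) {
  if (length(stages) == 0L) stop("at least one stage output is required")
  jsonlite::write_json(stages, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  txt <- c(
    "qtlspan pipeline report",
    sprintf("seed: %d  config: %s", stages$seed, stages$config_hash),
    sprintf("mice: %d (%d F2)  markers: %d", stages$n_mice, stages$n_f2,
            stages$n_markers),
    sprintf("marker pairs scanned: %d", stages$n_pairs_scanned),
    sprintf("permutations: %d  alpha: %g  interaction threshold: %.4f",
            stages$n_perm, stages$alpha, stages$threshold_int),
    sprintf("top pair: %s (chr %s) x %s (chr %s)  lod_int: %.4f  significant: %s",
            stages$top_pair$marker_a, stages$top_pair$chr_a,
            stages$top_pair$marker_b, stages$top_pair$chr_b,
            stages$top_pair$lod_int, stages$top_pair$significant),
    sprintf("high responders (AA at both peaks): %d",
            stages$n_high_responders),
    sprintf("window a: chr %s %.0f-%.0f (%s..%s)", stages$windows$chromosome[1],
            stages$windows$start_bp[1], stages$windows$end_bp[1],
            stages$windows$first_marker[1], stages$windows$last_marker[1]),
    sprintf("window b: chr %s %.0f-%.0f (%s..%s)", stages$windows$chromosome[2],
            stages$windows$start_bp[2], stages$windows$end_bp[2],
            stages$windows$first_marker[2], stages$windows$last_marker[2]),
    sprintf("genes: %d in window a, %d in window b", stages$n_genes_a,
            stages$n_genes_b),
    sprintf("filtered network: %d proteins, %d edges", stages$n_ppin_nodes,
            stages$n_ppin_edges),
    sprintf("cross-locus edges: %d  headline (strong node+edge FDR): %d",
            stages$n_cross_edges, stages$n_headline_edges),
    if (!is.null(stages$top_edge))
      sprintf("top edge: %s -- %s  q = %.4g", stages$top_edge$protein_a,
              stages$top_edge$protein_b, stages$top_edge$q_value)
    else "top edge: none (no cross-locus edge observed)"
  )
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(stages)
}
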