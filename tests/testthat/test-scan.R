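# Fixtures are small enough that every LOD can be checked against the
# explicit least-squares oracles in helper-oracles.R.

test_that("single-marker scan handles the hand-worked cases", {
  # equal class means -> lod 0
  cr <- toy_cross(cbind(c(1, 1, 1, 3, 3, 3)), c(1, 2, 3, 1, 2, 3),
                  map = toy_map(1, 1))
  expect_equal(scan_one(cr)$lod, 0)

  # three classes, means (11, 15, 21): lod = 3 log10(RSS0 / 6)
  y <- c(10, 12, 14, 16, 20, 22)
  cr <- toy_cross(cbind(c(1, 1, 2, 2, 3, 3)), y, map = toy_map(1, 1))
  rss0 <- sum((y - mean(y))^2)
  expect_equal(scan_one(cr)$lod, 3 * log10(rss0 / 6), tolerance = 1e-12)

  # zero residual -> infinite LOD, flagged
  cr <- toy_cross(cbind(c(1, 1, 3, 3)), c(1, 1, 2, 2), map = toy_map(1, 1))
  s <- scan_one(cr)
  expect_true(is.infinite(s$lod))
  expect_equal(s$flag, "perfect_fit")
})

test_that("degenerate markers are flagged, not fatal", {
  g <- cbind(rep(1L, 6), c(1, 1, 2, 2, 3, 3), rep(NA_integer_, 6))
  cr <- toy_cross(g, c(5, 3, 6, 2, 8, 4), map = toy_map(1, 3))
  expect_warning(s <- scan_one(cr), "classes")
  expect_equal(s$lod[1], 0)
  expect_equal(s$flag[1], "too_few_classes")
  expect_equal(s$n_used[3], 0L)
  expect_equal(s$flag[3], "all_missing")
  expect_gt(s$lod[2], 0)
})

test_that("pair scan matches the explicit least-squares oracle exactly", {
  # 12-mouse fixture with all 9 joint classes occupied
  ga <- c(1, 1, 1, 2, 2, 2, 3, 3, 3, 1, 2, 3)
  gb <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 2, 1, 3)
  set.seed(42)
  y <- round(stats::runif(12, 1, 10), 3)
  cr <- toy_cross(cbind(ga, gb), y, map = toy_map(2, 1))
  s2 <- scan_two(cr)
  o <- lm_scan2_oracle(ga, gb, y)
  expect_close(s2$lod_full, o$lod_full)
  expect_close(s2$lod_add, o$lod_add)
  expect_close(s2$lod_int, o$lod_int)
  expect_equal(s2$n_classes, 9L)
})

test_that("noiseless additive phenotype has zero interaction LOD", {
  set.seed(1)
  map <- toy_map(2, 1, spacing_cM = 10)
  ga <- sample(1:3, 40, replace = TRUE)
  gb <- sample(1:3, 40, replace = TRUE)
  y <- 2 * ga + 5 * gb + 1
  cr <- toy_cross(cbind(ga, gb), y, map = map)
  s2 <- scan_two(cr)
  expect_equal(s2$lod_int, 0, tolerance = 1e-9)
  expect_gt(s2$lod_add, 0)
})

test_that("noiseless epistatic phenotype saturates the full model", {
  set.seed(2)
  ga <- sample(1:3, 30, replace = TRUE)
  gb <- sample(1:3, 30, replace = TRUE)
  y <- ifelse(ga == 1 & gb == 1, 2, 1)
  cr <- toy_cross(cbind(ga, gb), y, map = toy_map(2, 1))
  s2 <- scan_two(cr)
  expect_equal(s2$flag, "perfect_fit")
  expect_true(is.infinite(s2$lod_full))
  expect_true(is.finite(s2$lod_add))
  expect_true(is.na(s2$lod_int))
})

test_that("scans agree with the oracles on random fixtures with missing data", {
  for (s in 1:6) {
    set.seed(s)
    n <- sample(8:20, 1)
    geno <- matrix(sample(c(1:3, NA), n * 6, replace = TRUE,
                          prob = c(0.3, 0.3, 0.3, 0.1)), n, 6)
    y <- round(stats::runif(n, 0.5, 3), 4)
    cr <- toy_cross(geno, y, map = toy_map(3, 2))
    s1 <- suppressWarnings(scan_one(cr))
    for (j in 1:6) {
      exp_lod <- lm_scan1_oracle(geno[, j], y)
      if (is.finite(exp_lod) && s1$n_classes[j] >= 2)
        expect_close(s1$lod[j], exp_lod)
    }
    s2 <- scan_two(cr)
    for (k in seq_len(nrow(s2))) {
      if (s2$flag[k] != "ok") next
      a <- match(s2$marker_a[k], cr$map$marker)
      b <- match(s2$marker_b[k], cr$map$marker)
      o <- lm_scan2_oracle(geno[, a], geno[, b], y)
      expect_close(s2$lod_full[k], o$lod_full)
      expect_close(s2$lod_add[k], o$lod_add)
      expect_close(s2$lod_int[k], o$lod_int)
    }
  }
})

test_that("model nesting orders the LODs on complete fixtures", {
  map <- toy_map(3, 2, spacing_cM = 30)
  cr <- simulate_f2(map, 40, seed = 12)
  cr <- simulate_phenotype(cr, pheno_model(1, 2, 0.3, "t01m01", "t02m01"),
                           seed = 13)
  s1 <- scan_one(cr)
  s2 <- scan_two(cr)
  lod1 <- stats::setNames(s1$lod, s1$marker)
  ok <- s2$flag == "ok"
  expect_true(all(s2$lod_full[ok] >= s2$lod_add[ok] - 1e-9))
  expect_true(all(s2$lod_add[ok] >= -1e-9))
  expect_true(all(s2$lod_int[ok] >= -1e-9))
  expect_true(all(s2$lod_full[ok] >= lod1[s2$marker_a[ok]] - 1e-9))
  expect_true(all(s2$lod_full[ok] >= lod1[s2$marker_b[ok]] - 1e-9))
})

test_that("LOD scores are invariant under affine phenotype maps", {
  map <- toy_map(2, 3, spacing_cM = 20)
  cr <- simulate_f2(map, 30, seed = 21)
  cr <- simulate_phenotype(cr, pheno_model(1, 2, 0.25, "t01m02", "t02m01"),
                           seed = 22)
  cr2 <- cr
  cr2$phenotype <- 2 * cr$phenotype + 3
  expect_equal(scan_one(cr)$lod, scan_one(cr2)$lod, tolerance = 1e-9)
  a <- scan_two(cr); b <- scan_two(cr2)
  expect_equal(a$lod_full, b$lod_full, tolerance = 1e-9)
  expect_equal(a$lod_int, b$lod_int, tolerance = 1e-9)
})

test_that("permutation thresholds are deterministic and quantile-monotone", {
  map <- toy_map(3, 3, spacing_cM = 25)
  cr <- simulate_f2(map, 40, seed = 31)
  cr <- simulate_phenotype(cr, pheno_model(1, 1, 0.25, "t01m01", "t02m01"),
                           seed = 32)
  t1 <- permutation_thresholds(cr, n_perm = 40, alpha = 0.05, seed = 5)
  t2 <- permutation_thresholds(cr, n_perm = 40, alpha = 0.05, seed = 5)
  expect_identical(t1$threshold_int, t2$threshold_int)
  expect_identical(t1$maxima, t2$maxima)

  # monotone in alpha, computed from the same maxima vector
  t20 <- permutation_thresholds(cr, n_perm = 40, alpha = 0.20, seed = 5)
  expect_gte(t1$threshold_int, t20$threshold_int)
  expect_equal(t1$maxima, t20$maxima)

  # alpha = 1 degenerates to the minimum of the permuted maxima
  tall <- permutation_thresholds(cr, n_perm = 40, alpha = 1, seed = 5)
  expect_equal(tall$threshold_int, min(tall$maxima))

  expect_error(permutation_thresholds(cr, 40, alpha = 0, seed = 1), "alpha")
  expect_error(permutation_thresholds(cr, 40, alpha = 1.2, seed = 1),
               "alpha")
  expect_error(permutation_thresholds(cr, n_perm = 5, seed = 1), "n_perm")

  # the 1d statistic runs through the same machinery
  t1d <- permutation_thresholds(cr, n_perm = 40, alpha = 0.05, seed = 5,
                                statistic = "max_1d")
  expect_true(is.finite(t1d$threshold_1d))
  expect_true(is.na(t1d$threshold_int))
})

test_that("peak ranking breaks ties deterministically and flags significance", {
  # constant phenotype differences -> all interaction LODs zero
  set.seed(3)
  geno <- matrix(sample(1:3, 20 * 4, replace = TRUE), 20, 4)
  y <- rep(c(1, 2), 10)
  cr <- toy_cross(geno, y, map = toy_map(4, 1))
  s2 <- scan_two(cr)
  s2$lod_int[] <- 0; s2$lod_full[] <- 1; s2$lod_add[] <- 1
  thr <- structure(list(threshold_int = 0.5, alpha = 0.05,
                        statistic = "max_int"), class = "perm_thresholds")
  pk <- peak_pair(s2, thr)
  expect_false(pk$significant[1])
  # ties ordered lexicographically by chromosome and position
  expect_equal(pk$chr_a[1], "1")
  expect_true(!is.unsorted(order(pk$lod_int, decreasing = TRUE)))
  first_tie_block <- pk[pk$lod_int == pk$lod_int[1], ]
  expect_equal(first_tie_block$marker_a[1], "t01m01")
})

test_that("planted interaction is recovered near the true loci", {
  map <- make_map(n_autosomes = 6, n_markers_total = 60)
  loci <- c("c02m005", "c05m004")
  cr <- add_parental_averages(simulate_f2(map, 115, seed = 41))
  cr <- simulate_phenotype(cr, pheno_model(1, 2, 0.25, loci[1], loci[2]),
                           seed = 42)
  s2 <- scan_two(cr)
  thr <- permutation_thresholds(cr, n_perm = 100, alpha = 0.05, seed = 43)
  pk <- peak_pair(s2, thr)
  pos <- function(mk) map$pos_cM[match(mk, map$marker)]
  chr <- function(mk) map$chr[match(mk, map$marker)]
  expect_equal(sort(c(chr(pk$marker_a[1]), chr(pk$marker_b[1]))),
               sort(c(chr(loci[1]), chr(loci[2]))))
  expect_lt(abs(pos(pk$marker_a[1]) - pos(loci[1])), 10)
  expect_lt(abs(pos(pk$marker_b[1]) - pos(loci[2])), 10)
  expect_true(pk$significant[1])
})
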