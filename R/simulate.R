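#' Simulate F2 intercross genotypes
#'
#' Draws genotypes for `n_f2` F2 animals from a two-founder intercross.
#' Each animal receives two independent gametes; along a gamete the founder
#' allele at the first marker of each chromosome is a fair coin flip, and
#' between adjacent markers the allele switches with the Haldane
#' recombination fraction `r = (1 - exp(-2 d / 100)) / 2` of their cM
#' distance `d` (no crossover interference).  Chromosomes segregate
#' independently.  The genotype at a marker is the number of A alleles
#' carried (2 = AA, 1 = AB, 0 = BB).
#'
#' @param map a `genetic_map`.
#' @param n_f2 number of F2 animals.
#' @param seed integer seed; results are bit-identical for equal seeds.
#' @return a `cross_data` with genotypes only (phenotype unset) and all
#'   rows labelled `F2`.
#' @examples
#' cross <- simulate_f2(make_map(2, 10, 5), n_f2 = 20, seed = 1)
#' table(cross$geno[, 1])
#' @export
simulate_f2 <- function(map, n_f2, seed = 1L) {
  validate_genetic_map(map)
  n_f2 <- as.integer(n_f2)
  if (n_f2 < 1L) stop("`n_f2` must be at least 1")
  geno <- matrix(NA_integer_, n_f2, nrow(map))
  withr::with_seed(as.integer(seed), {
    for (ch in unique(map$chr)) {
      j <- which(map$chr == ch)
      r <- haldane_r(diff(map$pos_cM[j]))
      g1 <- .gamete_matrix(n_f2, r)
      g2 <- .gamete_matrix(n_f2, r)
      # number of A alleles 2/1/0 -> codes 1 (AA) / 2 (AB) / 3 (BB)
      geno[, j] <- 3L - (g1 + g2)
    }
  })
  new_cross(map, geno)
}

# One gamete per row: 1 = founder A allele, 0 = founder B allele.
# r is the vector of recombination fractions between adjacent markers.
.gamete_matrix <- function(n, r) {
  k <- length(r) + 1L
  first <- stats::rbinom(n, 1L, 0.5)
  if (k == 1L) return(matrix(first, n, 1L))
  sw <- matrix(0L, n, k - 1L)
  for (j in seq_len(k - 1L)) sw[, j] <- stats::rbinom(n, 1L, r[j])
  cs <- sw
  if (k > 2L) for (j in 2:(k - 1L)) cs[, j] <- cs[, j] + cs[, j - 1L]
  (matrix(first, n, k) + cbind(0L, cs)) %% 2L
}

#' Specify an epistatic phenotype model
#'
#' The phenotype (airway responsiveness) has mean `baseline_mean` for every
#' animal except those homozygous AA at both `locus_a` and `locus_b`, whose
#' mean is multiplied by `effect_ratio`.  Gaussian noise with standard
#' deviation `noise_sd` is added and the result truncated below at a small
#' positive floor.
#'
#' @param baseline_mean positive mean for non-double-homozygous animals
#'   (units: cm H2O.ml^-1.s per (ug MCh per g body weight)).
#' @param effect_ratio multiplier (>= 1) for double-homozygous-AA animals;
#'   2 reproduces an "about double" interaction effect.
#' @param noise_sd non-negative residual standard deviation.
#' @param locus_a,locus_b marker ids of the interacting pair; must lie on
#'   different chromosomes.
#' @return a `pheno_model` list.
#' @export
pheno_model <- function(baseline_mean = 1, effect_ratio = 2,
                        noise_sd = 0.25, locus_a, locus_b) {
  stopifnot(baseline_mean > 0, noise_sd >= 0)
  if (effect_ratio < 1) stop("`effect_ratio` must be >= 1")
  structure(list(baseline_mean = baseline_mean, effect_ratio = effect_ratio,
                 noise_sd = noise_sd, locus_a = locus_a, locus_b = locus_b),
            class = "pheno_model")
}

#' Simulate the epistatic phenotype
#'
#' Fills the phenotype slot of a cross under a [pheno_model()]:
#' `y_i = baseline_mean * effect_ratio^[AA at both loci] + N(0, noise_sd^2)`,
#' truncated below at `1e-6`.  Parental-average rows receive the exact
#' model means rather than noisy draws: `parental_A` (AA everywhere, hence
#' AA at both loci) gets `baseline_mean * effect_ratio` and `parental_B`
#' gets `baseline_mean`.
#'
#' @param cross a `cross_data`.
#' @param model a `pheno_model`; its loci must exist in the map and lie on
#'   different chromosomes.
#' @param seed integer seed.
#' @return the cross with phenotype filled.
#' @export
simulate_phenotype <- function(cross, model, seed = 1L) {
  stopifnot(inherits(model, "pheno_model"))
  map <- cross$map
  ia <- match(model$locus_a, map$marker)
  ib <- match(model$locus_b, map$marker)
  if (is.na(ia) || is.na(ib)) stop("model loci must exist in the map")
  if (map$chr[ia] == map$chr[ib])
    stop("interacting loci must lie on different chromosomes")
  n <- length(cross$mouse_ids)
  both_aa <- !is.na(cross$geno[, ia]) & !is.na(cross$geno[, ib]) &
    cross$geno[, ia] == 1L & cross$geno[, ib] == 1L
  mu <- model$baseline_mean * model$effect_ratio^as.numeric(both_aa)
  withr::with_seed(as.integer(seed), {
    noise <- stats::rnorm(n, 0, model$noise_sd)
  })
  phen <- pmax(mu + noise, 1e-6)
  phen[cross$origin == "parental_A"] <-
    model$baseline_mean * model$effect_ratio
  phen[cross$origin == "parental_B"] <- model$baseline_mean
  cross$phenotype <- phen
  validate_cross(cross)
  cross
}

#' Inject missing genotypes and genotyping errors
#'
#' Robustness fixture for complete-case handling: each genotype cell is
#' independently set to missing with probability `missing_rate`; cells that
#' remain observed are flipped to a uniformly chosen different code with
#' probability `error_rate`.
#'
#' @param cross a `cross_data`.
#' @param missing_rate,error_rate probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @return a perturbed `cross_data` (parental purity is no longer
#'   guaranteed and is not re-checked).
#' @export
inject_missing_and_errors <- function(cross, missing_rate = 0,
                                      error_rate = 0, seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1)
  g <- cross$geno
  nc <- length(g)
  withr::with_seed(as.integer(seed), {
    miss <- stats::runif(nc) < missing_rate
    err <- stats::runif(nc) < error_rate
    shift <- sample(1:2, nc, replace = TRUE)
  })
  err <- err & !miss & !is.na(g)
  g[err] <- ((g[err] - 1L + shift[err]) %% 3L) + 1L
  g[miss] <- NA_integer_
  cross$geno <- g
  validate_cross(cross, check_parental = FALSE)
  cross
}
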