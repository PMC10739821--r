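#' Locus configuration for one trait
#'
#' Each trait (body size, mating preference) is controlled by `L` diploid loci
#' with the tri-valued allele set \{-1, 0, +1\}. An individual's genetic value
#' for the trait is the plain sum of its `2L` alleles, so values span
#' \eqn{[-2L, +2L]}. `env_sd` is the standard deviation of the optional
#' environmental noise added to the genetic value when size is expressed.
#'
#' @param L Number of loci per trait (default 5; the companion model uses 10).
#' @param mutation_rate Per-allele, per-generation probability that the allele
#'   is resampled uniformly from the allele set (default 0.01). Resampling may
#'   return the original allele, so one third of mutation events are silent.
#' @param env_sd Standard deviation of environmental noise on size expression;
#'   0 disables it. The calibrated values are 1.5 for `L = 5` and 2.16 for
#'   `L = 10`, which keep the genetic SD about 1.7 times the environmental SD.
#' @return A `loci_config` list.
#' @export
#' @examples
#' cfg <- loci_config(L = 5)
#' g <- init_genotype(cfg)
#' genotype_value(g)
loci_config <- function(L = 5L, mutation_rate = 0.01, env_sd = 0) {
  stopifnot(
    is.numeric(L), length(L) == 1L, L >= 1, L == as.integer(L),
    is.numeric(mutation_rate), length(mutation_rate) == 1L,
    mutation_rate >= 0, mutation_rate <= 1,
    is.numeric(env_sd), length(env_sd) == 1L, env_sd >= 0
  )
  structure(
    list(L = as.integer(L), mutation_rate = mutation_rate, env_sd = env_sd),
    class = "loci_config"
  )
}

# the fixed tri-valued allele set
allele_set <- c(-1L, 0L, 1L)

# coerce a genotype (vector) or stack of genotypes (matrix) to matrix form
genotype_matrix <- function(g) {
  if (is.matrix(g)) {
    storage.mode(g) <- "integer"
    g
  } else {
    matrix(as.integer(g), nrow = 1L)
  }
}

#' Draw a random genotype
#'
#' Alleles are drawn independently and uniformly from \{-1, 0, +1\}, the
#' initialization used for the founding population. Columns are arranged as
#' locus pairs: columns `2l - 1` and `2l` are the maternal and paternal copy
#' of locus `l`.
#'
#' @param cfg A [loci_config()].
#' @return An integer vector of `2L` alleles.
#' @seealso [init_genotypes()] for a vectorized stack of genotypes.
#' @export
init_genotype <- function(cfg) {
  sample(allele_set, 2L * cfg$L, replace = TRUE)
}

#' @rdname init_genotype
#' @param n Number of genotypes to draw.
#' @return For `init_genotypes()`, an `n x 2L` integer matrix (one genotype
#'   per row).
#' @export
init_genotypes <- function(n, cfg) {
  matrix(sample(allele_set, n * 2L * cfg$L, replace = TRUE), nrow = n)
}

#' Genetic value of a genotype
#'
#' The trait value is the sum of all `2L` alleles (strictly additive model:
#' no dominance, no epistasis).
#'
#' @param g A genotype vector or an `n x 2L` genotype matrix.
#' @return An integer (or integer vector, one per row).
#' @export
genotype_value <- function(g) {
  if (is.matrix(g)) as.integer(rowSums(g)) else as.integer(sum(g))
}

#' Free recombination of two parental genotypes
#'
#' For each locus independently the offspring receives one of the mother's two
#' allele copies (probability 1/2 each) and one of the father's two copies.
#' Loci segregate independently (free recombination, no linkage). Both
#' arguments may be matrices of stacked genotypes, in which case row `i` of
#' the result is the child of maternal row `i` and paternal row `i`.
#'
#' @param maternal,paternal Genotype vectors or `n x 2L` matrices with the
#'   same dimensions.
#' @return A genotype of the same shape class as the inputs (vector in,
#'   vector out).
#' @export
recombine <- function(maternal, paternal) {
  vec_in <- !is.matrix(maternal) && !is.matrix(paternal)
  m <- genotype_matrix(maternal)
  p <- genotype_matrix(paternal)
  if (ncol(m) != ncol(p)) {
    stop("incompatible parents: genotypes have different locus counts")
  }
  if (nrow(m) != nrow(p)) {
    stop("maternal and paternal genotype stacks differ in size")
  }
  if (ncol(m) %% 2L != 0L) stop("genotype length must be 2L")
  n <- nrow(m)
  L <- ncol(m) %/% 2L
  rows <- rep.int(seq_len(n), L)
  offs <- rep(seq_len(L) * 2L - 2L, each = n)
  from_m <- m[cbind(rows, offs + sample.int(2L, n * L, replace = TRUE))]
  from_p <- p[cbind(rows, offs + sample.int(2L, n * L, replace = TRUE))]
  child <- matrix(0L, n, 2L * L)
  child[, seq(1L, 2L * L, by = 2L)] <- from_m
  child[, seq(2L, 2L * L, by = 2L)] <- from_p
  if (vec_in) child[1L, ] else child
}

#' Mutate a genotype
#'
#' Each allele is, independently and with probability `rate`, replaced by a
#' uniform draw from \{-1, 0, +1\}. The draw may equal the original allele,
#' so a third of mutation events leave the genotype unchanged.
#'
#' @param g Genotype vector or matrix.
#' @param rate Per-allele mutation probability in \[0, 1\].
#' @return Genotype of the same shape.
#' @export
mutate_genotype <- function(g, rate) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0, rate <= 1)
  if (rate == 0) return(g)
  hit <- runif(length(g)) < rate
  if (any(hit)) g[hit] <- sample(allele_set, sum(hit), replace = TRUE)
  g
}

#' Environmental noise on size expression
#'
#' Realized size is the genetic value plus a zero-mean normal deviate with SD
#' `env_sd`; with `env_sd = 0` the genetic value is returned unchanged.
#'
#' @param genetic_value Numeric vector of genetic values.
#' @param env_sd Nonnegative standard deviation.
#' @return Numeric vector of realized sizes.
#' @export
apply_env_noise <- function(genetic_value, env_sd) {
  if (!is.numeric(env_sd) || length(env_sd) != 1L || is.na(env_sd) || env_sd < 0) {
    stop("env_sd must be a single nonnegative number")
  }
  if (env_sd == 0) return(as.numeric(genetic_value))
  genetic_value + rnorm(length(genetic_value), 0, env_sd)
}
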