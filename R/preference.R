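#' Empirical preference-function model
#'
#' Females accept a courting male with a logistic probability whose intercept
#' (\eqn{\alpha}, the propensity to mate with an average male) and slope on
#' male size (\eqn{\beta}, the direction and strength of size preference) vary
#' between females. The defaults are the moments estimated for the jumping
#' spider system on z-scored sizes: \eqn{\mu_\alpha \approx 0.95},
#' \eqn{\sigma^2_\alpha \approx 19.4}, \eqn{\mu_\beta \approx 0.52},
#' \eqn{\sigma^2_\beta \approx 5.7}, covariance \eqn{\approx 10.4} (an almost
#' perfect correlation of about 0.99), and a fixed female-size effect of
#' \eqn{-2.9} shared by all females.
#'
#' @param mu_alpha,var_alpha Mean and variance of the random intercept.
#' @param mu_beta,var_beta Mean and variance of the random slope on male size.
#' @param cov_alpha_beta Covariance between intercept and slope; the implied
#'   2x2 covariance matrix must be positive semi-definite.
#' @param female_size_slope Fixed effect of the female's own (z-scored) size.
#' @param per_class Number of (alpha, beta) pairs reserved for each preference
#'   genotype class when the pool is rank-binned (default 50).
#' @param pool_sort Ranking key used to order the pool before binning:
#'   `"beta"` (default; the slope encodes the small-male/large-male direction
#'   that the genotype represents) or `"alpha"`. With a correlation of ~0.99
#'   the two orders are nearly identical.
#' @return A `preference_model` list.
#' @export
preference_model <- function(mu_alpha = 0.95, var_alpha = 19.4,
                             mu_beta = 0.52, var_beta = 5.7,
                             cov_alpha_beta = 10.4,
                             female_size_slope = -2.9,
                             per_class = 50L,
                             pool_sort = c("beta", "alpha")) {
  pool_sort <- match.arg(pool_sort)
  stopifnot(var_alpha >= 0, var_beta >= 0, per_class >= 1)
  sigma <- matrix(c(var_alpha, cov_alpha_beta, cov_alpha_beta, var_beta), 2L)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("preference covariance matrix is not positive semi-definite")
  }
  structure(
    list(
      mu_alpha = mu_alpha, var_alpha = var_alpha,
      mu_beta = mu_beta, var_beta = var_beta,
      cov_alpha_beta = cov_alpha_beta,
      female_size_slope = female_size_slope,
      per_class = as.integer(per_class),
      pool_sort = pool_sort,
      sigma = sigma
    ),
    class = "preference_model"
  )
}

#' Draw the rank-binned preference pool
#'
#' Draws \eqn{(4L + 1) \times per\_class} (alpha, beta) pairs from the
#' bivariate normal of the preference model and sorts them ascending by the
#' model's ranking key. The sorted pool is partitioned into `4L + 1`
#' contiguous rank blocks of `per_class` pairs, one block per preference
#' genotype value \eqn{-2L, \dots, +2L}: a female whose preference genotype is
#' the minimum draws her phenotype from the lowest-ranked block, and so on.
#' For `L = 5` the pool holds 1050 pairs; for `L = 10`, 2050.
#'
#' @param model A [preference_model()].
#' @param L Loci per trait.
#' @return A tibble with columns `rank`, `alpha`, `beta` (rows sorted by the
#'   ranking key) and attributes `L`, `per_class`.
#' @export
draw_pref_pool <- function(model, L) {
  n <- (4L * L + 1L) * model$per_class
  draws <- MASS::mvrnorm(n, c(model$mu_alpha, model$mu_beta), model$sigma)
  key <- if (model$pool_sort == "beta") draws[, 2L] else draws[, 1L]
  ord <- order(key)
  pool <- tibble::tibble(
    rank = seq_len(n),
    alpha = draws[ord, 1L],
    beta = draws[ord, 2L]
  )
  attr(pool, "L") <- as.integer(L)
  attr(pool, "per_class") <- model$per_class
  attr(pool, "pool_sort") <- model$pool_sort
  class(pool) <- c("pref_pool", class(pool))
  pool
}

#' Assign a preference phenotype from the pool
#'
#' Maps each preference genotype value to its rank block of the sorted pool
#' and draws one (alpha, beta) pair uniformly at random from that block. This
#' ties the phenotype to the genotype while retaining within-class noise.
#'
#' @param pref_value Integer vector of preference genotype values in
#'   \eqn{[-2L, +2L]}.
#' @param pool A pool from [draw_pref_pool()].
#' @return A tibble with one row per female: columns `alpha`, `beta`.
#' @export
assign_preference <- function(pref_value, pool) {
  L <- attr(pool, "L")
  pc <- attr(pool, "per_class")
  if (is.null(L) || is.null(pc)) stop("pool lacks rank-bin attributes; use draw_pref_pool()")
  if (any(pref_value < -2L * L | pref_value > 2L * L)) {
    stop("preference genotype value outside [-2L, 2L]")
  }
  cls <- as.integer(pref_value) + 2L * L # 0-based class index
  idx <- cls * pc + sample.int(pc, length(pref_value), replace = TRUE)
  tibble::tibble(alpha = pool$alpha[idx], beta = pool$beta[idx])
}

#' Copulation probability
#'
#' Logistic mate-acceptance probability for a female with intercept `alpha`
#' and male-size slope `beta` meeting a male of z-scored size `male_z`, the
#' female's own z-scored size `female_z` entering through the fixed slope:
#' \deqn{p = \mathrm{logit}^{-1}(\alpha + s_F F + \beta M).}
#' Computed with [stats::plogis()] and clamped into the open interval (0, 1)
#' so that extreme linear predictors saturate smoothly without ever returning
#' exactly 0 or 1.
#'
#' @param alpha,beta Female-specific intercept and slope (vectors recycle).
#' @param female_z,male_z z-scored female and male sizes.
#' @param female_size_slope Fixed female-size effect (default -2.9).
#' @return Probabilities strictly inside (0, 1).
#' @export
#' @examples
#' mating_probability(0.95, 0.52, 0, 0) # acceptance of an average male
mating_probability <- function(alpha, beta, female_z, male_z,
                               female_size_slope = -2.9) {
  p <- plogis(alpha + female_size_slope * female_z + beta * male_z)
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}
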