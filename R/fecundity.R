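#' Fecundity model
#'
#' After copulating, a female lays eggs with probability `p_eggs` (0.695 in
#' the calibrated system). If she lays, the brood size is negative-binomial
#' with a sire-size-dependent mean
#' \deqn{\mu = e^{a + b M},\qquad a = 3.36,\ b = 0.42,}
#' where `M` is the sire's z-scored size, and a dispersion `k` drawn per
#' mating from the empirical pool `k_pool` (mean about 3.8; `k` does not
#' depend on male size).
#'
#' The residual term of the mean model has SD `sigma_eps = 13.15`. Written
#' literally inside the exponent this would multiply broods by factors up to
#' e^40, which is neither biologically nor numerically plausible for mean
#' broods of ~29 young, so by default the residual is treated as additive on
#' the count scale (`error_mode = "response_scale"`, with the mean floored at
#' `mu_min`); `"literal_log_scale"` keeps the exponent form for comparison.
#'
#' @param p_eggs Probability a mated female lays eggs.
#' @param a,b Intercept and slope of the log-mean on sire size z-score.
#' @param sigma_eps Residual SD of the mean model.
#' @param k_pool Numeric vector of positive dispersion values; see
#'   [default_k_pool()] and [read_k_pool()].
#' @param error_mode `"response_scale"` (default) or `"literal_log_scale"`.
#' @param mu_min Floor on the mean in response-scale mode (keeps the negative
#'   binomial defined when the additive residual drives the mean below 0).
#' @return A `fecundity_model` list.
#' @export
fecundity_model <- function(p_eggs = 0.695, a = 3.36, b = 0.42,
                            sigma_eps = 13.15,
                            k_pool = NULL,
                            error_mode = c("response_scale", "literal_log_scale"),
                            mu_min = 0.1) {
  error_mode <- match.arg(error_mode)
  stopifnot(p_eggs >= 0, p_eggs <= 1, sigma_eps >= 0, mu_min > 0)
  if (!is.null(k_pool)) {
    if (!length(k_pool) || any(!is.finite(k_pool)) || any(k_pool <= 0)) {
      stop("k_pool must be a nonempty vector of positive finite values")
    }
  }
  structure(
    list(
      p_eggs = p_eggs, a = a, b = b, sigma_eps = sigma_eps,
      k_pool = k_pool, error_mode = error_mode, mu_min = mu_min
    ),
    class = "fecundity_model"
  )
}

#' Negative-binomial probability mass function
#'
#' Mean/dispersion parameterization
#' \deqn{f(y; k, \mu) = \frac{\Gamma(y+k)}{\Gamma(k)\,\Gamma(y+1)}
#'   \left(\frac{k}{\mu+k}\right)^k \left(1 - \frac{k}{\mu+k}\right)^y,}
#' evaluated through log-gamma for numerical stability. Variance is
#' \eqn{\mu + \mu^2/k}, always overdispersed relative to Poisson.
#'
#' @param y Nonnegative integer counts (vectorized).
#' @param mu Mean, > 0.
#' @param k Dispersion, > 0 (smaller k = more overdispersion).
#' @return Probabilities.
#' @export
negbin_pmf <- function(y, mu, k) {
  if (any(mu <= 0) || any(k <= 0)) stop("negative binomial requires mu > 0 and k > 0")
  if (any(y < 0) || any(y != floor(y))) stop("y must be nonnegative integers")
  exp(lgamma(y + k) - lgamma(k) - lgamma(y + 1) +
        k * (log(k) - log(mu + k)) + y * (log(mu) - log(mu + k)))
}

#' Moment estimator of the dispersion parameter
#'
#' \eqn{k = \mu^2 / (\sigma^2 - \mu)}, defined only under overdispersion
#' (`var > mu`).
#'
#' @param mu Mean (> 0).
#' @param var Variance (> mu).
#' @return The dispersion k.
#' @export
dispersion_from_moments <- function(mu, var) {
  stopifnot(length(mu) == length(var))
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(var <= mu)) {
    stop("variance must exceed the mean (k undefined under equi/underdispersion)")
  }
  mu^2 / (var - mu)
}

#' Sire-size-dependent mean brood size
#'
#' @param male_z Sire z-scored sizes (vectorized).
#' @param model A [fecundity_model()].
#' @return Positive means, one per sire.
#' @export
mean_offspring <- function(male_z, model) {
  n <- length(male_z)
  base <- model$a + model$b * male_z
  if (model$error_mode == "literal_log_scale") {
    eps <- if (model$sigma_eps > 0) rnorm(n, 0, model$sigma_eps) else 0
    exp(base + eps)
  } else {
    eps <- if (model$sigma_eps > 0) rnorm(n, 0, model$sigma_eps) else 0
    pmax(exp(base) + eps, model$mu_min)
  }
}

#' Egg-laying decision
#'
#' @param n Number of independent Bernoulli decisions.
#' @param model A [fecundity_model()].
#' @return Logical vector, TRUE with probability `p_eggs`.
#' @export
lays_eggs <- function(n, model) {
  runif(n) < model$p_eggs
}

#' Sample brood sizes
#'
#' For each mating, draws a dispersion k uniformly from the model's pool, a
#' mean from [mean_offspring()], and one negative-binomial count.
#'
#' @inheritParams mean_offspring
#' @return Nonnegative integer counts.
#' @export
sample_offspring_count <- function(male_z, model) {
  if (is.null(model$k_pool) || !length(model$k_pool)) {
    stop("fecundity model has an empty dispersion pool")
  }
  n <- length(male_z)
  if (n == 0L) return(integer(0))
  k <- model$k_pool[sample.int(length(model$k_pool), n, replace = TRUE)]
  mu <- mean_offspring(male_z, model)
  rnbinom(n, size = k, mu = mu)
}

#' Synthetic dispersion pool
#'
#' Gamma-distributed stand-in for the empirically derived dispersion pool K
#' (mean 3.8): strictly positive with moderate spread (shape 4 by default).
#' Supply a file-based pool via [read_k_pool()] when empirical values are
#' available.
#'
#' @param n Pool size.
#' @param mean Target mean (default 3.8).
#' @param shape Gamma shape (default 4).
#' @return Numeric vector of n positive values.
#' @export
default_k_pool <- function(n, mean = 3.8, shape = 4) {
  stopifnot(n >= 1, mean > 0, shape > 0)
  rgamma(n, shape = shape, rate = shape / mean)
}

#' Read a dispersion pool from a plain-text file
#'
#' One positive decimal value per line.
#'
#' @param path File path.
#' @return Numeric vector.
#' @export
read_k_pool <- function(path) {
  k <- scan(path, what = numeric(), quiet = TRUE)
  if (!length(k) || any(!is.finite(k)) || any(k <= 0)) {
    stop("k pool file must contain only positive finite values")
  }
  k
}
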