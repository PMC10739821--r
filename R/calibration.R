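#' Enumerate ordered triples of distinct males
#'
#' All ordered arrangements of 3 distinct indices from `n` items:
#' \eqn{n(n-1)(n-2)} triples, the grouping that turns 20 single-mating male
#' records into 6,840 overlapping groups for moment estimation.
#'
#' @param n Number of records (>= 3).
#' @return An integer matrix with 3 columns, one triple per row.
#' @export
enumerate_triples <- function(n) {
  if (n < 3L) stop("need at least 3 records to form triples")
  g <- expand.grid(k = seq_len(n), j = seq_len(n), i = seq_len(n))
  keep <- g$i != g$j & g$i != g$k & g$j != g$k
  out <- as.matrix(g[keep, c("i", "j", "k")])
  dimnames(out) <- NULL
  out
}

#' Per-triple moment statistics
#'
#' For each triple: mean male size `M_bar`, mean offspring count `mu`,
#' sample variance of counts `var` (n-1 denominator), and the moment
#' dispersion `k = mu^2 / (var - mu)`, `NA` when the triple is not
#' overdispersed.
#'
#' @param records Data frame with numeric columns `size` (z-scored male
#'   size) and `young` (offspring count).
#' @param triples Index matrix from [enumerate_triples()].
#' @return A tibble with columns `M_bar`, `mu`, `var`, `k`.
#' @export
triple_stats <- function(records, triples) {
  stopifnot(all(c("size", "young") %in% names(records)))
  if (max(triples) > nrow(records)) stop("triple index outside records")
  y1 <- records$young[triples[, 1L]]
  y2 <- records$young[triples[, 2L]]
  y3 <- records$young[triples[, 3L]]
  s1 <- records$size[triples[, 1L]]
  s2 <- records$size[triples[, 2L]]
  s3 <- records$size[triples[, 3L]]
  mu <- (y1 + y2 + y3) / 3
  v <- ((y1 - mu)^2 + (y2 - mu)^2 + (y3 - mu)^2) / 2
  k <- ifelse(v > mu, mu^2 / (v - mu), NA_real_)
  tibble::tibble(M_bar = (s1 + s2 + s3) / 3, mu = mu, var = v, k = k)
}

#' Filter the dispersion values into a usable pool
#'
#' Drops undefined and nonpositive k, then removes outliers by the 1.5 x IQR
#' rule.
#'
#' @param k Numeric vector of dispersion values (NA = undefined).
#' @param iqr_mult Outlier multiplier (1.5).
#' @return The surviving positive k values.
#' @export
filter_k <- function(k, iqr_mult = 1.5) {
  k <- k[!is.na(k) & is.finite(k) & k > 0]
  if (!length(k)) stop("no positive, defined dispersion values to pool")
  q <- quantile(k, c(0.25, 0.75), names = FALSE)
  iqr <- q[2L] - q[1L]
  out <- k[k >= q[1L] - iqr_mult * iqr & k <= q[2L] + iqr_mult * iqr]
  if (!length(out)) stop("all dispersion values removed as outliers")
  out
}

#' Fit the log-linear size-fecundity relationship
#'
#' Ordinary least squares of `log(mu)` on mean male size over the triple
#' statistics, giving the exponential mean model
#' \eqn{\mu = e^{a + b M}}. The residual SD is reported on both the log and
#' the response (count) scale, to inform the choice of error mode in
#' [fecundity_model()].
#'
#' @param stats Tibble from [triple_stats()] (rows with `mu <= 0` are
#'   dropped).
#' @return A list: `a`, `b`, `sigma_log`, `sigma_response`, `n_used`.
#' @export
fit_log_linear <- function(stats) {
  d <- stats[is.finite(stats$mu) & stats$mu > 0, ]
  if (nrow(d) < 3L) stop("need at least 3 triples with positive mean counts")
  if (sd(d$M_bar) == 0) stop("degenerate design: all group mean sizes equal")
  fit <- lm(log(mu) ~ M_bar, data = d)
  co <- unname(coef(fit))
  list(
    a = co[1L], b = co[2L],
    sigma_log = sd(residuals(fit)),
    sigma_response = sd(d$mu - exp(fitted(fit))),
    n_used = nrow(d)
  )
}

#' Generate synthetic single-mating male records
#'
#' Stand-in for an empirical per-male (size, offspring count) table: sizes
#' standard normal then z-scored; counts negative-binomial with mean
#' \eqn{e^{a + b \cdot size}} and dispersion `k_true`.
#'
#' @param n Number of males.
#' @param a,b Log-mean intercept and slope (defaults 3.36, 0.42).
#' @param k_true Dispersion (default 3.8).
#' @return A tibble with columns `size` (z-scored), `young`.
#' @export
synthetic_males <- function(n, a = 3.36, b = 0.42, k_true = 3.8) {
  stopifnot(n >= 3L)
  size <- as.numeric(scale(rnorm(n)))
  young <- rnbinom(n, size = k_true, mu = exp(a + b * size))
  tibble::tibble(size = size, young = young)
}

#' Calibrate the fecundity model from male records
#'
#' The full permutation pipeline: z-score sizes, enumerate all ordered
#' triples of distinct males, compute per-triple moments, pool the filtered
#' dispersion values, and fit the log-linear mean model.
#'
#' @param records Data frame with columns `size` (raw or z-scored; z-scored
#'   internally) and `young`.
#' @param iqr_mult Outlier rule multiplier for the dispersion pool.
#' @return A `fecundity_calibration` object: the fitted `a`, `b`, residual
#'   SDs on both scales, the dispersion pool, and bookkeeping counts.
#' @export
#' @examples
#' set.seed(1)
#' calibrate_fecundity(synthetic_males(20))
calibrate_fecundity <- function(records, iqr_mult = 1.5) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("size", "young") %in% names(records)))
  if (any(records$young < 0)) stop("offspring counts must be nonnegative")
  records$size <- as.numeric(scale(records$size))
  triples <- enumerate_triples(nrow(records))
  stats <- triple_stats(records, triples)
  k_pool <- filter_k(stats$k, iqr_mult = iqr_mult)
  fit <- fit_log_linear(stats)
  structure(
    list(
      a = fit$a, b = fit$b,
      sigma_log = fit$sigma_log, sigma_response = fit$sigma_response,
      k_pool = k_pool, k_mean = mean(k_pool),
      n_males = nrow(records), n_triples = nrow(triples),
      n_k_defined = sum(!is.na(stats$k) & stats$k > 0),
      stats = stats
    ),
    class = "fecundity_calibration"
  )
}

#' Read per-male records from a TSV/CSV file
#'
#' Requires a header with columns `size` and `young`.
#'
#' @param path File path (delimiter inferred by readr).
#' @return A tibble.
#' @export
read_male_records <- function(path) {
  d <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("size", "young") %in% names(d))) {
    stop("records file needs `size` and `young` columns")
  }
  tibble::as_tibble(d[, c("size", "young")])
}

#' @export
print.fecundity_calibration <- function(x, ...) {
  cat("Fecundity calibration (triple permutation)\n")
  cat(sprintf("  males: %d, ordered triples: %d\n", x$n_males, x$n_triples))
  cat(sprintf("  mu = exp(%.3f + %.3f M)\n", x$a, x$b))
  cat(sprintf("  residual SD: %.3f (log scale), %.2f (count scale)\n",
              x$sigma_log, x$sigma_response))
  cat(sprintf("  k pool: %d values, mean %.2f\n",
              length(x$k_pool), x$k_mean))
  invisible(x)
}

#' @rdname calibrate_fecundity
#' @param x A `fecundity_calibration`.
#' @param ... Unused.
#' @method tidy fecundity_calibration
#' @export
tidy.fecundity_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b"),
    estimate = c(x$a, x$b)
  )
}

#' @rdname calibrate_fecundity
#' @method glance fecundity_calibration
#' @export
glance.fecundity_calibration <- function(x, ...) {
  tibble::tibble(
    a = x$a, b = x$b, sigma_log = x$sigma_log,
    sigma_response = x$sigma_response, k_mean = x$k_mean,
    n_males = x$n_males, n_triples = x$n_triples,
    n_k_pool = length(x$k_pool)
  )
}
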