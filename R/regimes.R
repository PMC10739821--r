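#' Default histogram bin edges
#'
#' Fixed, configuration-derived edges so that histograms are comparable
#' across generations: sizes span the genotype range \eqn{[-2L, 2L]} padded
#' by four environmental SDs, preference genotypes use unit bins.
#'
#' @param L Loci per trait.
#' @param env_sd Environmental noise SD.
#' @return List with elements `size` and `pref` (numeric edge vectors).
#' @export
default_bins <- function(L, env_sd = 0) {
  pad <- 4 * env_sd + 0.5
  list(
    size = seq(-2 * L - pad, 2 * L + pad, length.out = 41L),
    pref = seq(-2 * L - 0.5, 2 * L + 0.5, by = 1)
  )
}

hist_counts <- function(x, edges) {
  # clamp into the edge range so counts always sum to length(x)
  x <- pmin(pmax(x, edges[1L]), edges[length(edges)])
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(edges) - 1L)
  tabulate(idx, nbins = length(edges) - 1L)
}

#' Summarize a population into one generation record
#'
#' Per-trait means, variances and fixed-bin histograms for male size, female
#' size, pooled size, preference genotype, and the female preference
#' phenotypes alpha and beta.
#'
#' @param pop A `spider_pop` or a data frame with columns `sex`, `size`,
#'   `pref_value`, `alpha`, `beta`.
#' @param bins Bin edges from [default_bins()] (or `NULL` to derive them from
#'   the data range — only sensible for a single standalone summary).
#' @return A one-row tibble; histogram columns are list-columns of counts.
#' @export
summarize_population <- function(pop, bins = NULL) {
  tbl <- if (inherits(pop, "spider_pop")) pop$tbl else tibble::as_tibble(pop)
  gen <- if (inherits(pop, "spider_pop")) pop$generation else NA_integer_
  if (nrow(tbl) == 0L) stop("cannot summarize an empty population")
  if (is.null(bins)) {
    r <- range(tbl$size)
    bins <- list(size = seq(r[1L] - 0.5, r[2L] + 0.5, length.out = 41L),
                 pref = seq(min(tbl$pref_value) - 0.5,
                            max(tbl$pref_value) + 0.5, by = 1))
  }
  m <- tbl$sex == "M"
  fem <- !m
  v0 <- function(x) if (length(x) > 1L) var(x) else 0
  tibble::tibble(
    generation = gen,
    n_males = sum(m), n_females = sum(fem),
    size_mean = mean(tbl$size), size_var = v0(tbl$size),
    size_skew = if (nrow(tbl) > 2L && v0(tbl$size) > 0) e1071::skewness(tbl$size, type = 2) else 0,
    male_size_mean = mean(tbl$size[m]), male_size_var = v0(tbl$size[m]),
    female_size_mean = mean(tbl$size[fem]), female_size_var = v0(tbl$size[fem]),
    pref_mean = mean(tbl$pref_value), pref_var = v0(tbl$pref_value),
    alpha_mean = mean(tbl$alpha[fem]), alpha_var = v0(tbl$alpha[fem]),
    beta_mean = mean(tbl$beta[fem]), beta_var = v0(tbl$beta[fem]),
    size_hist = list(hist_counts(tbl$size, bins$size)),
    pref_hist = list(hist_counts(tbl$pref_value, bins$pref)),
    size_edges = list(bins$size), pref_edges = list(bins$pref)
  )
}

# ---- dip statistic ----------------------------------------------------------

# Empirical excess mass of at most `m` modes at level lambda, computed by a
# prefix-scan DP over candidate index intervals; O(n) per level per mode.
excess_mass_em <- function(x_sorted, lam) {
  n <- length(x_sorted)
  i <- seq_len(n)
  a <- lam * x_sorted - (i - 1) / n # value of opening an interval at i
  close_j <- i / n - lam * x_sorted # value of closing it at j
  c1 <- close_j + cummax(a)
  e1 <- max(c1)
  best_end <- cummax(c1) # best single interval inside [1..j]
  a2 <- a + c(0, best_end[-n]) # open a second interval after an earlier one
  e2 <- max(close_j + cummax(a2))
  c(e1 = e1, e2 = e2)
}

#' Hartigan's dip statistic
#'
#' Departure of the empirical distribution from the closest unimodal
#' distribution function, computed through the excess-mass characterization:
#' the dip equals half the largest difference, over density levels
#' \eqn{\lambda}, between the best two-interval and the best one-interval
#' excess mass. Levels are scanned on a log grid spanning the data-driven
#' slope range, iteratively refined around the maximum, plus the
#' zero-length-interval limit (which contributes exactly the second-largest
#' tie multiplicity divided by n, so a sample of n distinct equally spaced
#' points attains the theoretical minimum 1/(2n)).
#'
#' @param x Numeric sample.
#' @param n_lambda Grid size per refinement pass.
#' @param refine Number of refinement passes around the running maximum.
#' @return The dip statistic (0 for constant samples).
#' @export
dip_statistic <- function(x, n_lambda = 201L, refine = 2L) {
  x <- sort(as.numeric(x[is.finite(x)]))
  n <- length(x)
  if (n < 2L || x[1L] == x[n]) return(0)
  # zero-length-interval limit: two point masses vs one
  mult <- sort(tabulate(match(x, unique(x))), decreasing = TRUE)
  d_inf <- if (length(mult) >= 2L) mult[2L] / n else 0
  gaps <- diff(unique(x))
  lam_hi <- 2 / (n * min(gaps)) * 4
  lam_lo <- (1 / n) / (x[n] - x[1L]) / 4
  best <- d_inf
  lo <- lam_lo
  hi <- lam_hi
  for (pass in seq_len(refine + 1L)) {
    lam <- exp(seq(log(lo), log(hi), length.out = n_lambda))
    dd <- vapply(lam, function(l) {
      em <- excess_mass_em(x, l)
      em[["e2"]] - em[["e1"]]
    }, numeric(1))
    i <- which.max(dd)
    best <- max(best, dd[i])
    lo <- lam[max(1L, i - 1L)]
    hi <- lam[min(n_lambda, i + 1L)]
  }
  best / 2
}

# cached Monte-Carlo null distribution of the dip under uniform sampling
dip_null <- function(n, n_boot) {
  key <- paste0("dipnull_", n, "_", n_boot)
  if (!is.null(the[[key]])) return(the[[key]])
  null <- vapply(seq_len(n_boot), function(i) dip_statistic(runif(n)),
                 numeric(1))
  the[[key]] <- null
  null
}

#' Sample skewness/kurtosis bimodality coefficient
#'
#' \eqn{BC = (g_1^2 + 1) / (g_2 + 3 (n-1)^2 / ((n-2)(n-3)))} with
#' bias-corrected sample skewness \eqn{g_1} and excess kurtosis \eqn{g_2}.
#' The uniform distribution sits at the conventional bimodality boundary
#' 5/9.
#'
#' @param x Numeric sample with at least 4 values.
#' @return The coefficient.
#' @export
bimodality_coefficient <- function(x) {
  n <- length(x)
  stopifnot(n >= 4L)
  g1 <- e1071::skewness(x, type = 2)
  g2 <- e1071::kurtosis(x, type = 2)
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Test a sample for bimodality
#'
#' Combines the dip statistic (Monte-Carlo p-value against a uniform null of
#' the same size) with the bimodality coefficient: the sample is called
#' bimodal when dip p < `p_threshold` and the coefficient exceeds
#' `bc_threshold` (5/9, the uniform boundary). Samples larger than `max_n`
#' are subsampled for the dip computation.
#'
#' Both the dip and the coefficient assume continuous data. Traits measured
#' on a lattice (realized size without environmental noise is an integer, the
#' genotype resolution) concentrate on a few adjacent support points near
#' fixation, which a continuity-assuming test misreads as multimodality.
#' `dither = "auto"` (default) therefore adds uniform noise of plus/minus
#' half the smallest positive spacing between distinct values — the exact
#' de-discretization of the lattice, with no effect on genuinely separated
#' modes and a vanishing effect on continuous data.
#'
#' @param x Numeric sample (at least 50 values).
#' @param n_boot Monte-Carlo replicates for the null.
#' @param max_n Subsample cap for the dip computation.
#' @param p_threshold,bc_threshold Decision thresholds.
#' @param dither `"auto"`, `"none"`, or a numeric half-width of uniform
#'   dither applied before testing.
#' @return One-row tibble: `is_bimodal`, `dip`, `dip_p`, `bc`, `n`.
#' @export
detect_bimodality <- function(x, n_boot = 200L, max_n = 1000L,
                              p_threshold = 0.01, bc_threshold = 5 / 9,
                              dither = "auto") {
  x <- x[is.finite(x)]
  if (length(x) < 50L) stop("need at least 50 values to assess bimodality")
  if (length(x) > max_n) x <- sample(x, max_n)
  if (identical(dither, "auto")) {
    u <- sort(unique(x))
    dither <- if (length(u) > 1L) min(diff(u)) / 2 else 0
  } else if (identical(dither, "none")) {
    dither <- 0
  }
  if (dither > 0) x <- x + runif(length(x), -dither, dither)
  d <- dip_statistic(x)
  null <- dip_null(length(x), n_boot)
  p <- (1 + sum(null >= d)) / (n_boot + 1)
  bc <- bimodality_coefficient(x)
  tibble::tibble(
    is_bimodal = p < p_threshold && bc > bc_threshold,
    dip = d, dip_p = p, bc = bc, n = length(x)
  )
}

#' Classifier thresholds
#'
#' The thresholds operationalizing the by-eye regime judgement. Slopes and
#' displacements are in units of the initial trait SD; `block` is the width
#' (generations) of the block-averaging applied to the mean trajectory
#' before measuring counter-movements.
#'
#' @param slope_min Minimum |least-squares slope| of the mean, initial SDs
#'   per generation, for a directional call.
#' @param displacement_min Minimum |net standardized displacement| for a
#'   directional call.
#' @param drawdown_max Maximum counter-movement (initial SDs, block-averaged
#'   trajectory) tolerated in a directional call.
#' @param var_ratio_max Maximum final/initial variance ratio for a
#'   stabilizing call.
#' @param stab_displacement_max Maximum |net standardized displacement| for a
#'   stabilizing call.
#' @param dip_p,bc Bimodality thresholds passed to [detect_bimodality()].
#' @param block Block width in generations.
#' @return A list of thresholds.
#' @export
regime_thresholds <- function(slope_min = 0.02, displacement_min = 1,
                              drawdown_max = 0.5, var_ratio_max = 0.5,
                              stab_displacement_max = 0.5,
                              dip_p = 0.01, bc = 5 / 9, block = 5L) {
  list(slope_min = slope_min, displacement_min = displacement_min,
       drawdown_max = drawdown_max, var_ratio_max = var_ratio_max,
       stab_displacement_max = stab_displacement_max,
       dip_p = dip_p, bc = bc, block = as.integer(block))
}

block_means <- function(x, block) {
  g <- ceiling(seq_along(x) / block)
  as.numeric(tapply(x, g, mean))
}

#' Classify the selection regime of a run
#'
#' Makes the histogram-based judgement explicit: the trajectory of the trait
#' mean and variance across generations, plus a bimodality test on the raw
#' trait values pooled over the trailing generations, yield exactly one of
#' four calls.
#'
#' * **disruptive** — the pooled final-window values are bimodal
#'   ([detect_bimodality()]); takes precedence because a splitting
#'   population can also drift in mean.
#' * **directional** — the mean moves at least `displacement_min` initial
#'   SDs net, never retracing more than `drawdown_max` initial SDs (on the
#'   block-averaged trajectory), with |LS slope| at least `slope_min`
#'   initial SDs per generation.
#' * **stabilizing** — final/initial variance ratio below `var_ratio_max`
#'   with |net displacement| below `stab_displacement_max` initial SDs.
#' * **none** — anything else (e.g. a mean drifting back and forth).
#'
#' All decision quantities are in initial-SD units, so the call is invariant
#' to affine rescaling of the trait axis.
#'
#' @param x A `prefsel_sim` object, or a history tibble (needs >= 20
#'   generation rows with `<trait>_mean` and `<trait>_var` columns).
#' @param trait `"size"` or `"pref"`.
#' @param final_values Raw trait values of the trailing generations for the
#'   bimodality test; taken from the simulation object when `x` is one.
#' @param thresholds See [regime_thresholds()].
#' @param ... Unused.
#' @return A one-row tibble: `regime`, `trend_slope` (raw units/generation),
#'   `slope_sd` (initial SDs/generation), `displacement_sd`, `drawdown_sd`,
#'   `sign_consistency`, `variance_ratio`, `dip`, `dip_p`, `bc`,
#'   `window_start`, `window_end`.
#' @export
classify_regime <- function(x, trait = c("size", "pref"),
                            final_values = NULL,
                            thresholds = regime_thresholds(), ...) {
  trait <- match.arg(trait)
  if (inherits(x, "prefsel_sim")) {
    history <- x$history
    if (is.null(final_values) && trait == "size") {
      final_values <- unlist(x$final_sizes, use.names = FALSE)
    }
  } else {
    history <- tibble::as_tibble(x)
  }
  if (nrow(history) < 20L) {
    stop("need at least 20 generations of history to classify a regime")
  }
  mu <- history[[paste0(trait, "_mean")]]
  v <- history[[paste0(trait, "_var")]]
  if (is.null(mu) || is.null(v)) {
    stop(sprintf("history lacks %s_mean / %s_var columns", trait, trait))
  }
  ngen <- length(mu)
  sd0 <- sqrt(v[1L])
  if (sd0 == 0) sd0 <- 1e-12

  gen <- seq_len(ngen)
  slope <- unname(coef(lm(mu ~ gen))[2L])
  blk <- block_means(mu, thresholds$block)
  disp <- (mean(tail(mu, thresholds$block)) - mean(head(mu, thresholds$block))) / sd0
  s <- if (disp >= 0) 1 else -1
  dd <- max(cummax(s * blk) - s * blk) / sd0
  steps <- diff(mu)
  sign_cons <- if (length(steps)) mean(sign(steps) == s) else NA_real_
  var_ratio <- mean(tail(v, thresholds$block)) / v[1L]

  bim <- NULL
  if (!is.null(final_values) && length(final_values) >= 50L) {
    bim <- detect_bimodality(final_values,
                             p_threshold = thresholds$dip_p,
                             bc_threshold = thresholds$bc)
  }

  regime <- if (!is.null(bim) && bim$is_bimodal) {
    "disruptive"
  } else if (abs(disp) >= thresholds$displacement_min &&
             dd <= thresholds$drawdown_max &&
             abs(slope) / sd0 >= thresholds$slope_min) {
    "directional"
  } else if (var_ratio < thresholds$var_ratio_max &&
             abs(disp) < thresholds$stab_displacement_max) {
    "stabilizing"
  } else {
    "none"
  }

  tibble::tibble(
    regime = regime,
    trend_slope = slope,
    slope_sd = slope / sd0,
    displacement_sd = disp,
    drawdown_sd = dd,
    sign_consistency = sign_cons,
    variance_ratio = var_ratio,
    dip = if (is.null(bim)) NA_real_ else bim$dip,
    dip_p = if (is.null(bim)) NA_real_ else bim$dip_p,
    bc = if (is.null(bim)) NA_real_ else bim$bc,
    window_start = if (!is.null(history$generation)) history$generation[1L] else 1L,
    window_end = if (!is.null(history$generation)) history$generation[ngen] else ngen
  )
}
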