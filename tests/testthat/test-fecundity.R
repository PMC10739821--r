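test_that("negative-binomial pmf matches closed forms and independent routes", {
  # y = 0 collapses to (k/(mu+k))^k
  expect_equal(negbin_pmf(0, mu = 28.8, k = 3.8), (3.8 / 32.6)^3.8, tolerance = 1e-14)

  # normalization over an ample support
  mu <- 28.8; k <- 3.8
  yy <- 0:ceiling(mu + 20 * sqrt(mu + mu^2 / k))
  expect_gte(sum(negbin_pmf(yy, mu, k)), 0.9999)

  # ratio-recurrence oracle: pmf(y+1)/pmf(y) = (y+k)/(y+1) * mu/(mu+k)
  p <- negbin_pmf(0, mu, k)
  for (y in 0:200) {
    expect_equal(negbin_pmf(y, mu, k), p, tolerance = 1e-12)
    p <- p * (y + k) / (y + 1) * mu / (mu + k)
  }

  # agrees with the base distribution function
  expect_equal(negbin_pmf(0:100, mu, k), dnbinom(0:100, size = k, mu = mu),
               tolerance = 1e-13)

  # Poisson limit for huge k
  expect_equal(negbin_pmf(0:20, mu = 5, k = 1e6), dpois(0:20, 5),
               tolerance = 1e-4)

  expect_error(negbin_pmf(3, mu = -1, k = 2))
  expect_error(negbin_pmf(-1, mu = 1, k = 2))
})

test_that("moment dispersion inverts the variance relation", {
  expect_equal(dispersion_from_moments(2, 4), 2)
  expect_equal(dispersion_from_moments(3, 6), 3)
  expect_error(dispersion_from_moments(5, 5), "exceed")
  expect_error(dispersion_from_moments(5, 4), "exceed")
  # exact inversion: k = mu^2 / ((mu + mu^2/k) - mu)
  for (mu in c(0.5, 3, 28.8)) for (k in c(0.4, 3.8, 50)) {
    expect_equal(dispersion_from_moments(mu, mu + mu^2 / k), k, tolerance = 1e-12)
  }
})

test_that("mean brood size follows the exponential size model", {
  m0 <- fecundity_model(sigma_eps = 0)
  expect_equal(mean_offspring(0, m0), exp(3.36), tolerance = 1e-12)
  expect_equal(mean_offspring(1, m0) / mean_offspring(0, m0), exp(0.42),
               tolerance = 1e-12)

  # response-scale error: additive, zero-mean, floored
  set.seed(301)
  mr <- fecundity_model(sigma_eps = 13.15)
  mus <- mean_offspring(rep(0, 50000), mr)
  expect_true(all(mus >= mr$mu_min))
  # floor truncation at mu_min barely moves the mean (P(eps < -28.8) ~ 1.4%)
  expect_lt(abs(mean(mus) - exp(3.36)), 0.3)

  # literal mode keeps the error inside the exponent
  ml <- fecundity_model(sigma_eps = 0, error_mode = "literal_log_scale")
  expect_equal(mean_offspring(0.5, ml), exp(3.36 + 0.21), tolerance = 1e-12)
})

test_that("egg laying is Bernoulli(0.695)", {
  set.seed(302)
  expect_true(all(lays_eggs(100, fecundity_model(p_eggs = 1))))
  expect_false(any(lays_eggs(100, fecundity_model(p_eggs = 0))))
  frac <- mean(lays_eggs(100000, fecundity_model()))
  expect_lt(abs(frac - 0.695), 0.005)
})

test_that("brood sampling has negative-binomial mean, variance and law", {
  set.seed(303)
  m <- fecundity_model(sigma_eps = 0, k_pool = 3.8)
  y <- sample_offspring_count(rep(0, 100000), m)
  expect_true(all(y >= 0) && all(y == floor(y)))
  mu <- exp(3.36)
  expect_lt(abs(mean(y) - mu), 0.5)
  expect_lt(abs(var(y) / (mu + mu^2 / 3.8) - 1), 0.05)

  # chi-square goodness of fit against the pmf
  brk <- c(0:119, Inf)
  obs <- table(cut(y, c(-1, brk)))
  pr <- c(negbin_pmf(0:119, mu, 3.8), 1 - sum(negbin_pmf(0:119, mu, 3.8)))
  keep <- pr * length(y) >= 5
  chi <- sum((obs[keep] - length(y) * pr[keep])^2 / (length(y) * pr[keep]))
  expect_gt(pchisq(chi, sum(keep) - 1, lower.tail = FALSE), 0.001)

  # monotone fecundity selection: expected brood strictly increasing in M
  grid <- seq(-2, 2, by = 0.5)
  expect_true(all(diff(mean_offspring(grid, m)) > 0))

  expect_error(sample_offspring_count(0, fecundity_model(k_pool = NULL)), "pool")
})

test_that("the synthetic dispersion pool is positive with mean near 3.8", {
  set.seed(304)
  k <- default_k_pool(10000)
  expect_true(all(k > 0))
  expect_lt(abs(mean(k) - 3.8), 0.1)
  # singleton pool degenerates to fixed-k sampling
  m1 <- fecundity_model(sigma_eps = 0, k_pool = 2)
  expect_length(sample_offspring_count(rep(0, 10), m1), 10)
})
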