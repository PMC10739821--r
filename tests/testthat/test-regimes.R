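test_that("population summaries agree with direct recomputation", {
  set.seed(501)
  pop <- init_population(tiny_config())
  bins <- default_bins(5, 0)
  rec <- summarize_population(pop, bins)
  tbl <- as_tibble(pop)
  expect_equal(rec$size_mean, mean(tbl$size), tolerance = 1e-12)
  expect_equal(rec$size_var, var(tbl$size), tolerance = 1e-12)
  expect_equal(rec$alpha_mean, mean(tbl$alpha[tbl$sex == "F"]), tolerance = 1e-12)
  expect_identical(sum(rec$size_hist[[1]]), nrow(tbl))
  expect_identical(sum(rec$pref_hist[[1]]), nrow(tbl))

  # identical individuals: zero variance, one occupied bin
  flat <- pop
  flat$tbl$size <- 3
  rf <- summarize_population(flat, bins)
  expect_identical(rf$size_var, 0)
  expect_identical(sum(rf$size_hist[[1]] > 0), 1L)

  expect_error(summarize_population(prefsel:::subset_population(pop, integer(0))),
               "empty")
})

test_that("dip statistic attains its exact anchors", {
  # equally spaced points: theoretical minimum 1/(2n)
  for (n in c(10, 50, 201)) {
    expect_equal(dip_statistic(seq_len(n)), 1 / (2 * n), tolerance = 1e-12)
  }
  # two equal point clusters: theoretical maximum 1/4
  x <- c(rep(0, 10), rep(1, 10))
  expect_equal(dip_statistic(x), 0.25, tolerance = 1e-12)
  # affine invariance
  expect_equal(dip_statistic(x * 37 - 11), 0.25, tolerance = 1e-12)
  expect_identical(dip_statistic(rep(2, 5)), 0)
})

test_that("excess-mass scan agrees with brute-force interval enumeration", {
  set.seed(502)
  for (rep in 1:5) {
    x <- sort(c(rnorm(7), rnorm(5, 4)))
    for (lam in c(0.01, 0.05, 0.2, 1, 5)) {
      fast <- prefsel:::excess_mass_em(x, lam)
      slow <- brute_excess_mass(x, lam)
      expect_equal(unname(fast), unname(slow), tolerance = 1e-12)
    }
  }
})

test_that("bimodality detection separates mixtures from unimodal samples", {
  set.seed(503)
  expect_false(detect_bimodality(rnorm(1000))$is_bimodal)
  mix <- c(rnorm(1000, -5), rnorm(1000, 5))
  bm <- detect_bimodality(mix)
  expect_true(bm$is_bimodal)
  expect_lt(bm$dip_p, 0.01)
  # uniform sits at the coefficient boundary and is not called bimodal
  u <- runif(2000)
  expect_lt(abs(bimodality_coefficient(u) - 5 / 9), 0.05)
  expect_false(detect_bimodality(u)$is_bimodal)
  expect_error(detect_bimodality(rnorm(10)), "at least 50")

  # independent cross-check: model-based clustering picks 2 components for
  # the mixture and 1 for the unimodal sample
  best_g <- function(x) {
    b <- mclust::mclustBIC(x, G = 1:3, modelNames = "V", verbose = FALSE)
    as.integer(rownames(b)[which.max(b[, "V"])])
  }
  expect_gte(best_g(mix), 2L)
  expect_identical(best_g(rnorm(500)), 1L)

  # lattice concentration near fixation is not misread as bimodality
  fix <- sample(c(9, 10), 2000, replace = TRUE, prob = c(0.35, 0.65))
  expect_false(detect_bimodality(fix)$is_bimodal)
})

test_that("constructed trajectories are classified as intended", {
  set.seed(504)
  gens <- 0:74
  base <- tibble::tibble(
    generation = gens,
    size_mean = 0, size_var = 1,
    pref_mean = 0, pref_var = 1
  )

  # mean rising 0.1 SD/generation, flat variance -> directional
  up <- base
  up$size_mean <- 0.1 * gens + rnorm(75, 0, 0.02)
  cl <- classify_regime(up, final_values = rnorm(500, 7.4))
  expect_identical(cl$regime, "directional")

  # flat mean, variance shrinking to 20% -> stabilizing
  st <- base
  st$size_var <- seq(1, 0.2, length.out = 75)
  st$size_mean <- rnorm(75, 0, 0.02)
  cl <- classify_regime(st, final_values = rnorm(500, 0, sqrt(0.2)))
  expect_identical(cl$regime, "stabilizing")

  # final two-component mixture -> disruptive, overriding any drift
  di <- base
  di$size_var <- seq(1, 9, length.out = 75)
  cl <- classify_regime(di, final_values = c(rnorm(400, -4), rnorm(400, 4)))
  expect_identical(cl$regime, "disruptive")

  # wandering drift: large excursions both ways -> none
  dr <- base
  dr$size_mean <- 2 * sin(gens / 8)
  cl <- classify_regime(dr, final_values = rnorm(500, dr$size_mean[75]))
  expect_identical(cl$regime, "none")

  # affine invariance of the call
  up2 <- up
  up2$size_mean <- up$size_mean * 13 + 5
  up2$size_var <- up$size_var * 169
  cl2 <- classify_regime(up2, final_values = rnorm(500, 7.4 * 13 + 5, 13))
  expect_identical(cl2$regime, "directional")

  expect_error(classify_regime(base[1:10, ]), "at least 20")
})
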