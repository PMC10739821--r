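test_that("the founding population matches the configured census and ranges", {
  set.seed(401)
  cfg <- simulation_config()
  pop <- init_population(cfg)
  tbl <- as_tibble(pop)
  expect_identical(sum(tbl$sex == "M"), 1000L)
  expect_identical(sum(tbl$sex == "F"), 1000L)
  expect_true(all(tbl$size == floor(tbl$size))) # integers without env noise
  expect_true(all(tbl$size >= -10 & tbl$size <= 10))
  expect_true(all(!tbl$mated))
  # preference phenotypes on females only
  expect_true(all(is.na(tbl$alpha[tbl$sex == "M"])))
  expect_true(all(is.finite(tbl$alpha[tbl$sex == "F"])))
  # approximately normal founding size distribution
  expect_lt(abs(e1071::skewness(tbl$size)), 0.15)
  expect_lt(abs(e1071::kurtosis(tbl$size)), 0.4)
})

test_that("z-scoring is per sex, exact, and location invariant", {
  set.seed(402)
  pop <- init_population(tiny_config())
  z <- zscore_sizes(pop)
  tbl <- as_tibble(z)
  for (s in c("M", "F")) {
    expect_lt(abs(mean(tbl$size_z[tbl$sex == s])), 1e-12)
    expect_lt(abs(sd(tbl$size_z[tbl$sex == s]) - 1), 1e-12)
  }
  shifted <- pop
  shifted$tbl$size <- shifted$tbl$size + 7
  expect_equal(as_tibble(zscore_sizes(shifted))$size_z, tbl$size_z)

  degen <- pop
  degen$tbl$size <- 0
  expect_error(zscore_sizes(degen), "degenerate")
})

test_that("mating season honours acceptance probabilities and the round cap", {
  cfg <- tiny_config()
  set.seed(403)

  # an always-accepting female mates in round 1
  eager <- handmade_pop(50, 50, alpha = 50, beta = 0)
  m <- mating_season(eager, cfg)
  expect_identical(nrow(m), 50L)
  expect_true(all(m$round == 1L))

  # never-accepting females produce zero matings
  frigid <- handmade_pop(50, 50, alpha = -Inf, beta = 0)
  m0 <- mating_season(frigid, cfg)
  expect_identical(nrow(m0), 0L)
  expect_identical(attr(m0, "n_unmated"), 50L)

  # single-round acceptance at the mean phenotypes ~ logistic(0.95)
  one <- handmade_pop(10000, 1, alpha = 0.95, beta = 0.52)
  cfg1 <- tiny_config(max_mating_rounds = 1)
  m1 <- mating_season(one, cfg1)
  expect_lt(abs(nrow(m1) / 10000 - 0.72112), 0.01)

  # mated females never re-enter the pool
  pop <- handmade_pop(100, 100, alpha = 0.95, beta = 0.52)
  mat <- mating_season(pop, cfg)
  pop$tbl$mated[mat$female] <- TRUE
  again <- mating_season(pop, cfg)
  expect_identical(length(intersect(again$female, mat$female)), 0L)
})

test_that("offspring production splits sexes evenly and respects egg probability", {
  set.seed(404)
  cfg <- tiny_config()
  pop <- zscore_sizes(init_population(cfg))
  mat <- mating_season(pop, cfg)

  cfg0 <- tiny_config(fec = fecundity_model(p_eggs = 0))
  empty <- produce_offspring(mat, pop, cfg0)
  expect_identical(nrow(as_tibble(empty)), 0L)

  counts <- prefsel:::offspring_counts(mat, prefsel:::resolve_fecundity(cfg))
  even <- counts$young %% 2L == 0L
  expect_true(all(counts$n_males[even] == counts$young[even] / 2L))
  expect_true(all(abs(counts$n_males - counts$n_females) <= 1L))
  # an odd leftover goes to either sex with probability 1/2
  odd <- counts$young %% 2L == 1L
  if (sum(odd) > 20) {
    expect_gt(mean(counts$n_males[odd] > counts$n_females[odd]), 0.2)
    expect_lt(mean(counts$n_males[odd] > counts$n_females[odd]), 0.8)
  }

  # replaying the same RNG state, the realized cohort matches the counts
  cfgk <- tiny_config(fec = fecundity_model(k_pool = default_k_pool(100)))
  pool <- draw_pref_pool(cfgk$pref, 5)
  set.seed(99)
  counts2 <- prefsel:::offspring_counts(mat, prefsel:::resolve_fecundity(cfgk))
  set.seed(99)
  cohort <- produce_offspring(mat, pop, cfgk, pool = pool)
  ct <- as_tibble(cohort)
  expect_identical(nrow(ct), as.integer(sum(counts2$young)))
  expect_identical(sum(ct$sex == "M"), as.integer(sum(counts2$n_males)))
  expect_lt(abs(mean(ct$sex == "M") - 0.5), 0.05)
  expect_true(all(ct$birth_gen == 1L))
})

test_that("advancing a generation enforces the cap and the overlap age rule", {
  set.seed(405)
  cfg <- simulation_config()
  pool <- draw_pref_pool(cfg$pref, 5)
  big <- prefsel:::build_individuals(
    rep("M", 14000), init_genotypes(14000, cfg$loci),
    init_genotypes(14000, cfg$loci), cfg, pool, 1L)
  parents <- init_population(cfg, pool)
  culled <- advance_generation(parents, big, cfg)
  expect_identical(sum(as_tibble(culled)$sex == "M"), 10000L)

  # below the cap nothing is removed
  small_cfg <- tiny_config()
  p0 <- init_population(small_cfg)
  coh <- prefsel:::build_individuals(
    rep(c("M", "F"), 50), init_genotypes(100, small_cfg$loci),
    init_genotypes(100, small_cfg$loci), small_cfg,
    draw_pref_pool(small_cfg$pref, 5), 1L)
  nxt <- advance_generation(p0, coh, small_cfg)
  expect_identical(nrow(as_tibble(nxt)), 100L)

  # overlap keeps parents but never grandparents
  ov <- tiny_config(overlap = TRUE, max_generations = 6)
  sim <- run_simulation(ov)
  expect_gt(nrow(sim$history), 3)
  # ages in the recorded pools are checked through birth_gen bookkeeping:
  # rerun manually for two steps
  set.seed(406)
  cfgo <- tiny_config(overlap = TRUE)
  pop <- init_population(cfgo)
  for (g in 1:3) {
    pop <- zscore_sizes(pop)
    mat <- mating_season(pop, cfgo)
    pop$tbl$mated[mat$female] <- TRUE
    coh <- produce_offspring(mat, pop, cfgo, generation = g)
    pop <- advance_generation(pop, coh, cfgo)
    expect_true(all(pop$tbl$birth_gen %in% c(g, g - 1L)))
  }
})

test_that("runs are reproducible, recorded, and capped throughout", {
  a <- run_simulation(tiny_config(seed = 777))
  b <- run_simulation(tiny_config(seed = 777))
  expect_equal(a$history, b$history)
  expect_identical(a$status, b$status)

  h <- a$history
  expect_true(all(h$n_males <= 400 & h$n_females <= 400))
  expect_identical(h$generation, 0:8)
  # summaries carry the mating bookkeeping
  expect_true(all(h$n_matings[-1] > 0))
  expect_true(all(h$n_matings[-1] + h$n_unmated[-1] <= 400 + h$n_females[-1]))

  # convergence stop: a flat model (no selection pressure at tiny alpha range)
  set.seed(407)
  sim <- run_simulation(tiny_config(converge = TRUE, max_generations = 60,
                                    converge_window = 8, seed = 5,
                                    fecundity_selection = FALSE))
  expect_true(sim$status %in% c("converged", "max_generations"))

  # tidy/glance interface
  td <- tidy(a)
  expect_s3_class(td, "tbl_df")
  expect_false(any(c("size_hist", "pref_hist") %in% names(td)))
  gl <- glance(a)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$size_mean_final, h$size_mean[nrow(h)])
})

test_that("population snapshots round-trip through TSV", {
  set.seed(408)
  pop <- init_population(tiny_config())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_population_tsv(pop, path)
  back <- read_population_tsv(path)
  expect_identical(back$size_alleles, pop$size_alleles)
  expect_identical(back$pref_alleles, pop$pref_alleles)
  expect_equal(as_tibble(back)$size, as_tibble(pop)$size)
})
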