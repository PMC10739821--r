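#' Simulation configuration
#'
#' Assembles the full parameter set for one run. The defaults are the
#' calibrated study conditions: 1000 founders per sex, per-sex cap of 10,000
#' after culling, 1% per-allele mutation, the empirical preference and
#' fecundity models, and free recombination over `L = 5` loci per trait.
#'
#' The eight base variants are the combinations of `L` in \{5, 10\},
#' `env_noise` on/off, and `overlap` on/off. Three experimental manipulations
#' probe the selection regime: `fecundity_selection = FALSE` removes the
#' dependence of brood size on sire size (slope b set to 0);
#' `force_alpha = -5` replaces every female's intercept so that average-sized
#' males are almost never accepted; `assortative_beta = TRUE` ties each
#' female's preference slope to her own size z-score
#' (\eqn{\beta_i = \mu_\beta + \sqrt{\sigma^2_\beta}\, F_i}, preserving the
#' marginal mean and SD of beta), which induces assortative mating by size.
#'
#' @param L Loci per trait.
#' @param env_noise Add environmental noise to size expression? `env_sd`
#'   defaults to the calibrated 1.5 (L = 5) or 2.16 (L = 10); for other L the
#'   genetic-to-environmental SD ratio of ~1.72 implied by those values is
#'   kept.
#' @param overlap Two overlapping generations? When on, the mating pool holds
#'   the newest cohort plus its parents' cohort, never grandparents.
#' @param fecundity_selection Brood size depends on sire size? (default TRUE)
#' @param force_alpha Optional value overriding every female's alpha at
#'   mating time (the -5 manipulation); `NULL` disables.
#' @param assortative_beta Tie female slope beta to own size z-score?
#' @param n_init_per_sex Founders per sex (1000).
#' @param cap_per_sex Per-sex cap enforced by uniform random culling (10,000).
#' @param mutation_rate Per-allele mutation probability (0.01).
#' @param max_generations Backstop generation count.
#' @param max_mating_rounds Rounds per mating season before remaining
#'   unmated females are recorded as childless (guards non-termination when
#'   acceptance probabilities are tiny).
#' @param converge Stop early once the size distribution is stationary?
#'   Judged on a sliding window of `converge_window` generations: absolute
#'   slope of mean size below `converge_slope_tol` per generation and
#'   relative variance change below `converge_var_tol`.
#' @param converge_window,converge_slope_tol,converge_var_tol Convergence
#'   window and tolerances.
#' @param zscore_ref Sizes are z-scored per sex within the current mating
#'   pool (`"per_generation"`, default: the empirical models were fitted on
#'   z-scored data and only relative size within the pool is meaningful as
#'   the mean evolves) or against the founding generation (`"initial"`).
#' @param fresh_pool Redraw the (alpha, beta) preference pool for every
#'   cohort (default) or keep the founders' pool fixed.
#' @param env_sd Override the environmental noise SD.
#' @param pref A [preference_model()].
#' @param fec A [fecundity_model()]; a `NULL` `k_pool` is filled with
#'   [default_k_pool()] (n = 1000) when the run starts.
#' @param two_subpop_init Initialize size genotypes as two fixed-allele
#'   subpopulations (half all -1, half all +1) instead of uniform draws.
#' @param keep_last How many trailing generations of raw pooled sizes to
#'   retain for bimodality assessment (default 5).
#' @param seed Optional integer seed; set for reproducible runs.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(L = 5L, env_noise = FALSE, overlap = FALSE,
                              fecundity_selection = TRUE,
                              force_alpha = NULL,
                              assortative_beta = FALSE,
                              n_init_per_sex = 1000L,
                              cap_per_sex = 10000L,
                              mutation_rate = 0.01,
                              max_generations = 100L,
                              max_mating_rounds = 200L,
                              converge = TRUE,
                              converge_window = 10L,
                              converge_slope_tol = 0.01,
                              converge_var_tol = 0.05,
                              zscore_ref = c("per_generation", "initial"),
                              fresh_pool = TRUE,
                              env_sd = NULL,
                              pref = preference_model(),
                              fec = fecundity_model(),
                              two_subpop_init = FALSE,
                              keep_last = 5L,
                              seed = NULL) {
  zscore_ref <- match.arg(zscore_ref)
  stopifnot(n_init_per_sex >= 2, cap_per_sex >= n_init_per_sex,
            max_generations >= 1, max_mating_rounds >= 1)
  if (is.null(env_sd)) {
    env_sd <- if (!env_noise) {
      0
    } else if (L == 5L) {
      1.5
    } else if (L == 10L) {
      2.16
    } else {
      # keep the calibrated genetic:environmental SD ratio (~1.72)
      sqrt(4 * L / 3) / 1.72
    }
  }
  loci <- loci_config(L = L, mutation_rate = mutation_rate, env_sd = env_sd)
  structure(
    list(
      loci = loci, pref = pref, fec = fec,
      env_noise = env_noise, overlap = overlap,
      fecundity_selection = fecundity_selection,
      force_alpha = force_alpha,
      assortative_beta = assortative_beta,
      n_init_per_sex = as.integer(n_init_per_sex),
      cap_per_sex = as.integer(cap_per_sex),
      max_generations = as.integer(max_generations),
      max_mating_rounds = as.integer(max_mating_rounds),
      converge = converge,
      converge_window = as.integer(converge_window),
      converge_slope_tol = converge_slope_tol,
      converge_var_tol = converge_var_tol,
      zscore_ref = zscore_ref,
      fresh_pool = fresh_pool,
      two_subpop_init = two_subpop_init,
      keep_last = as.integer(keep_last),
      seed = seed
    ),
    class = "sim_config"
  )
}

# ---- population container ---------------------------------------------------

new_population <- function(tbl, size_alleles, pref_alleles, generation = 0L) {
  stopifnot(nrow(tbl) == nrow(size_alleles), nrow(tbl) == nrow(pref_alleles))
  structure(
    list(tbl = tbl, size_alleles = size_alleles, pref_alleles = pref_alleles,
         generation = as.integer(generation)),
    class = "spider_pop"
  )
}

#' @export
print.spider_pop <- function(x, ...) {
  n <- table(factor(x$tbl$sex, levels = c("F", "M")))
  cat(sprintf("<spider_pop> generation %d: %d females, %d males (L = %d)\n",
              x$generation, n[["F"]], n[["M"]], ncol(x$size_alleles) %/% 2L))
  invisible(x)
}

#' Phenotype table of a population
#'
#' @param x A `spider_pop`.
#' @param ... Unused.
#' @return A tibble with one row per individual: `sex`, `size`, `pref_value`,
#'   `alpha`, `beta` (females), `mated`, `birth_gen`, and `size_z` if the
#'   population has been z-scored.
#' @method as_tibble spider_pop
#' @export
as_tibble.spider_pop <- function(x, ...) {
  x$tbl
}

subset_population <- function(pop, idx) {
  new_population(pop$tbl[idx, , drop = FALSE],
                 pop$size_alleles[idx, , drop = FALSE],
                 pop$pref_alleles[idx, , drop = FALSE],
                 pop$generation)
}

bind_populations <- function(a, b, generation) {
  new_population(dplyr::bind_rows(a$tbl, b$tbl),
                 rbind(a$size_alleles, b$size_alleles),
                 rbind(a$pref_alleles, b$pref_alleles),
                 generation)
}

# realize individuals from allele matrices
build_individuals <- function(sex, size_alleles, pref_alleles, cfg, pool,
                              birth_gen) {
  size <- apply_env_noise(genotype_value(size_alleles), cfg$loci$env_sd)
  pref_value <- genotype_value(pref_alleles)
  alpha <- rep(NA_real_, length(sex))
  beta <- rep(NA_real_, length(sex))
  f <- sex == "F"
  if (any(f)) {
    ab <- assign_preference(pref_value[f], pool)
    alpha[f] <- ab$alpha
    beta[f] <- ab$beta
  }
  tbl <- tibble::tibble(
    sex = sex, size = size, pref_value = pref_value,
    alpha = alpha, beta = beta,
    mated = FALSE, birth_gen = as.integer(birth_gen)
  )
  new_population(tbl, size_alleles, pref_alleles, birth_gen)
}

#' Initialize the founding population
#'
#' 1000 males and 1000 females (configurable) with genotypes drawn uniformly
#' from the allele set, realized sizes (plus environmental noise when
#' configured), and female preference phenotypes assigned from `pool`.
#' Founders' size genotypes can instead be two fixed-allele subpopulations
#' via `two_subpop_init`.
#'
#' @param cfg A [simulation_config()].
#' @param pool Preference pool; drawn from `cfg$pref` if missing.
#' @return A `spider_pop` at generation 0.
#' @export
init_population <- function(cfg, pool = NULL) {
  if (is.null(pool)) pool <- draw_pref_pool(cfg$pref, cfg$loci$L)
  n <- cfg$n_init_per_sex
  sex <- rep(c("M", "F"), each = n)
  size_alleles <- init_genotypes(2L * n, cfg$loci)
  if (isTRUE(cfg$two_subpop_init)) {
    half <- seq_len(2L * n) %% 2L == 0L
    size_alleles[half, ] <- -1L
    size_alleles[!half, ] <- 1L
  }
  pref_alleles <- init_genotypes(2L * n, cfg$loci)
  build_individuals(sex, size_alleles, pref_alleles, cfg, pool, 0L)
}

#' z-score sizes within the mating pool
#'
#' Adds a `size_z` column to the population's phenotype table, computed per
#' sex as (size - sex mean) / sex SD. The reference statistics default to the
#' current pool; pass `ref` (list with `mean_m`, `sd_m`, `mean_f`, `sd_f`) to
#' standardize against a fixed pool such as the founders.
#'
#' @param pop A `spider_pop`.
#' @param ref Optional fixed reference statistics.
#' @return The population with `size_z` filled in.
#' @export
zscore_sizes <- function(pop, ref = NULL) {
  tbl <- pop$tbl
  m <- tbl$sex == "M"
  if (sum(m) < 2L || sum(!m) < 2L) {
    stop("degenerate population: need at least 2 individuals per sex to z-score")
  }
  if (is.null(ref)) {
    ref <- list(mean_m = mean(tbl$size[m]), sd_m = sd(tbl$size[m]),
                mean_f = mean(tbl$size[!m]), sd_f = sd(tbl$size[!m]))
  }
  if (ref$sd_m == 0 || ref$sd_f == 0) {
    stop("degenerate population: zero size variance in at least one sex")
  }
  z <- numeric(nrow(tbl))
  z[m] <- (tbl$size[m] - ref$mean_m) / ref$sd_m
  z[!m] <- (tbl$size[!m] - ref$mean_f) / ref$sd_f
  pop$tbl$size_z <- z
  pop
}

pool_reference_stats <- function(pop) {
  m <- pop$tbl$sex == "M"
  list(mean_m = mean(pop$tbl$size[m]), sd_m = sd(pop$tbl$size[m]),
       mean_f = mean(pop$tbl$size[!m]), sd_f = sd(pop$tbl$size[!m]))
}

#' Run one mating season
#'
#' Every unmated female is repeatedly paired with a male drawn uniformly at
#' random with replacement from all males in the pool (males may mate many
#' times; a female may re-meet a male who already courted her). She accepts
#' with the logistic probability of [mating_probability()]; on acceptance she
#' is flagged mated and leaves the pool. The season ends when every female
#' has mated or after `max_mating_rounds` rounds; females still unmated then
#' produce no offspring this generation.
#'
#' The `force_alpha` and `assortative_beta` manipulations act here, on the
#' effective (alpha, beta) used for acceptance, leaving stored phenotypes
#' untouched.
#'
#' @param pop A z-scored `spider_pop` (see [zscore_sizes()]).
#' @param cfg A [simulation_config()].
#' @return A tibble of matings with columns `female`, `male` (row indices
#'   into the population), `female_z`, `male_z`, `round`, and attribute
#'   `n_unmated`.
#' @export
mating_season <- function(pop, cfg) {
  tbl <- pop$tbl
  if (is.null(tbl$size_z)) stop("population must be z-scored before mating")
  males <- which(tbl$sex == "M")
  fem <- which(tbl$sex == "F" & !tbl$mated)
  empty <- tibble::tibble(female = integer(0), male = integer(0),
                          female_z = numeric(0), male_z = numeric(0),
                          round = integer(0))
  if (!length(males) || !length(fem)) {
    attr(empty, "n_unmated") <- length(fem)
    return(empty)
  }
  fz <- tbl$size_z[fem]
  mz <- tbl$size_z[males]
  alpha <- tbl$alpha[fem]
  beta <- tbl$beta[fem]
  if (!is.null(cfg$force_alpha)) alpha <- rep(cfg$force_alpha, length(fem))
  if (isTRUE(cfg$assortative_beta)) {
    beta <- cfg$pref$mu_beta + sqrt(cfg$pref$var_beta) * fz
  }
  slope <- cfg$pref$female_size_slope
  res_f <- vector("list", cfg$max_mating_rounds)
  res_m <- vector("list", cfg$max_mating_rounds)
  res_r <- vector("list", cfg$max_mating_rounds)
  active <- seq_along(fem)
  r <- 0L
  while (length(active) && r < cfg$max_mating_rounds) {
    r <- r + 1L
    pick <- sample.int(length(males), length(active), replace = TRUE)
    p <- mating_probability(alpha[active], beta[active], fz[active], mz[pick],
                            female_size_slope = slope)
    acc <- runif(length(active)) < p
    if (any(acc)) {
      res_f[[r]] <- active[acc]
      res_m[[r]] <- pick[acc]
      res_r[[r]] <- rep.int(r, sum(acc))
      active <- active[!acc]
    }
  }
  fi <- unlist(res_f)
  mi <- unlist(res_m)
  if (is.null(fi)) {
    attr(empty, "n_unmated") <- length(fem)
    return(empty)
  }
  out <- tibble::tibble(
    female = fem[fi], male = males[mi],
    female_z = fz[fi], male_z = mz[mi],
    round = unlist(res_r)
  )
  attr(out, "n_unmated") <- length(active)
  out
}

# per-mating egg-laying + brood size + sex split
offspring_counts <- function(matings, fec) {
  n <- nrow(matings)
  y <- integer(n)
  laid <- lays_eggs(n, fec)
  if (any(laid)) y[laid] <- sample_offspring_count(matings$male_z[laid], fec)
  n_m <- y %/% 2L
  odd <- y %% 2L == 1L
  if (any(odd)) n_m[odd] <- n_m[odd] + rbinom(sum(odd), 1L, 0.5)
  tibble::tibble(laid = laid, young = y, n_males = n_m, n_females = y - n_m)
}

# instantiate (a subset of) the offspring implied by `counts`
realize_offspring <- function(matings, counts, pop, cfg, pool, generation,
                              keep_m = NULL, keep_f = NULL) {
  mom_m <- rep.int(matings$female, counts$n_males)
  dad_m <- rep.int(matings$male, counts$n_males)
  mom_f <- rep.int(matings$female, counts$n_females)
  dad_f <- rep.int(matings$male, counts$n_females)
  if (!is.null(keep_m)) {
    mom_m <- mom_m[keep_m]; dad_m <- dad_m[keep_m]
  }
  if (!is.null(keep_f)) {
    mom_f <- mom_f[keep_f]; dad_f <- dad_f[keep_f]
  }
  mothers <- c(mom_m, mom_f)
  fathers <- c(dad_m, dad_f)
  sex <- rep(c("M", "F"), c(length(mom_m), length(mom_f)))
  rate <- cfg$loci$mutation_rate
  size_alleles <- mutate_genotype(
    recombine(pop$size_alleles[mothers, , drop = FALSE],
              pop$size_alleles[fathers, , drop = FALSE]), rate)
  pref_alleles <- mutate_genotype(
    recombine(pop$pref_alleles[mothers, , drop = FALSE],
              pop$pref_alleles[fathers, , drop = FALSE]), rate)
  build_individuals(sex, size_alleles, pref_alleles, cfg, pool, generation)
}

#' Produce the offspring cohort of a mating season
#'
#' For each mating: an egg-laying Bernoulli trial (`p_eggs`), a
#' negative-binomial brood size driven by the sire's size z-score, free
#' recombination plus mutation of both trait genotypes, and a half/half sex
#' split (an odd leftover is assigned a sex by fair coin). Daughters receive
#' preference phenotypes from `pool` at birth.
#'
#' @param matings Output of [mating_season()].
#' @param pop The population the matings refer to.
#' @param cfg A [simulation_config()].
#' @param pool Preference pool for the newborn cohort; redrawn from
#'   `cfg$pref` if missing.
#' @param generation Birth generation recorded on the cohort.
#' @return A `spider_pop` cohort.
#' @export
produce_offspring <- function(matings, pop, cfg, pool = NULL,
                              generation = pop$generation + 1L) {
  if (is.null(pool)) pool <- draw_pref_pool(cfg$pref, cfg$loci$L)
  fec <- resolve_fecundity(cfg)
  counts <- offspring_counts(matings, fec)
  realize_offspring(matings, counts, pop, cfg, pool, generation)
}

resolve_fecundity <- function(cfg) {
  fec <- cfg$fec
  if (is.null(fec$k_pool)) fec$k_pool <- default_k_pool(1000L)
  if (!cfg$fecundity_selection) fec$b <- 0
  fec
}

#' Advance to the next generation
#'
#' Builds the next mating pool from the newborn cohort — plus, under
#' two-generation overlap, the parental cohort (grandparents always drop
#' out) — then culls each sex uniformly at random down to `cap_per_sex`.
#'
#' @param pop Current population (its newest members are the parents).
#' @param cohort Newborn cohort from [produce_offspring()].
#' @param cfg A [simulation_config()].
#' @return The next `spider_pop`; generation counter incremented.
#' @export
advance_generation <- function(pop, cohort, cfg) {
  gen <- pop$generation + 1L
  if (isTRUE(cfg$overlap)) {
    keep <- which(pop$tbl$birth_gen == pop$generation)
    nxt <- bind_populations(cohort, subset_population(pop, keep), gen)
  } else {
    nxt <- cohort
    nxt$generation <- gen
  }
  if (nrow(nxt$tbl) == 0L) {
    stop("population extinct: no individuals left in the mating pool")
  }
  cull_population(nxt, cfg$cap_per_sex)
}

cull_population <- function(pop, cap) {
  keep <- unlist(lapply(c("M", "F"), function(s) {
    idx <- which(pop$tbl$sex == s)
    if (length(idx) > cap) sort(sample(idx, cap)) else idx
  }))
  if (length(keep) == nrow(pop$tbl)) pop else subset_population(pop, sort(keep))
}

# ---- full run ---------------------------------------------------------------

#' Run the full simulation
#'
#' Iterates init -> z-score -> mating season -> offspring -> advance,
#' recording one summary row per generation (see [summarize_population()]),
#' until convergence of the size distribution, the generation cap, or
#' extinction/degeneracy. Deterministic given `cfg$seed`.
#'
#' Culling is applied before newborn genotypes are instantiated (survivors of
#' the uniform cull are chosen among the counted offspring first), which is
#' distributionally identical to realizing the full cohort and then culling
#' but avoids materializing transient cohorts an order of magnitude above the
#' cap.
#'
#' @param cfg A [simulation_config()].
#' @return A `prefsel_sim` object: `history` (tibble of per-generation
#'   records), `final_sizes` (named list of raw pooled size vectors for the
#'   trailing `keep_last` generations), `status` (`"converged"`,
#'   `"max_generations"`, `"extinct"`, or `"degenerate"`), `config`.
#' @export
#' @examples
#' \donttest{
#' cfg <- simulation_config(n_init_per_sex = 100, cap_per_sex = 500,
#'                          max_generations = 10, converge = FALSE, seed = 1)
#' sim <- run_simulation(cfg)
#' glance(sim)
#' }
run_simulation <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fec <- resolve_fecundity(cfg)
  cfg$fec <- fec # freeze the realized k pool into the run record
  bins <- default_bins(cfg$loci$L, cfg$loci$env_sd)
  pool0 <- draw_pref_pool(cfg$pref, cfg$loci$L)
  pop <- init_population(cfg, pool0)
  ref <- if (cfg$zscore_ref == "initial") pool_reference_stats(pop) else NULL

  history <- vector("list", cfg$max_generations + 1L)
  final_sizes <- list()
  status <- "max_generations"
  mean_trace <- numeric(cfg$max_generations + 1L)
  var_trace <- numeric(cfg$max_generations + 1L)

  rec <- summarize_population(pop, bins)
  rec$n_matings <- NA_integer_; rec$n_unmated <- NA_integer_
  rec$cohort_males <- NA_integer_; rec$cohort_females <- NA_integer_
  history[[1L]] <- rec
  mean_trace[1L] <- rec$size_mean
  var_trace[1L] <- rec$size_var
  final_sizes[["0"]] <- pop$tbl$size
  last_gen <- 0L

  for (g in seq_len(cfg$max_generations)) {
    pop <- tryCatch(zscore_sizes(pop, ref), error = function(e) e)
    if (inherits(pop, "error")) {
      status <- "degenerate"
      break
    }
    matings <- mating_season(pop, cfg)
    if (nrow(matings)) pop$tbl$mated[matings$female] <- TRUE # once per lifetime
    counts <- offspring_counts(matings, fec)
    tot_m <- sum(counts$n_males)
    tot_f <- sum(counts$n_females)

    carry_idx <- if (isTRUE(cfg$overlap)) {
      which(pop$tbl$birth_gen == pop$generation)
    } else {
      integer(0)
    }
    carry_m <- carry_idx[pop$tbl$sex[carry_idx] == "M"]
    carry_f <- carry_idx[pop$tbl$sex[carry_idx] == "F"]

    if (tot_m + tot_f + length(carry_idx) == 0L) {
      status <- "extinct"
      break
    }

    # joint uniform cull over newborns + carried-over adults, per sex,
    # resolved before newborn genotypes are instantiated
    cull_sex <- function(n_new, n_carry, cap) {
      tot <- n_new + n_carry
      if (tot <= cap) {
        list(new = NULL, carry = seq_len(n_carry))
      } else {
        ids <- sample.int(tot, cap)
        list(new = sort(ids[ids <= n_new]),
             carry = sort(ids[ids > n_new] - n_new))
      }
    }
    km <- cull_sex(tot_m, length(carry_m), cfg$cap_per_sex)
    kf <- cull_sex(tot_f, length(carry_f), cfg$cap_per_sex)

    pool_g <- if (cfg$fresh_pool) draw_pref_pool(cfg$pref, cfg$loci$L) else pool0
    cohort <- realize_offspring(matings, counts, pop, cfg, pool_g, g,
                                keep_m = km$new, keep_f = kf$new)
    carry_keep <- c(carry_m[km$carry], carry_f[kf$carry])
    pop <- if (length(carry_keep)) {
      bind_populations(cohort, subset_population(pop, sort(carry_keep)), g)
    } else {
      cohort$generation <- g
      cohort
    }
    if (nrow(pop$tbl) == 0L) {
      status <- "extinct"
      break
    }

    rec <- summarize_population(pop, bins)
    rec$n_matings <- nrow(matings)
    rec$n_unmated <- attr(matings, "n_unmated")
    rec$cohort_males <- tot_m
    rec$cohort_females <- tot_f
    history[[g + 1L]] <- rec
    mean_trace[g + 1L] <- rec$size_mean
    var_trace[g + 1L] <- rec$size_var
    last_gen <- g

    final_sizes[[as.character(g)]] <- pop$tbl$size
    if (length(final_sizes) > cfg$keep_last) {
      final_sizes[[1L]] <- NULL
    }

    if (cfg$converge && g >= cfg$converge_window) {
      w <- (g + 2L - cfg$converge_window):(g + 1L)
      mu <- mean_trace[w]
      sl <- coef(lm(mu ~ seq_along(mu)))[2L]
      v <- var_trace[w]
      vrel <- if (v[1L] > 0) abs(v[length(v)] / v[1L] - 1) else 0
      if (abs(sl) < cfg$converge_slope_tol && vrel < cfg$converge_var_tol) {
        status <- "converged"
        break
      }
    }
  }

  structure(
    list(
      history = dplyr::bind_rows(history[!vapply(history, is.null, TRUE)]),
      final_sizes = final_sizes,
      status = status,
      generations = last_gen,
      config = cfg
    ),
    class = "prefsel_sim"
  )
}
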