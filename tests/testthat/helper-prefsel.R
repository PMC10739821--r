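# small-scale config for mechanics tests (not the study conditions)
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_init_per_sex = 80, cap_per_sex = 400,
         max_generations = 8, converge = FALSE),
    list(...)
  )
  do.call(simulation_config, args)
}

# a z-scored population with hand-set phenotypes, for mating-season tests
handmade_pop <- function(n_f, n_m, alpha, beta, female_z = 0, male_z = 0,
                         L = 5L) {
  n <- n_f + n_m
  tbl <- tibble::tibble(
    sex = rep(c("F", "M"), c(n_f, n_m)),
    size = 0, pref_value = 0L,
    alpha = c(rep_len(alpha, n_f), rep(NA_real_, n_m)),
    beta = c(rep_len(beta, n_f), rep(NA_real_, n_m)),
    mated = FALSE, birth_gen = 0L,
    size_z = c(rep_len(female_z, n_f), rep_len(male_z, n_m))
  )
  prefsel:::new_population(tbl, matrix(0L, n, 2L * L), matrix(0L, n, 2L * L))
}

# brute-force empirical excess mass at one level: enumerate every index
# interval (and pair of disjoint intervals) directly
brute_excess_mass <- function(x, lam) {
  x <- sort(x)
  n <- length(x)
  val <- function(i, j) (j - i + 1) / n - lam * (x[j] - x[i])
  e1 <- -Inf
  for (i in 1:n) for (j in i:n) e1 <- max(e1, val(i, j))
  e2 <- e1
  for (i1 in 1:n) for (j1 in i1:n) {
    if (j1 + 1 > n) next
    v1 <- val(i1, j1)
    for (i2 in (j1 + 1):n) for (j2 in i2:n) {
      e2 <- max(e2, v1 + val(i2, j2))
    }
  }
  c(e1 = e1, e2 = e2)
}
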