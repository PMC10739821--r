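#' Write a population snapshot to TSV
#'
#' One row per individual: sex, comma-joined size alleles, comma-joined
#' preference alleles, realized size.
#'
#' @param pop A `spider_pop`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_tsv <- function(pop, path) {
  d <- tibble::tibble(
    sex = pop$tbl$sex,
    size_alleles = apply(pop$size_alleles, 1L, paste, collapse = ","),
    pref_alleles = apply(pop$pref_alleles, 1L, paste, collapse = ","),
    size = pop$tbl$size
  )
  readr::write_tsv(d, path)
  invisible(path)
}

#' Read a population snapshot written by [write_population_tsv()]
#'
#' Preference phenotypes are not stored in snapshots; females read back in
#' have `NA` alpha/beta until reassigned from a pool.
#'
#' @param path Snapshot path.
#' @return A `spider_pop` at generation 0.
#' @export
read_population_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  parse_alleles <- function(s) {
    do.call(rbind, lapply(strsplit(s, ","), as.integer))
  }
  sa <- parse_alleles(d$size_alleles)
  pa <- parse_alleles(d$pref_alleles)
  tbl <- tibble::tibble(
    sex = d$sex, size = d$size,
    pref_value = genotype_value(pa),
    alpha = NA_real_, beta = NA_real_,
    mated = FALSE, birth_gen = 0L
  )
  new_population(tbl, sa, pa, 0L)
}

#' Read a simulation configuration from YAML
#'
#' Scalar fields of the YAML map onto [simulation_config()] arguments;
#' nested `pref:` and `fec:` maps override [preference_model()] and
#' [fecundity_model()] parameters.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  pref <- do.call(preference_model, y$pref %||% list())
  fec <- do.call(fecundity_model, y$fec %||% list())
  y$pref <- NULL
  y$fec <- NULL
  keep <- intersect(names(y), names(formals(simulation_config)))
  do.call(simulation_config, c(y[keep], list(pref = pref, fec = fec)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save run outputs to a directory
#'
#' Writes `summary.csv` (tidied history), `metadata.json` (configuration
#' echo, status, seed), and optionally a final population snapshot.
#'
#' @param sim A `prefsel_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_run <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tidy(sim), file.path(dir, "summary.csv"))
  cfg <- sim$config
  meta <- list(
    package_version = as.character(utils::packageVersion("prefsel")),
    status = sim$status,
    generations = sim$generations,
    seed = cfg$seed,
    L = cfg$loci$L, env_sd = cfg$loci$env_sd,
    mutation_rate = cfg$loci$mutation_rate,
    overlap = cfg$overlap,
    fecundity_selection = cfg$fecundity_selection,
    force_alpha = cfg$force_alpha,
    assortative_beta = cfg$assortative_beta,
    n_init_per_sex = cfg$n_init_per_sex,
    cap_per_sex = cfg$cap_per_sex,
    max_generations = cfg$max_generations,
    max_mating_rounds = cfg$max_mating_rounds
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}
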