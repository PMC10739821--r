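# prefsel

Individual-based simulation of sexual selection with divergent female
preference functions.

## The problem

Variation in female preference — some females preferring small males, others
large — is the classic theoretical route from sexual selection to disruptive
selection and sympatric speciation. `prefsel` asks what happens when a model
of that process is calibrated with parameters actually measured in a jumping
spider mating system, rather than chosen for theoretical convenience. It is
aimed at behavioural ecologists and quantitative geneticists who want to run,
perturb, and classify such simulations, and at anyone who needs the
supporting pieces: a rank-binned preference-pool construction, a
negative-binomial fecundity model, a dip-statistic bimodality test, and a
triple-permutation calibration pipeline.

## The model in brief

Diploid individuals carry two traits, body size and preference, each the sum
of 2L tri-valued alleles (L = 5 or 10), with free recombination and 1%
per-allele mutation. A female accepts a courting male with logistic
probability

    p = logit⁻¹(α_i − 2.9 F + β_i M)

where F and M are female and male size z-scores and each female's (α_i, β_i)
is drawn from a bivariate normal with means (0.95, 0.52), variances
(19.4, 5.7) and covariance 10.4, matched to her preference genotype by rank
binning (50 pool pairs per genotype class). Females mate once; a mated
female lays eggs with probability 0.695; brood size is negative-binomial
with mean μ = e^{3.36 + 0.42M} and a dispersion k sampled from an empirical
pool (mean 3.8). Populations of 1000 + 1000 founders evolve under a per-sex
cap of 10,000, across eight base variants (L, environmental noise,
two-generation overlap) and three manipulations (no fecundity selection;
all α_i = −5; size-dependent β_i, i.e. assortative mating). A classifier
makes the selection-regime call — directional, stabilizing, disruptive, or
none — explicit and testable.

## A worked example

```r
library(prefsel)

cfg <- simulation_config(max_generations = 75, converge = FALSE, seed = 1)
sim <- run_simulation(cfg)
sim
#> <prefsel_sim> 75 generations (max_generations)
#>   L = 5, env_sd = 0.00, overlap = FALSE, fecundity selection = TRUE
#>   mean size: 0.05 -> 9.75; size variance: 6.72 -> 0.41

classify_regime(sim)
#> # A tibble: 1 × 12
#>   regime      trend_slope slope_sd displacement_sd drawdown_sd sign_consistency
#>   <chr>             <dbl>    <dbl>           <dbl>       <dbl>            <dbl>
#> 1 directional      0.0707   0.0273            3.24     0.00732             0.68
```

Mean size climbs from 0.05 to 9.75 (the genotype ceiling is +10) — a net
displacement of 3.2 initial SDs with essentially no counter-movement, so the
base model is under clear directional selection: large males sire more
offspring, and realized matings also tilt toward large males. With
`fecundity_selection = FALSE, force_alpha = -5, assortative_beta = TRUE`
the same call returns `disruptive` with a bimodal final size distribution —
the speciation-prone regime.

The calibration pipeline recovers the fecundity model from per-male records
(here the bundled synthetic stand-in for a 20-male data set):

```r
calibrate_fecundity(read_male_records(
  system.file("extdata", "synthetic_males_20.tsv", package = "prefsel")))
#> Fecundity calibration (triple permutation)
#>   males: 20, ordered triples: 6840
#>   mu = exp(3.484 + 0.231 M)
#>   residual SD: 0.301 (log scale), 9.61 (count scale)
#>   k pool: 5694 values, mean 4.51
```

(The bundled records are synthetic — a 20-male draw from the generating
model — so the point estimates carry the sampling noise a 20-record data set
implies. Note the two residual scales: ~0.3 on the log scale versus ~10 on
the count scale. A residual SD of 13.15 is only plausible on the count
scale, which is why `fecundity_model()` defaults to a response-scale error
term.)

`tidy()`, `glance()` and `autoplot()` methods are provided for simulation
and calibration objects; a thin command-line wrapper lives at
`inst/cli/prefsel.R` (`run`, `classify`, `calibrate` subcommands).

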