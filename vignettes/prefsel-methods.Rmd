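---
title: "Methods: an empirically calibrated simulator of sexual selection by divergent female preference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an empirically calibrated simulator of sexual selection by divergent female preference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prefsel)
```

## The question and the model

Divergent female preferences — some females preferring small males, others
large — are the textbook precondition for disruptive sexual selection and,
ultimately, sympatric speciation. `prefsel` is a forward-in-time,
individual-based quantitative-genetics simulator built to ask whether the
preference variation actually measured in a jumping spider mating system is
enough to make selection disruptive, or whether other parts of the biology
(fecundity selection, once-only female mating) push it elsewhere.

Each individual is diploid. Two traits — body size and mating preference —
are each controlled by $L$ loci (5 by default, 10 as a variant) with alleles
drawn from $\{-1, 0, +1\}$. A trait's genetic value is the plain sum of its
$2L$ alleles (no dominance, no epistasis), so values span $[-2L, 2L]$.
Reproduction is free recombination (each offspring locus receives one allele
of each parent, independently across loci) followed by per-allele mutation at
rate 0.01, where mutation resamples uniformly from the allele set — one third
of mutation events are therefore silent, which is intentional: it keeps the
effective rate interpretable while preventing allele loss by drift.

A female's preference is a logistic acceptance function of the courting
male's z-scored size $M$:

$$p(\text{copulation}) = \frac{e^{\alpha_i - 2.9F + \beta_i M}}
{1 + e^{\alpha_i - 2.9F + \beta_i M}},$$

where $F$ is the female's own z-scored size with a fixed slope of $-2.9$, and
$(\alpha_i, \beta_i)$ are female-specific: drawn from a bivariate normal with
means $(0.95, 0.52)$, variances $(19.4, 5.7)$ and covariance $10.4$ (a
correlation of about $0.99$). These moments, the fixed $-2.9$, the egg-laying
probability $0.695$, and the fecundity coefficients below are the empirical
calibration of the simulator; they are defaults everywhere
(`preference_model()`, `fecundity_model()`), not tuning knobs.

Phenotypes are tied to genotypes by rank binning: each cohort draws
$(4L+1) \times 50$ pairs from the bivariate normal (1050 for $L=5$), sorts
them, and gives a female with preference genotype $v$ a random pair from the
$(v + 2L)$-th block of 50 consecutive ranks. Mated females never remate.
After mating, a female lays eggs with probability 0.695; the brood size is
negative-binomial,

$$f(y; k, \mu) = \frac{\Gamma(y+k)}{\Gamma(k)\,\Gamma(y+1)}
\left(\frac{k}{\mu+k}\right)^{k}\left(1 - \frac{k}{\mu+k}\right)^{y},
\qquad \mu = e^{3.36 + 0.42M},$$

with the dispersion $k$ drawn per mating from an empirical pool (mean 3.8);
$k$ does not depend on male size. Generations iterate — initialize 1000
individuals per sex, z-score sizes, run the mating season, produce offspring,
cull each sex to 10,000 — across eight base variants ($L \in \{5, 10\}$ ×
environmental noise on size on/off × two-generation overlap on/off) and three
manipulations: removing fecundity selection ($b = 0$), forcing every
$\alpha_i$ to $-5$ (making average males almost never acceptable), and tying
$\beta_i$ to the female's own size (assortative mating).

## Decisions where the design was open

**Scale of the fecundity residual.** The mean model's residual is printed
with SD 13.15. Inside the exponent that would multiply broods of mean
$e^{3.36} \approx 29$ by factors up to $e^{\pm 40}$, which is biologically
and numerically implausible; we treat 13.15 as an additive count-scale
residual by default (`error_mode = "response_scale"`, mean floored at 0.1)
and retain the literal exponent form as an option. The calibration module
reports residual SD on both scales so an empirical data set can arbitrate.

**Pool ordering.** "The 50 lowest values of α and β" does not define a joint
order. We rank by $\beta$, the slope that encodes the small-male/large-male
direction the genotype represents; with a correlation of 0.99 ranking by
$\alpha$ or by the first principal component is nearly equivalent
(`pool_sort` switches it).

**z-scoring reference.** Acceptance and fecundity were estimated on z-scored
sizes. Sizes are re-standardized within each generation's mating pool per sex
(`zscore_ref = "per_generation"`): only relative size within the current pool
is meaningful as the mean evolves, and this is what permits a sustained
directional response. Standardizing against the founding cohort is available
(`"initial"`); in our experiments the regime outcomes are the same.

**Finite mating season.** A female who rejects is re-paired with a uniformly
random male, indefinitely in principle. We cap the season at
`max_mating_rounds = 200` rounds: it guards non-termination when all
acceptance probabilities are tiny (the $\alpha_i = -5$ manipulation) and
mimics a finite season; unmated females at the cap are childless that
generation. Regime outcomes were insensitive to caps between 20 and 5000.

**Odd broods.** Half of each brood is male; an odd leftover is assigned a
sex by fair coin.

**Triples.** "Groups of three, with replacement" conflicts with the printed
group total, which equals $20 \times 19 \times 18 = 6840$ — ordered triples
of *distinct* males. The count is authoritative; `enumerate_triples()`
enumerates distinct-member ordered triples.

**Culling order.** Offspring counts are drawn for every mating, and the
uniform cull to 10,000 per sex is resolved *before* newborn genotypes are
instantiated. Because offspring are i.i.d. given their parents and the cull
is uniform, this is distributionally identical to realizing the full
(~200,000-individual) transient cohort and then culling, at a tenth of the
memory and time. The exported `produce_offspring()` and
`advance_generation()` still realize and cull full cohorts.

**Manipulations act on effective phenotypes.** `force_alpha` and
`assortative_beta` ($\beta_i = \mu_\beta + \sqrt{\sigma^2_\beta} F_i$, which
preserves the marginal mean and SD of $\beta$) are applied at mating time,
using the same standardization pool as the acceptance model, leaving stored
phenotypes untouched for reporting.

## Regime classification

The original judgement — directional, stabilizing, or disruptive, "by
looking at the histograms" — is made explicit in `classify_regime()`. All
quantities are in units of the initial trait SD, so calls are invariant to
affine rescaling:

* **disruptive** if the raw sizes pooled over the trailing five generations
  are bimodal: dip-statistic Monte-Carlo p < 0.01 *and* bimodality
  coefficient > 5/9. Disruptive takes precedence — a splitting population can
  also drift in mean, and speciation is the rarest, most consequential call.
* **directional** if the mean moves ≥ 1 initial SD net, never retracing more
  than 0.5 initial SDs (on a 5-generation block-averaged trajectory), with
  |least-squares slope| ≥ 0.02 initial SD/generation.
* **stabilizing** if the final/initial variance ratio < 0.5 with net
  displacement < 0.5 initial SDs.
* **none** otherwise — deliberately including preference means that drift to
  higher and lower values without a consistent direction.

We report per-step sign consistency but do not gate the directional call on
it: with strictly additive loci the response saturates as the mean approaches
the genotype boundary $\pm 2L$ (initial response here is roughly 0.1–0.2 SD
per generation, so saturation arrives well before generation 75), after which
inter-generation steps are mean-zero noise and full-run sign consistency
decays toward 1/2 for trajectories that are unambiguously directional by eye.
Net displacement with a bounded drawdown is robust to saturation while still
rejecting back-and-forth drift. All thresholds live in
`regime_thresholds()`.

**Dip statistic.** No dip implementation is available in this stack, so the
package computes it from first principles via the excess-mass
characterization: the dip equals half the largest difference, over density
levels, between the best two-interval and best one-interval empirical excess
mass. The level scan is a log-grid with iterative refinement plus the
zero-length-interval limit, each level evaluated by an $O(n)$ prefix-scan.
Two exact anchors pin the implementation: $n$ equally spaced points give the
theoretical minimum $1/(2n)$, and two equal point clusters give the maximum
$1/4$; the scan is also tested against brute-force interval enumeration. The
p-value is Monte-Carlo against a uniform null of the same sample size (200
replicates, cached per size); samples above 1000 values are subsampled.

**Lattice dither.** Without environmental noise, realized size is an integer
(the genotype's resolution). Near fixation the distribution concentrates on
two or three *adjacent* lattice points, which a continuity-assuming dip test
misreads as multimodal. `detect_bimodality()` therefore adds uniform dither
of half the smallest distinct-value spacing — the exact de-discretization of
the lattice. It cannot merge genuinely separated modes and is negligible for
continuous data.

## The synthetic-data generator

`synthetic_males()` stands in for the 20-male single-mating data set used to
calibrate fecundity: z-scored standard-normal sizes and negative-binomial
counts with $\mu = e^{3.36 + 0.42\,size}$ and $k = 3.8$. It reproduces the
statistical structure the calibration assumes (exponential mean–size
relationship, overdispersion near $k = 3.8$) but not features of real
records such as measurement error in size, within-male variation across
matings, or any size–dispersion dependence — passing recovery tests
therefore validates the pipeline's estimators, not the biology of any real
data set. The dispersion pool stand-in (`default_k_pool()`) is gamma with
mean 3.8 and shape 4: strictly positive, moderately spread; an empirically
derived pool can be supplied as a plain-text file. With only 20 males the
moment estimators are noisy by construction; recovery is asserted on medians
across replicate data sets (median slope within 0.2, median pool mean within
20%), not on single draws.

## Problem sizes and numerical notes

Regime properties are checked on 75-generation runs at the full study census
(1000 founders, cap 10,000 per sex), five seeds per scenario; the
acceptance script runs one seed per scenario. Moment checks use $10^5$–$10^6$
draws. The logistic acceptance is computed with `plogis` and clamped into
the open unit interval so extreme predictors saturate without returning
exactly 0 or 1; the negative-binomial pmf is evaluated through log-gamma;
z-scoring halts with a diagnostic if a sex's size variance hits zero;
convergence (optional) is declared when the windowed mean-size slope falls
below 0.01/generation with variance change below 5%.

## Known limitations and an honest discrepancy

With fecundity selection removed, this implementation does not produce
stabilizing selection: it remains directional (mean size up ~3 initial SDs
over 75 generations, across both z-scoring conventions and season caps from
20 to 5000 rounds). The mechanism is verifiable against a closed-form oracle
of the conditional sire distribution ($\propto p(M)$ for a female who keeps
sampling males): (i) rank-binning through the binomially concentrated
genotype classes means the extreme low-$\alpha$/low-$\beta$ tail of the
preference distribution — the hyper-picky, small-male-preferring females
whose matings would balance the tilt — is essentially never sampled (the
extreme class has probability $3^{-2L}$); (ii) the $-2.9F$ term makes large
females choosier, and their slopes (mean $\beta > 0$) tilt realized matings
toward large males. The net sire differential is about $+0.1$ SD per
generation even without fecundity selection. A stabilizing outcome for this
manipulation would require preference-assignment or mating-season mechanics
beyond those specified here.

Out of scope by design: linkage, dominance, epistasis, sex chromosomes,
spatial structure, migration, male mate choice, sperm competition, female
remating, and formal speciation metrics (e.g. assortment indices or $F_{ST}$
between modes) beyond bimodality of the trait distribution.

## A worked example

```{r example, eval = FALSE}
library(prefsel)

cfg <- simulation_config(max_generations = 75, converge = FALSE, seed = 1)
sim <- run_simulation(cfg)
glance(sim)
classify_regime(sim)
autoplot(sim)

# the speciation scenario
cfg_d <- simulation_config(max_generations = 75, converge = FALSE, seed = 1,
                           fecundity_selection = FALSE, force_alpha = -5,
                           assortative_beta = TRUE)
classify_regime(run_simulation(cfg_d))

# calibration from (synthetic) per-male records
calibrate_fecundity(synthetic_males(20))
```
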