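---
title: "Modelling insecticide-resistance evolution under bed nets and larvicides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling insecticide-resistance evolution under bed nets and larvicides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resistevol)
```

## The model

`resistevol` couples a mechanistic description of the mosquito feeding
cycle to a standard one-locus, two-allele, two-sex selection recursion.
Resistance is controlled by a single gene with alleles R (resistant) and
S (sensitive); the three genotypes SS, RS and RR differ in how well they
survive insecticide exposure, and the heterozygote expresses a fraction
`h` of the homozygote's resistance `rho` and of its fitness cost `Z`.
Generations are discrete and non-overlapping; mating is random, so
zygote genotypes are cross products of the male and female gamete pools.
There is no mutation, migration, density dependence or age structure:
the model isolates the selective effect of the two interventions.

Two selection pressures act:

* **Larvicide** (coverage `psi`) kills larvae of *both* sexes in treated
  sites. Survival is standardized to 1 in untreated sites, so genotype
  survival is `1 - psi`, `1 - psi(1 - h rho)`, `1 - psi(1 - rho)`.
  `psi` doubles as a proxy for agricultural insecticide run-off into
  breeding sites.
* **Insecticide-treated nets** (coverage `phi`) act only on adult
  females attempting to feed on humans indoors. Males never contact
  nets; their fitness is larval survival times the fertility cost.

A female's feeding attempt targets a human indoors with probability `Q`
(otherwise an animal); a protected house is met with probability `phi`,
where the mosquito is repelled (and restarts host search, at extra death
risk `mu_r`) with probability `r`, or feeds and survives the insecticide
with genotype-specific probability `s_g`. Each bite carries a
feeding-associated death risk survived with probability `sigma`. Summing
the repelled-and-retry geometric series gives the per-cycle feeding
success `sigma (1 - Q phi (1 - (1 - r) s_g)) / (1 - Q phi r (1 - mu_r))`;
multiplied by the feeding-independent survival `1 - mu_gt` it gives the
per-cycle survival, whose geometric mean lifetime `1/(1 - survival)` is
the expected number of egg batches. Female fitness is larval survival ×
fecundity `kappa` × cost factor × lifespan; `kappa` cancels in the
frequency recursion but is kept so the table holds absolute lifetime
reproductive success.

The recursion advances the resistance-allele frequency in each sex's
gamete pool,

```
p_x(t+1) = (W_x,RR p_m p_f + 0.5 W_x,RS (p_m q_f + p_f q_m)) / Wbar_x ,
```

and `simulate_trajectory()` iterates it, recording frequencies and mean
fitnesses per generation.

## Parameters

| name | meaning | default | units |
|------|---------|---------|-------|
| `phi` | ITN coverage | 0 | probability |
| `psi` | larvicide coverage | 0 | probability |
| `Q` | indoor human-feeding propensity | 0.7 | probability |
| `r` | repellency of the treated net | 0.7 | probability |
| `s` | sensitive survival of net contact | 0.16 | probability |
| `sigma` | survival of feeding-associated risk | 0.9 | probability |
| `mu` | daily adult mortality | 0.1 | / day |
| `gt` | gonotrophic cycle length | 3 | days |
| `mu_r` | extra mortality per repeat search | 0.03 | probability |
| `h` | dominance of resistance | 0.25 | — |
| `rho` | resistance level | 0.95 | — |
| `Z` | fecundity/fertility cost | 0.1 | — |
| `kappa` | female fecundity | 100 | offspring |

The defaults are typical field values for *Anopheles* and pyrethroid
nets; `phi` and `psi` default to 0 because they are the quantities every
analysis varies. The per-cycle mortality is derived exactly as
`mu_gt = 1 - (1 - mu)^gt = 0.271`; the conventional rounded 0.27 is
reachable through the `mu_gt` override, and reference values quoted in
the test suite that were computed at 0.27 use that override explicitly.
Parameters are validated strictly on construction — probabilities outside
[0, 1], a non-positive cycle length or fecundity, or a repeat-search
series ratio `Q phi r (1 - mu_r) >= 1` are errors, never clamped, so a
mistyped configuration fails loudly rather than silently shifting a
threshold.

## Invasion analysis and thresholds

Linearizing the recursion around a monomorphic resident gives the
per-generation growth factor of a rare allele,
`lambda = 0.5 (W_m,RS / W_m,res + W_f,RS / W_f,res)`
(`invasion_growth_factor()`); the package verifies it against a
one-generation simulation from frequency 1e-8 to 1e-6 relative accuracy.
`find_coverage_threshold()` defines coverage thresholds through these
factors — *invasion*: `lambda_R > 1`; *fixation*: `lambda_R > 1` and
`lambda_S < 1` — because they are analytic, fast and deterministic, and
cross-checks against full simulation are part of the test suite. The
boundary is bracketed by a 101-point grid scan on [0, 1] and refined by
bisection to 1e-4; if the criterion flips more than once on the grid the
smallest crossing is reported with a warning. Reported percentages are
rounded half-up to the nearest integer percent, matching the coarse
granularity at which coverage targets are discussed in practice.

A noteworthy structural feature: under larvicide-only selection at
default parameters the two criteria do not coincide. The resistance
allele invades for `psi > 0.0974`, but the sensitive allele still
invades a resistant population until `psi = 0.1074` (the root of
`0.975 (1 - 0.7625 psi) = 0.9 (1 - 0.05 psi)`), because the heterozygote
pays only a quarter of the cost while enjoying most of the larval
protection. Between the two roots both alleles increase when rare — a
protected polymorphism — and `classify_outcome()` reports
`"not-converged"` there honestly instead of forcing a binary label.
Outside that narrow band every parameter set tested leads to fixation or
elimination.

## Tolerances and numerical choices

* Fixation is declared when the sex-averaged frequency exceeds
  `1 - 1e-6`, elimination when it falls below `1e-9` — two orders of
  magnitude under the conventional 1e-5 starting frequency, so a
  declining allele is never misread as eliminated while still near its
  start. The default horizon is 50 000 generations.
* "Time to 50%" (`time_to_frequency()`) is evaluated on the sex-averaged
  frequency `(p_m + p_f)/2`, the quantity the neutral recursion
  preserves exactly; `Inf` encodes "never".
* The geometric series for feeding success is evaluated in closed form;
  the tests confirm agreement with the truncated partial sum (200 terms)
  to 1e-10 across the parameter ranges.
* Degenerate corners fail loudly: an all-zero-fitness population (e.g.
  `psi = 1` with `rho < 1` and the allele absent) raises a classed
  population-extinct error rather than producing NaN.
* `evolution_time_ratio()` returns `Inf` when the ITN-only arm never
  reaches the target, and raises a classed undefined-ratio error when
  the larvicide-only arm does not either; CSV serialization writes the
  literal markers `never`, `inf` and `undefined`, never sentinel
  numbers.

## The stochastic counterpart

`stochastic_generation()` embeds the recursion in a finite population:
the deterministic selection step is applied to the allele frequencies
implied by the current genotype counts, and the next generation's counts
are drawn by one multinomial sample per sex from the random-mating cross
products of the post-selection gamete frequencies, at constant census
sizes `N_m`, `N_f` (soft selection — the deterministic model tracks only
frequencies, so constant N is the minimal consistent embedding). Both
sexes use the same transmission probabilities, matching the recursion's
symmetric inheritance. Runs are reproducible bit-for-bit under a fixed
seed.

This sampling model is a *verification oracle*, not a field simulator:
it adds genuine multinomial drift (deviations from the deterministic
path shrink as `1/sqrt(N)`, and a neutral allele performs an unbiased
random walk), but it inherits every idealization of the deterministic
model — constant population size, no mutation or migration, no
spatial or temporal heterogeneity in coverage, no age structure. Tests
passing against it show the recursion and its sampling analogue are
mutually consistent; they do not show that either captures the
demography of a real vector population.

## Problem sizes used in the tests

The test suite runs the model at the scales the analyses actually need:
single trajectories of a few hundred to a few thousand generations,
101-point coverage grids with 1e-4 bisection, 100-point random parameter
samples for the linearization checks, and stochastic runs of 50
generations at census sizes up to 1e6 (drawing a multinomial at N = 1e6
is cheap; it is the number of generations, not N, that costs time). The
full suite completes in well under a minute.

## Limitations

Behavioural resistance (evolving repellency-avoidance or outdoor
feeding) is outside the model's scope, as are epidemiological outcomes
(transmission, prevalence), genetic linkage between behaviour and
resistance, and any density dependence in the larval sites. The
fitness cost is implemented through fecundity/fertility only; a
longevity cost would interact with the lifespan expression and is not
modelled. Coverage parameters are homogeneous — every house and larval
site shares one probability — so patchy deployment, which is known to
change resistance dynamics, cannot be represented.
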