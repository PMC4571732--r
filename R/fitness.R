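#' Probability of surviving insecticide exposure on a net, by genotype
#'
#' Sensitive homozygotes survive net contact with probability `s`.
#' Resistance reduces the kill probability `1 - s` by the factor
#' `1 - rho` in `RR` homozygotes and by `1 - h * rho` in heterozygotes,
#' giving survival `s + rho * (1 - s)` and `s + h * rho * (1 - s)`.
#'
#' @param genotype One of `"SS"`, `"RS"`, `"RR"`.
#' @param params A [resist_params()] object.
#' @return A survival probability.
#' @examples
#' insecticide_survival("RR", resist_params())  # 0.958
#' @export
insecticide_survival <- function(genotype, params) {
  genotype <- match.arg(genotype, genotypes())
  stopifnot(inherits(params, "resist_params"))
  switch(genotype,
         SS = params$s,
         RS = params$s + params$h * params$rho * (1 - params$s),
         RR = params$s + params$rho * (1 - params$s))
}

#' Larval survival under larvicide exposure, by genotype
#'
#' Survival is standardized so all larvae in untreated sites survive.
#' A proportion `psi` of sites is treated; sensitive larvae there are
#' killed, while resistance rescues a fraction `rho` (`h * rho` in
#' heterozygotes): survival is `1 - psi`, `1 - psi * (1 - h * rho)` and
#' `1 - psi * (1 - rho)` for `SS`, `RS`, `RR`.
#'
#' @inheritParams insecticide_survival
#' @return A survival probability.
#' @export
larval_survival <- function(genotype, params) {
  genotype <- match.arg(genotype, genotypes())
  stopifnot(inherits(params, "resist_params"))
  switch(genotype,
         SS = 1 - params$psi,
         RS = 1 - params$psi * (1 - params$h * params$rho),
         RR = 1 - params$psi * (1 - params$rho))
}

#' Probability of feeding successfully and surviving one attempt
#'
#' A mosquito feeds on an animal with probability `1 - Q` or attempts a
#' human indoors with probability `Q`; a fraction `phi` of houses is
#' protected, where it is repelled with probability `r` or, if not
#' repelled, survives the insecticide with probability `surv`. Every bite
#' carries feeding-associated death survived with probability `sigma`.
#' The success probability of a single attempt is
#' `sigma * (1 - Q * phi * (1 - (1 - r) * surv))`.
#'
#' @param params A [resist_params()] object.
#' @param surv Insecticide survival of the genotype considered, from
#'   [insecticide_survival()].
#' @return A probability.
#' @export
single_attempt_success <- function(params, surv) {
  stopifnot(inherits(params, "resist_params"),
            is.numeric(surv), surv >= 0, surv <= 1)
  params$sigma *
    (1 - params$Q * params$phi * (1 - (1 - params$r) * surv))
}

#' Probability of ever feeding successfully in one gonotrophic cycle
#'
#' A repelled mosquito restarts its host search, incurring an extra death
#' risk `mu_r` per repeat, so lifetime success is the geometric series of
#' single attempts with ratio `Q * phi * r * (1 - mu_r)`, summing to
#' `single_attempt_success / (1 - Q * phi * r * (1 - mu_r))`.
#'
#' @inheritParams single_attempt_success
#' @return A probability.
#' @export
lifetime_feeding_success <- function(params, surv) {
  ratio <- params$Q * params$phi * params$r * (1 - params$mu_r)
  if (ratio >= 1)
    resist_error(paste0("repeat-search ratio ", ratio,
                        " >= 1: feeding-success series diverges"),
                 "resistevol_convergence_error")
  single_attempt_success(params, surv) / (1 - ratio)
}

#' Probability of surviving a whole gonotrophic cycle
#'
#' Combines feeding-related risk ([lifetime_feeding_success()]) with the
#' feeding-independent per-cycle mortality ([effective_mu_gt()]).
#'
#' @inheritParams single_attempt_success
#' @return A probability.
#' @export
gonotrophic_cycle_survival <- function(params, surv) {
  (1 - effective_mu_gt(params)) * lifetime_feeding_success(params, surv)
}

#' Expected adult female lifespan in gonotrophic cycles
#'
#' With per-cycle survival `P`, the number of completed cycles is
#' geometric with mean `1 / (1 - P)`. Resistance enters through the
#' genotype's survival of net contact, so lifespans are genotype-specific
#' whenever nets are present (`phi > 0`) and not fully repellent.
#'
#' @inheritParams insecticide_survival
#' @return Expected number of gonotrophic cycles (>= 1).
#' @examples
#' expected_lifespan("SS", resist_params(phi = 0.7, mu_gt = 0.27))
#' @export
expected_lifespan <- function(genotype, params) {
  surv <- insecticide_survival(genotype, params)
  p_cycle <- gonotrophic_cycle_survival(params, surv)
  if (p_cycle >= 1)
    resist_error(paste0("per-cycle survival ", p_cycle,
                        " >= 1: expected lifespan diverges (degenerate ",
                        "parameters)"),
                 "resistevol_degenerate_error")
  1 / (1 - p_cycle)
}

# fecundity/fertility cost factor shared by the sexes
cost_factor <- function(genotype, params) {
  switch(genotype,
         SS = 1,
         RS = 1 - params$h * params$Z,
         RR = 1 - params$Z)
}

#' Absolute male fitness by genotype
#'
#' Males never contact nets, so their fitness is larval survival times the
#' fertility cost of resistance: `1 - psi` for `SS`,
#' `(1 - psi * (1 - h * rho)) * (1 - h * Z)` for `RS`,
#' `(1 - psi * (1 - rho)) * (1 - Z)` for `RR`.
#'
#' @inheritParams insecticide_survival
#' @return A non-negative fitness value.
#' @export
male_fitness <- function(genotype, params) {
  genotype <- match.arg(genotype, genotypes())
  larval_survival(genotype, params) * cost_factor(genotype, params)
}

#' Absolute female fitness by genotype
#'
#' Lifetime reproductive success: larval survival times fecundity `kappa`,
#' the fecundity cost of resistance, and the expected adult lifespan in
#' gonotrophic cycles (one egg batch per completed cycle).
#'
#' @inheritParams insecticide_survival
#' @return A non-negative fitness value (offspring units).
#' @export
female_fitness <- function(genotype, params) {
  genotype <- match.arg(genotype, genotypes())
  larval_survival(genotype, params) * params$kappa *
    cost_factor(genotype, params) * expected_lifespan(genotype, params)
}

#' Fitness table for both sexes and all genotypes
#'
#' Evaluates [male_fitness()] and [female_fitness()] for `SS`, `RS` and
#' `RR`, returning a 2 x 3 matrix with rows `male`, `female` and columns
#' `SS`, `RS`, `RR`. With `rho = 0` and `Z = 0` all entries within a sex
#' are equal (the allele is then neutral).
#'
#' @param params A [resist_params()] object.
#' @return A `fitness_table`: a numeric matrix with the parameters
#'   attached as attribute `params`.
#' @examples
#' build_fitness_table(resist_params(phi = 0.7))
#' @export
build_fitness_table <- function(params) {
  stopifnot(inherits(params, "resist_params"))
  W <- matrix(NA_real_, 2L, 3L, dimnames = list(sexes(), genotypes()))
  for (g in genotypes()) {
    W["male", g] <- male_fitness(g, params)
    W["female", g] <- female_fitness(g, params)
  }
  stopifnot(all(W >= 0))
  structure(W, class = c("fitness_table", "matrix"), params = params)
}

#' @export
print.fitness_table <- function(x, ...) {
  cat("Absolute fitnesses (rows: sex, columns: genotype)\n")
  print(matrix(unclass(x), 2L, 3L, dimnames = dimnames(x)), ...)
  invisible(x)
}
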