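#' Model parameters for the resistance-evolution model
#'
#' Bundles every parameter of the feeding-cycle and selection model into a
#' validated object. Defaults are the typical field values used throughout
#' the package: anthropophily `Q = 0.7`, repellency `r = 0.7`, insecticide
#' survival of sensitives `s = 0.16`, feeding survival `sigma = 0.9`, daily
#' adult mortality `mu = 0.1` over a `gt = 3`-day gonotrophic cycle,
#' repeat-search mortality `mu_r = 0.03`, dominance `h = 0.25`, resistance
#' level `rho = 0.95`, fecundity cost `Z = 0.1` and fecundity `kappa = 100`.
#' The intervention coverages `phi` (ITNs) and `psi` (larvicide) default to
#' zero; they are the quantities experiments vary.
#'
#' @param phi ITN coverage: probability that a human-feeding attempt targets
#'   a protected house.
#' @param psi Larvicide coverage: proportion of larval sites treated (also a
#'   proxy for agricultural insecticide run-off).
#' @param Q Probability that a feeding attempt targets a human indoors
#'   rather than an animal.
#' @param r Repellency: probability that a mosquito contacting a treated net
#'   is deterred and restarts host search.
#' @param s Probability that a fully sensitive mosquito survives insecticide
#'   exposure on a net.
#' @param sigma Probability of surviving feeding-associated death, per bite.
#' @param mu Daily adult mortality probability.
#' @param gt Length of the gonotrophic cycle in days (> 0).
#' @param mu_gt Optional override for the per-cycle feeding-independent
#'   mortality. When `NULL` (default) it is derived exactly as
#'   `1 - (1 - mu)^gt`; supply `0.27` to reproduce the conventional rounded
#'   value.
#' @param mu_r Additional mortality risk incurred each time the mosquito is
#'   repelled and searches for a new host.
#' @param h Dominance of the resistance allele in \[0, 1\]: the fraction of
#'   the homozygote's resistance (and of its cost) expressed in
#'   heterozygotes.
#' @param rho Resistance level in \[0, 1\]: proportional reduction of
#'   insecticide-induced mortality in `RR` homozygotes.
#' @param Z Fecundity/fertility cost of resistance in \[0, 1\], paid by both
#'   sexes.
#' @param kappa Female fecundity (offspring per female, > 0). Cancels in
#'   the frequency recursion but is kept in the female fitness values.
#'
#' @details
#' Construction fails (rather than clamping) when any probability is
#' outside \[0, 1\], when the derived or overridden per-cycle mortality
#' leaves \[0, 1\], or when the repeat-search geometric-series ratio
#' `Q * phi * r * (1 - mu_r)` is not strictly below 1, which would break
#' convergence of the lifetime feeding-success series.
#'
#' @return An object of class `resist_params`: a named list of the fourteen
#'   parameters, with `mu_gt` kept as `NULL` when not overridden.
#' @seealso [effective_mu_gt()], [build_fitness_table()], [read_params()]
#' @examples
#' p <- resist_params(phi = 0.7)
#' effective_mu_gt(p)
#' @export
resist_params <- function(phi = 0, psi = 0, Q = 0.7, r = 0.7, s = 0.16,
                          sigma = 0.9, mu = 0.1, gt = 3, mu_gt = NULL,
                          mu_r = 0.03, h = 0.25, rho = 0.95, Z = 0.1,
                          kappa = 100) {
  p <- list(phi = phi, psi = psi, Q = Q, r = r, s = s, sigma = sigma,
            mu = mu, gt = gt, mu_gt = mu_gt, mu_r = mu_r, h = h,
            rho = rho, Z = Z, kappa = kappa)
  validate_resist_params(p)
  structure(p, class = "resist_params")
}

# names of parameters that must be probabilities
.prob_fields <- c("phi", "psi", "Q", "r", "s", "sigma", "mu", "mu_r",
                  "h", "rho", "Z")

validate_resist_params <- function(p) {
  for (nm in names(p)) {
    v <- p[[nm]]
    if (nm == "mu_gt" && is.null(v)) next
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  for (nm in .prob_fields) {
    v <- p[[nm]]
    if (v < 0 || v > 1)
      stop("parameter '", nm, "' = ", v, " is not a probability in [0, 1]",
           call. = FALSE)
  }
  if (p$gt <= 0) stop("gonotrophic cycle length 'gt' must be positive",
                      call. = FALSE)
  if (p$kappa <= 0) stop("fecundity 'kappa' must be positive", call. = FALSE)
  mgt <- if (is.null(p$mu_gt)) 1 - (1 - p$mu)^p$gt else p$mu_gt
  if (mgt < 0 || mgt > 1)
    stop("effective per-cycle mortality mu_gt = ", mgt,
         " is not a probability in [0, 1]", call. = FALSE)
  ratio <- p$Q * p$phi * p$r * (1 - p$mu_r)
  if (ratio >= 1)
    stop("repeat-search ratio Q*phi*r*(1-mu_r) = ", ratio,
         " must be strictly below 1 for the feeding-success series ",
         "to converge", call. = FALSE)
  invisible(p)
}

#' Replace fields of a parameter set, re-validating the result
#'
#' @param params A [resist_params()] object.
#' @param ... Named parameter replacements, e.g. `phi = 0.5`.
#' @return A new `resist_params` object.
#' @examples
#' update_params(resist_params(), phi = 0.8, psi = 0.1)
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "resist_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(unclass(params)))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(resist_params, utils::modifyList(unclass(params), repl,
                                           keep.null = TRUE))
}

#' Per-cycle feeding-independent mortality
#'
#' The probability of dying of causes unrelated to feeding during one
#' gonotrophic cycle. Derived from the daily mortality as
#' `1 - (1 - mu)^gt` unless an explicit override was stored in the
#' parameter set (e.g. the conventional rounded 0.27 for `mu = 0.1`,
#' `gt = 3`, whose exact value is 0.271).
#'
#' @param params A [resist_params()] object.
#' @return A probability.
#' @examples
#' effective_mu_gt(resist_params())            # 0.271
#' effective_mu_gt(resist_params(mu_gt = 0.27)) # the override
#' @export
effective_mu_gt <- function(params) {
  stopifnot(inherits(params, "resist_params"))
  if (!is.null(params$mu_gt)) params$mu_gt else 1 - (1 - params$mu)^params$gt
}

#' Read a parameter set from a flat JSON or YAML config file
#'
#' The file holds a flat key/value mapping with keys among `phi`, `psi`,
#' `Q`, `r`, `s`, `sigma`, `mu`, `gt`, `mu_gt`, `mu_r`, `h`, `rho`, `Z`,
#' `kappa`. Absent keys fall back to the defaults of [resist_params()];
#' unknown keys are an error. Format is chosen by extension (`.json`
#' versus `.yaml`/`.yml`).
#'
#' @param path Path to the config file.
#' @return A `resist_params` object.
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported config extension '.", ext,
         "' (use .json, .yaml or .yml)", call. = FALSE))
  if (!is.list(vals)) vals <- as.list(vals)
  allowed <- names(formals(resist_params))
  bad <- setdiff(names(vals), allowed)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(resist_params, vals)
}

#' @export
print.resist_params <- function(x, ...) {
  mgt <- effective_mu_gt(x)
  cat("Resistance-evolution model parameters\n")
  cat(sprintf("  interventions : phi = %g (ITN), psi = %g (larvicide)\n",
              x$phi, x$psi))
  cat(sprintf("  feeding cycle : Q = %g, r = %g, s = %g, sigma = %g, mu_r = %g\n",
              x$Q, x$r, x$s, x$sigma, x$mu_r))
  cat(sprintf("  survival      : mu = %g/day, gt = %g d, mu_gt = %g%s\n",
              x$mu, x$gt, mgt,
              if (is.null(x$mu_gt)) " (derived)" else " (override)"))
  cat(sprintf("  genetics      : h = %g, rho = %g, Z = %g, kappa = %g\n",
              x$h, x$rho, x$Z, x$kappa))
  invisible(x)
}

#' Genotype and sex level sets
#'
#' The model tracks one biallelic locus (`R` resistant, `S` sensitive),
#' hence three genotypes, in each of two sexes. These constants define the
#' canonical ordering used by every table and vector in the package.
#'
#' @format `genotypes()` returns `c("SS", "RS", "RR")`; `sexes()` returns
#'   `c("male", "female")`.
#' @return A character vector.
#' @name levels
NULL

#' @rdname levels
#' @export
genotypes <- function() c("SS", "RS", "RR")

#' @rdname levels
#' @export
sexes <- function() c("male", "female")

# classed error conditions -------------------------------------------------

resist_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "resistevol_error", "error")))
}
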