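#' Resistance-allele frequencies in males and females
#'
#' The model tracks the frequency of the resistance allele separately in
#' the male and female gamete pools; the sensitive-allele frequencies
#' `1 - p_m` and `1 - p_f` are implicit.
#'
#' @param p_m Resistance-allele frequency in males, in \[0, 1\].
#' @param p_f Resistance-allele frequency in females, in \[0, 1\].
#' @return An object of class `allele_freqs` with fields `p_m`, `p_f`.
#' @examples
#' allele_freqs(1e-5, 1e-5)
#' @export
allele_freqs <- function(p_m, p_f = p_m) {
  stopifnot(is.numeric(p_m), length(p_m) == 1L, is.finite(p_m),
            is.numeric(p_f), length(p_f) == 1L, is.finite(p_f),
            p_m >= 0, p_m <= 1, p_f >= 0, p_f <= 1)
  structure(list(p_m = p_m, p_f = p_f), class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat(sprintf("allele frequencies: p_m = %g, p_f = %g (mean %g)\n",
              x$p_m, x$p_f, (x$p_m + x$p_f) / 2))
  invisible(x)
}

# zygote genotype weights under random mating: SS, RS, RR cross products
zygote_weights <- function(freqs) {
  pm <- freqs$p_m; pf <- freqs$p_f
  qm <- 1 - pm; qf <- 1 - pf
  c(SS = qm * qf, RS = pm * qf + pf * qm, RR = pm * pf)
}

#' Mean fitness of one sex at given allele frequencies
#'
#' Random mating forms zygotes as cross products of the male and female
#' allele frequencies, so the mean fitness of sex `x` is
#' `W_RR * p_m * p_f + W_RS * (p_m * q_f + p_f * q_m) + W_SS * q_m * q_f`.
#'
#' @param table A [build_fitness_table()] result.
#' @param freqs An [allele_freqs()] object.
#' @param sex `"male"` or `"female"`.
#' @return The mean absolute fitness of that sex.
#' @export
mean_fitness <- function(table, freqs, sex) {
  sex <- match.arg(sex, sexes())
  stopifnot(inherits(table, "fitness_table"), inherits(freqs, "allele_freqs"))
  sum(table[sex, genotypes()] * zygote_weights(freqs))
}

#' Genotype frequencies after selection within one sex
#'
#' Zygote frequencies (cross products of the parental gamete pools) are
#' weighted by the sex-specific absolute fitnesses and renormalized by the
#' sex's mean fitness.
#'
#' @inheritParams mean_fitness
#' @return A named numeric vector `c(SS=, RS=, RR=)` summing to 1.
#' @examples
#' W <- build_fitness_table(resist_params(phi = 0.7))
#' genotype_freqs_after_selection(W, allele_freqs(0.5), "female")
#' @export
genotype_freqs_after_selection <- function(table, freqs, sex) {
  sex <- match.arg(sex, sexes())
  stopifnot(inherits(table, "fitness_table"), inherits(freqs, "allele_freqs"))
  w <- zygote_weights(freqs) * table[sex, genotypes()]
  wbar <- sum(w)
  if (wbar <= 0)
    resist_error(paste0("mean ", sex, " fitness is 0: population extinct"),
                 "resistevol_extinct_error")
  w / wbar
}

#' One generation of the two-sex selection recursion
#'
#' Advances the resistance-allele frequencies by one discrete,
#' non-overlapping generation. The post-selection gamete frequency of sex
#' `x` is `(W_x,RR * p_m * p_f + 0.5 * W_x,RS * (p_m*q_f + p_f*q_m)) /
#' Wbar_x`. Under neutrality (all fitnesses equal within each sex) both
#' outputs collapse to the sex-averaged frequency `(p_m + p_f) / 2`.
#'
#' @inheritParams mean_fitness
#' @return An [allele_freqs()] object for the next generation.
#' @examples
#' W <- build_fitness_table(resist_params(phi = 0.7))
#' next_allele_freqs(W, allele_freqs(1e-5))
#' @export
next_allele_freqs <- function(table, freqs) {
  stopifnot(inherits(table, "fitness_table"), inherits(freqs, "allele_freqs"))
  zw <- zygote_weights(freqs)
  out <- numeric(2L)
  for (i in seq_along(sexes())) {
    sx <- sexes()[i]
    w <- zw * table[sx, genotypes()]
    wbar <- sum(w)
    if (wbar <= 0)
      resist_error(paste0("mean ", sx, " fitness is 0: population extinct"),
                   "resistevol_extinct_error")
    out[i] <- (w[["RR"]] + 0.5 * w[["RS"]]) / wbar
  }
  # guard against tiny negative round-off at the boundaries
  out <- pmin(pmax(out, 0), 1)
  allele_freqs(out[1L], out[2L])
}
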