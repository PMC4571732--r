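#' Finite-population state: genotype counts per sex
#'
#' State container for the Wright-Fisher sampling counterpart of the
#' deterministic recursion. Census sizes are the column sums and stay
#' constant across generations (soft selection).
#'
#' @param males,females Named integer vectors of genotype counts
#'   `c(SS=, RS=, RR=)`, each summing to at least 1.
#' @return An object of class `population_state` with fields `males`,
#'   `females`, `N_m`, `N_f`.
#' @examples
#' population_state(c(SS = 990, RS = 10, RR = 0),
#'                  c(SS = 990, RS = 10, RR = 0))
#' @export
population_state <- function(males, females) {
  chk <- function(x, what) {
    if (!is.numeric(x) || length(x) != 3L ||
        !setequal(names(x), genotypes()))
      stop(what, " must be a named vector with entries SS, RS, RR",
           call. = FALSE)
    x <- x[genotypes()]
    if (any(x < 0) || any(x != round(x)))
      stop(what, " counts must be non-negative integers", call. = FALSE)
    if (sum(x) < 1) stop(what, " population size must be >= 1",
                         call. = FALSE)
    x
  }
  males <- chk(males, "males"); females <- chk(females, "females")
  structure(list(males = males, females = females,
                 N_m = sum(males), N_f = sum(females)),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("population state (N_m = %d, N_f = %d)\n", x$N_m, x$N_f))
  print(rbind(male = x$males, female = x$females))
  invisible(x)
}

#' Monomorphic-plus-heterozygote helper for a given allele frequency
#'
#' Builds a `population_state` whose genotype counts are the rounded
#' Hardy-Weinberg proportions at frequency `p` in both sexes. Convenient
#' for seeding stochastic runs comparable to deterministic ones.
#'
#' @param p Resistance-allele frequency.
#' @param N Census size per sex.
#' @return A `population_state`.
#' @export
population_from_frequency <- function(p, N) {
  stopifnot(p >= 0, p <= 1, N >= 1)
  counts <- round(N * c(SS = (1 - p)^2, RS = 2 * p * (1 - p), RR = p^2))
  counts["SS"] <- N - counts[["RS"]] - counts[["RR"]]
  population_state(counts, counts)
}

# allele frequencies implied by genotype counts
state_freqs <- function(state) {
  allele_freqs((2 * state$males[["RR"]] + state$males[["RS"]]) / (2 * state$N_m),
               (2 * state$females[["RR"]] + state$females[["RS"]]) / (2 * state$N_f))
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# one unseeded sampling generation (uses the current RNG stream)
stochastic_step <- function(state, W) {
  freqs <- state_freqs(state)
  nxt <- next_allele_freqs(W, freqs)  # post-selection gamete frequencies
  pm <- nxt$p_m; pf <- nxt$p_f
  probs <- c(SS = (1 - pm) * (1 - pf),
             RS = pm * (1 - pf) + pf * (1 - pm),
             RR = pm * pf)
  draw <- function(N) {
    x <- as.vector(stats::rmultinom(1L, N, probs))
    names(x) <- genotypes()
    x
  }
  population_state(draw(state$N_m), draw(state$N_f))
}

#' One generation of the Wright-Fisher sampling counterpart
#'
#' Applies the deterministic selection machinery to the allele frequencies
#' implied by the current genotype counts, then draws the next
#' generation's genotype counts by one multinomial sample per sex from the
#' random-mating cross products of the post-selection gamete frequencies,
#' at constant census sizes. Reproducible under a fixed seed.
#'
#' @param state A [population_state()].
#' @param params A [resist_params()] object.
#' @param rng_seed Integer seed.
#' @return The next `population_state`.
#' @export
stochastic_generation <- function(state, params, rng_seed) {
  stopifnot(inherits(state, "population_state"),
            inherits(params, "resist_params"))
  W <- build_fitness_table(params)
  with_seed(rng_seed, stochastic_step(state, W))
}

#' Multi-generation stochastic trajectory
#'
#' Repeats [stochastic_generation()] under one seed, recording the allele
#' frequency in each sex every generation. Identical seeds replay
#' bit-identical sequences.
#'
#' @inheritParams stochastic_generation
#' @param generations Number of generations to simulate (>= 1).
#' @return A data frame with columns `generation`, `p_m`, `p_f`,
#'   `p_mean`, with the final `population_state` in attribute `state` and
#'   the seed and census sizes in attribute `run`.
#' @examples
#' st <- population_from_frequency(0.01, 1000)
#' stochastic_trajectory(st, resist_params(phi = 1), 10, rng_seed = 1)
#' @export
stochastic_trajectory <- function(state, params, generations, rng_seed) {
  stopifnot(inherits(state, "population_state"),
            inherits(params, "resist_params"), generations >= 1)
  W <- build_fitness_table(params)
  p_m <- p_f <- numeric(generations + 1L)
  f0 <- state_freqs(state)
  p_m[1L] <- f0$p_m; p_f[1L] <- f0$p_f
  state <- with_seed(rng_seed, {
    for (t in seq_len(generations)) {
      state <- stochastic_step(state, W)
      f <- state_freqs(state)
      p_m[t + 1L] <- f$p_m; p_f[t + 1L] <- f$p_f
    }
    state
  })
  structure(data.frame(generation = 0:generations, p_m = p_m, p_f = p_f,
                       p_mean = (p_m + p_f) / 2),
            state = state,
            run = list(rng_seed = rng_seed, N_m = state$N_m,
                       N_f = state$N_f),
            class = c("stochastic_trajectory", "data.frame"))
}
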