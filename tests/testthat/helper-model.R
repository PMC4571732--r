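# shared fixtures: parameter sets, random draws, brute-force references

# defaults with the conventional rounded per-cycle mortality (0.27), used
# where frozen reference values were computed with it
p27 <- function(...) resist_params(mu_gt = 0.27, ...)

# n random valid parameter sets spanning the plausible ranges
random_params <- function(n, seed) {
  set.seed(seed)
  replicate(n, resist_params(
    phi = runif(1), psi = runif(1, 0, 0.5), Q = runif(1, 0.3, 1),
    r = runif(1), s = runif(1, 0.05, 0.5), sigma = runif(1, 0.7, 1),
    mu = runif(1, 0.05, 0.2), mu_r = runif(1, 0, 0.1),
    h = runif(1), rho = runif(1, 0.5, 1), Z = runif(1, 0, 0.3)),
    simplify = FALSE)
}

# truncated geometric series for lifetime feeding success (independent of
# the closed form in the package)
feeding_series <- function(params, surv, n_terms = 200) {
  xi <- params$sigma *
    (1 - params$Q * params$phi * (1 - (1 - params$r) * surv))
  ratio <- params$Q * params$phi * params$r * (1 - params$mu_r)
  sum(xi * ratio^(0:n_terms))
}

# deterministic sex-averaged frequency path, as a plain loop
det_mean_path <- function(params, p0, generations) {
  W <- build_fitness_table(params)
  cur <- allele_freqs(p0, p0)
  out <- numeric(generations + 1L)
  out[1L] <- p0
  for (t in seq_len(generations)) {
    cur <- next_allele_freqs(W, cur)
    out[t + 1L] <- (cur$p_m + cur$p_f) / 2
  }
  out
}

# hand-built fitness table for selection-operator unit tests
mk_table <- function(male, female = male) {
  W <- rbind(male = male, female = female)
  colnames(W) <- c("SS", "RS", "RR")
  structure(W, class = c("fitness_table", "matrix"))
}
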