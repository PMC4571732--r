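#' Simulate the deterministic allele-frequency trajectory
#'
#' Iterates the two-sex selection recursion from an initial frequency pair
#' over discrete non-overlapping generations, recording every generation,
#' and stops early once the sex-averaged frequency crosses the fixation or
#' elimination tolerance.
#'
#' @param params A [resist_params()] object.
#' @param init An [allele_freqs()] object; the conventional starting point
#'   for invasion experiments is `allele_freqs(1e-5)`.
#' @param max_generations Horizon after which the run is labelled
#'   `"not-converged"`.
#' @param fix_tol Fixation is declared when the mean frequency exceeds
#'   `1 - fix_tol`.
#' @param elim_tol Elimination is declared when the mean frequency falls
#'   below `elim_tol`. Kept far below the usual `1e-5` start.
#' @return A `resist_trajectory`: a data frame with columns `generation`,
#'   `p_m`, `p_f`, `p_mean`, `W_bar_m`, `W_bar_f`, and attributes
#'   `outcome` (`"fixation"`, `"elimination"` or `"not-converged"`),
#'   `params` and `tolerances`.
#' @examples
#' tr <- simulate_trajectory(resist_params(phi = 0.7, psi = 0.25))
#' outcome(tr)
#' tail(tr, 3)
#' @export
simulate_trajectory <- function(params, init = allele_freqs(1e-5),
                                max_generations = 50000,
                                fix_tol = 1e-6, elim_tol = 1e-9) {
  stopifnot(inherits(params, "resist_params"),
            inherits(init, "allele_freqs"),
            max_generations >= 1)
  W <- build_fitness_table(params)
  n_max <- max_generations + 1L
  p_m <- p_f <- wb_m <- wb_f <- numeric(n_max)
  cur <- init
  outcome <- "not-converged"
  n <- 0L
  for (t in seq_len(n_max)) {
    n <- t
    p_m[t] <- cur$p_m
    p_f[t] <- cur$p_f
    wb_m[t] <- mean_fitness(W, cur, "male")
    wb_f[t] <- mean_fitness(W, cur, "female")
    pbar <- (cur$p_m + cur$p_f) / 2
    if (pbar > 1 - fix_tol) { outcome <- "fixation"; break }
    if (pbar < elim_tol)    { outcome <- "elimination"; break }
    if (t == n_max) break
    cur <- next_allele_freqs(W, cur)
  }
  idx <- seq_len(n)
  out <- data.frame(generation = idx - 1L,
                    p_m = p_m[idx], p_f = p_f[idx],
                    p_mean = (p_m[idx] + p_f[idx]) / 2,
                    W_bar_m = wb_m[idx], W_bar_f = wb_f[idx])
  structure(out,
            outcome = outcome,
            params = params,
            tolerances = c(fix_tol = fix_tol, elim_tol = elim_tol),
            class = c("resist_trajectory", "data.frame"))
}

#' Terminal outcome of a simulated trajectory
#'
#' @param x A `resist_trajectory`.
#' @return `"fixation"`, `"elimination"` or `"not-converged"`.
#' @export
outcome <- function(x) {
  stopifnot(inherits(x, "resist_trajectory"))
  attr(x, "outcome")
}

#' @export
print.resist_trajectory <- function(x, ...) {
  cat(sprintf(
    "Allele-frequency trajectory: %d generations, outcome: %s\n",
    nrow(x) - 1L, attr(x, "outcome")))
  cat(sprintf("  final p_m = %g, p_f = %g\n",
              x$p_m[nrow(x)], x$p_f[nrow(x)]))
  invisible(x)
}

#' Generations until the resistance allele first reaches a frequency
#'
#' Counts generations of the recursion until the sex-averaged frequency
#' `(p_m + p_f) / 2` first reaches `target`. Returns `Inf` ("never") if
#' the target is not reached within `max_generations` or the allele is
#' eliminated first.
#'
#' @inheritParams simulate_trajectory
#' @param target Frequency in (0, 1) to be reached.
#' @return A generation count (0 if already at or above `target`), or
#'   `Inf`.
#' @examples
#' time_to_frequency(resist_params(phi = 1), target = 0.5)
#' @export
time_to_frequency <- function(params, init = allele_freqs(1e-5),
                              target = 0.5, max_generations = 50000,
                              elim_tol = 1e-9) {
  stopifnot(inherits(params, "resist_params"),
            inherits(init, "allele_freqs"),
            target > 0, target < 1, max_generations >= 1)
  W <- build_fitness_table(params)
  cur <- init
  for (t in 0:max_generations) {
    pbar <- (cur$p_m + cur$p_f) / 2
    if (pbar >= target) return(as.numeric(t))
    if (pbar < elim_tol) return(Inf)
    cur <- next_allele_freqs(W, cur)
  }
  Inf
}

#' Invasion growth factor of a rare allele
#'
#' Linearizing the recursion around a monomorphic resident population
#' gives the per-generation multiplication rate of a rare allele's summed
#' frequency: for a rare resistance allele in a sensitive population,
#' `lambda = 0.5 * (W_m,RS / W_m,SS + W_f,RS / W_f,SS)`; for a rare
#' sensitive allele in a resistant population the `SS` fitnesses are
#' replaced by the `RR` ones. `lambda > 1` means the rare allele
#' increases.
#'
#' @param params A [resist_params()] object.
#' @param invading `"R"` (resistance invading sensitive residents) or
#'   `"S"` (sensitive invading resistant residents).
#' @return The growth factor, a non-negative number.
#' @examples
#' invasion_growth_factor(resist_params(psi = 0.2))        # > 1: invades
#' invasion_growth_factor(resist_params(r = 1, phi = 0.7)) # cost only
#' @export
invasion_growth_factor <- function(params, invading = c("R", "S")) {
  invading <- match.arg(invading)
  W <- build_fitness_table(params)
  resident <- if (invading == "R") "SS" else "RR"
  if (any(W[, resident] <= 0))
    resist_error(paste0("resident genotype ", resident,
                        " has zero fitness in at least one sex"),
                 "resistevol_resident_inviable_error")
  0.5 * (W["male", "RS"] / W["male", resident] +
           W["female", "RS"] / W["female", resident])
}

#' Classify the long-run fate of the resistance allele
#'
#' Runs the recursion (without storing the path) and reports whether the
#' allele fixes, is eliminated, or has done neither within the horizon.
#' `"not-converged"` is a legitimate result: besides neutral parameter
#' sets, a narrow larvicide regime exists where both alleles invade when
#' rare (a protected polymorphism), and it is reported honestly rather
#' than forced into a binary label.
#'
#' @inheritParams simulate_trajectory
#' @return An outcome label: `"fixation"`, `"elimination"` or
#'   `"not-converged"`.
#' @examples
#' classify_outcome(resist_params(psi = 0.3))
#' @export
classify_outcome <- function(params, init = allele_freqs(1e-5),
                             max_generations = 50000,
                             fix_tol = 1e-6, elim_tol = 1e-9) {
  stopifnot(inherits(params, "resist_params"),
            inherits(init, "allele_freqs"), max_generations >= 1)
  W <- build_fitness_table(params)
  cur <- init
  for (t in 0:max_generations) {
    pbar <- (cur$p_m + cur$p_f) / 2
    if (pbar > 1 - fix_tol) return("fixation")
    if (pbar < elim_tol) return("elimination")
    cur <- next_allele_freqs(W, cur)
  }
  "not-converged"
}

# does the invasion/fixation criterion hold at this parameter set?
# resident-inviable residents count as invadable (lambda -> Inf).
criterion_holds <- function(params, criterion) {
  lam_R <- tryCatch(invasion_growth_factor(params, "R"),
                    resistevol_resident_inviable_error = function(e) Inf)
  if (criterion == "invasion") return(lam_R > 1)
  lam_S <- tryCatch(invasion_growth_factor(params, "S"),
                    resistevol_resident_inviable_error = function(e) Inf)
  lam_R > 1 && lam_S < 1
}

#' Smallest intervention coverage at which resistance invades or fixes
#'
#' Scans one coverage axis (`phi` for nets, `psi` for larvicide) holding
#' every other parameter fixed, and finds the smallest coverage at which
#' the chosen criterion holds: `"invasion"` requires the rare-resistance
#' growth factor to exceed 1; `"fixation"` additionally requires a rare
#' sensitive allele to decline in a resistant population. A coarse
#' grid scan (default 101 points on \[0, 1\]) brackets the boundary,
#' which is then refined by bisection to absolute tolerance `tol`.
#'
#' @inheritParams simulate_trajectory
#' @param vary `"phi"` or `"psi"`: which coverage to scan.
#' @param criterion `"invasion"` or `"fixation"`.
#' @param tol Absolute tolerance of the bisection refinement.
#' @param grid_points Number of points of the bracketing pre-scan.
#' @return The threshold coverage in \[0, 1\], or `NA` if the criterion
#'   holds nowhere on the grid. If the criterion flips more than once on
#'   the grid, the smallest crossing is refined and a warning is issued.
#' @examples
#' find_coverage_threshold(resist_params(), vary = "psi")  # ~0.0974
#' @export
find_coverage_threshold <- function(params, vary = c("phi", "psi"),
                                    criterion = c("invasion", "fixation"),
                                    tol = 1e-4, grid_points = 101) {
  vary <- match.arg(vary)
  criterion <- match.arg(criterion)
  stopifnot(inherits(params, "resist_params"), tol > 0, grid_points >= 2)
  at <- function(x)

    criterion_holds(do.call(update_params,
                            stats::setNames(list(params, x), c("params", vary))),
                    criterion)
  xs <- seq(0, 1, length.out = grid_points)
  flags <- vapply(xs, at, logical(1L))
  if (!any(flags)) return(NA_real_)
  if (flags[1L]) return(0)
  crossings <- which(diff(flags) != 0L)
  if (length(crossings) > 1L)
    warning("criterion flips more than once on the ", vary,
            " grid; reporting the smallest crossing", call. = FALSE)
  i <- crossings[1L] + 1L
  lo <- xs[i - 1L]; hi <- xs[i]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (at(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Ratio of ITN-only to larvicide-only resistance-evolution times
#'
#' Compares the selection pressure of the two deployment modes at equal
#' coverage: the time for the resistance allele to reach `target` with
#' nets alone (`phi = coverage`, `psi = 0`) divided by the time with
#' larvicide alone (`psi = coverage`, `phi = 0`), both starting from
#' frequency `1e-5` in both sexes. A ratio of 8 means larvicides drive
#' resistance eight times faster than nets at the same coverage.
#'
#' @param coverage Common coverage in (0, 1\].
#' @inheritParams time_to_frequency
#' @return A positive ratio, or `Inf` when nets alone never get the
#'   allele to `target` while larvicide alone does.
#' @examples
#' evolution_time_ratio(0.5, resist_params(r = 0))
#' @export
evolution_time_ratio <- function(coverage, params, target = 0.5,
                                 init = allele_freqs(1e-5),
                                 max_generations = 50000) {
  stopifnot(coverage > 0, coverage <= 1)
  t_itn <- time_to_frequency(update_params(params, phi = coverage, psi = 0),
                             init = init, target = target,
                             max_generations = max_generations)
  t_larv <- time_to_frequency(update_params(params, phi = 0, psi = coverage),
                              init = init, target = target,
                              max_generations = max_generations)
  if (!is.finite(t_larv))
    resist_error(paste0("larvicide-only scenario never reaches target ",
                        target, " at coverage ", coverage,
                        ": ratio undefined"),
                 "resistevol_undefined_ratio_error")
  if (!is.finite(t_itn)) return(Inf)
  t_itn / t_larv
}
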