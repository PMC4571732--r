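#' Specification of a parameter sweep
#'
#' Describes one family of experiment curves: a coverage axis to scan, a
#' grid of values on it, a second parameter distinguishing the curves,
#' and a fixed baseline parameter set for everything else.
#'
#' @param base_params A [resist_params()] baseline.
#' @param grid Numeric grid on the coverage axis, each value in the
#'   parameter's valid range.
#' @param grid_param Name of the scanned parameter (`"phi"`, `"psi"` or
#'   `"coverage"` for the equal-coverage ratio experiment).
#' @param curve_param Name of the parameter distinguishing curves (e.g.
#'   `"r"` or `"Q"`), or `NULL` for a single curve.
#' @param curve_values Numeric values of `curve_param`, one per curve.
#' @return An object of class `sweep_spec`.
#' @examples
#' sweep_spec(resist_params(), grid = seq(0, 1, 0.1), grid_param = "phi",
#'            curve_param = "r", curve_values = seq(0, 1, 0.2))
#' @export
sweep_spec <- function(base_params = resist_params(),
                       grid, grid_param,
                       curve_param = NULL, curve_values = NULL) {
  stopifnot(inherits(base_params, "resist_params"),
            is.numeric(grid), length(grid) >= 1,
            is.character(grid_param), length(grid_param) == 1L)
  if (any(grid < 0 | grid > 1))
    stop("grid values must lie in [0, 1]", call. = FALSE)
  if (is.null(curve_param) != is.null(curve_values))
    stop("curve_param and curve_values must be supplied together",
         call. = FALSE)
  if (!is.null(curve_param)) {
    if (!curve_param %in% names(formals(resist_params)))
      stop("unknown curve parameter: ", curve_param, call. = FALSE)
    # each override must yield a valid parameter set
    for (v in curve_values)
      do.call(update_params,
              stats::setNames(list(base_params, v),
                              c("params", curve_param)))
  }
  structure(list(base_params = base_params, grid = grid,
                 grid_param = grid_param, curve_param = curve_param,
                 curve_values = curve_values),
            class = "sweep_spec")
}

# apply a curve override (no-op for single-curve specs)
curve_params <- function(spec, value) {
  if (is.null(spec$curve_param)) return(spec$base_params)
  do.call(update_params,
          stats::setNames(list(spec$base_params, value),
                          c("params", spec$curve_param)))
}

curve_iter <- function(spec) {
  if (is.null(spec$curve_param)) NA_real_ else spec$curve_values
}

#' Minimal larvicide coverage for fixation, across ITN coverages
#'
#' For each curve (e.g. repellency value) and each ITN coverage on the
#' grid, finds the smallest larvicide coverage `psi` at which resistance
#' both invades when rare and cannot be reinvaded by the sensitive allele
#' ([find_coverage_threshold()] with the fixation criterion). Points where
#' no larvicide coverage fixes resistance are reported as `NA`.
#'
#' @param spec A [sweep_spec()] whose `grid` is the ITN coverage axis.
#' @param tol,grid_points Passed on to [find_coverage_threshold()].
#' @return A data frame with columns `curve_param`, `curve_value`, `phi`,
#'   `psi_threshold`.
#' @examples
#' sp <- sweep_spec(resist_params(), grid = c(0, 0.5, 1),
#'                  grid_param = "phi", curve_param = "r",
#'                  curve_values = c(0, 1))
#' fixation_boundary_experiment(sp)
#' @export
fixation_boundary_experiment <- function(spec, tol = 1e-4,
                                         grid_points = 101) {
  stopifnot(inherits(spec, "sweep_spec"), spec$grid_param == "phi")
  rows <- list()
  for (cv in curve_iter(spec)) {
    base <- curve_params(spec, cv)
    for (phi in spec$grid) {
      p <- update_params(base, phi = phi)
      thr <- find_coverage_threshold(p, vary = "psi",
                                     criterion = "fixation",
                                     tol = tol, grid_points = grid_points)
      rows[[length(rows) + 1L]] <-
        data.frame(curve_param = spec$curve_param %||% "none",
                   curve_value = cv, phi = phi, psi_threshold = thr)
    }
  }
  do.call(rbind, rows)
}

#' Generations to 50% resistance, across ITN coverages
#'
#' For each curve and each ITN coverage on the grid, the number of
#' generations for the resistance allele to climb from `1e-5` to
#' `target`. Points never reaching the target within the horizon are
#' reported as `Inf` (serialized as `"never"` in CSV output).
#'
#' @param spec A [sweep_spec()] whose `grid` is the ITN coverage axis.
#' @param target Frequency to reach, default 0.5.
#' @param init Initial frequencies, default `allele_freqs(1e-5)`.
#' @param max_generations Horizon.
#' @return A data frame with columns `curve_param`, `curve_value`, `phi`,
#'   `generations`.
#' @export
time_to_resistance_experiment <- function(spec, target = 0.5,
                                          init = allele_freqs(1e-5),
                                          max_generations = 50000) {
  stopifnot(inherits(spec, "sweep_spec"), spec$grid_param == "phi")
  rows <- list()
  for (cv in curve_iter(spec)) {
    base <- curve_params(spec, cv)
    for (phi in spec$grid) {
      p <- update_params(base, phi = phi)
      tt <- time_to_frequency(p, init = init, target = target,
                              max_generations = max_generations)
      rows[[length(rows) + 1L]] <-
        data.frame(curve_param = spec$curve_param %||% "none",
                   curve_value = cv, phi = phi, generations = tt)
    }
  }
  do.call(rbind, rows)
}

#' Larvicide-versus-ITN evolution-rate ratio, across equal coverages
#'
#' For each repellency curve and each coverage on the grid, the ratio of
#' the ITN-only to the larvicide-only time to 50% resistance
#' ([evolution_time_ratio()]). Ratios are `Inf` when nets alone never
#' drive resistance to the target, and `NA` with status `"undefined"`
#' when larvicide alone does not either.
#'
#' @param spec A [sweep_spec()] whose `grid` is the common coverage axis
#'   (`grid_param = "coverage"`).
#' @inheritParams time_to_resistance_experiment
#' @return A data frame with columns `curve_param`, `curve_value`,
#'   `coverage`, `ratio`, `status` (`"finite"`, `"inf"` or
#'   `"undefined"`).
#' @export
larvicide_itn_ratio_experiment <- function(spec, target = 0.5,
                                           init = allele_freqs(1e-5),
                                           max_generations = 50000) {
  stopifnot(inherits(spec, "sweep_spec"),
            spec$grid_param %in% c("coverage", "phi", "psi"))
  rows <- list()
  for (cv in curve_iter(spec)) {
    base <- curve_params(spec, cv)
    for (cov in spec$grid) {
      ratio <- if (cov == 0) NA_real_ else
        tryCatch(evolution_time_ratio(cov, base, target = target,
                                      init = init,
                                      max_generations = max_generations),
                 resistevol_undefined_ratio_error = function(e) NA_real_)
      status <- if (is.na(ratio)) "undefined"
                else if (is.infinite(ratio)) "inf" else "finite"
      rows[[length(rows) + 1L]] <-
        data.frame(curve_param = spec$curve_param %||% "none",
                   curve_value = cv, coverage = cov, ratio = ratio,
                   status = status)
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
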