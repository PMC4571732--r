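#' Write a trajectory or experiment table as CSV
#'
#' Trajectories keep their `(generation, p_m, p_f, p_mean, W_bar_m,
#' W_bar_f)` columns. Non-finite entries in experiment tables are
#' serialized as literal markers rather than sentinel numbers: `Inf`
#' becomes `"inf"` in ratio columns and `"never"` in generation-count
#' columns, and `NA` ratios become `"undefined"`.
#'
#' @param x A data frame (trajectory, stochastic trajectory or experiment
#'   table).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  out <- as.data.frame(x)
  if ("generations" %in% names(out)) {
    v <- out$generations
    out$generations <- ifelse(is.finite(v), as.character(v), "never")
  }
  if ("ratio" %in% names(out)) {
    v <- out$ratio
    out$ratio <- ifelse(is.na(v), "undefined",
                        ifelse(is.infinite(v), "inf", as.character(v)))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON run-record for an invocation
#'
#' Records the fully resolved parameter set, tolerances, and any extra
#' fields (outcome label, seed, census sizes, grid specification, tool
#' version) so a run can be audited and reproduced.
#'
#' @param path Output file path.
#' @param params A [resist_params()] object.
#' @param ... Further named fields to include.
#' @return `path`, invisibly.
#' @export
write_run_record <- function(path, params, ...) {
  stopifnot(inherits(params, "resist_params"))
  rec <- list(
    tool = "resistevol",
    version = as.character(utils::packageVersion("resistevol")),
    parameters = c(unclass(params)[setdiff(names(unclass(params)), "mu_gt")],
                   list(mu_gt = effective_mu_gt(params),
                        mu_gt_overridden = !is.null(params$mu_gt))),
    ...)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
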