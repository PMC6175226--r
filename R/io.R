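#' Write / read an IPD dataset as CSV with a truth sidecar
#'
#' The patient table is written as plain CSV with header
#' `study_id,y,group,x`.  The generating scenario and the per-study truth
#' table travel in a JSON sidecar (`<path>.json`) so a re-read dataset can
#' still be scored against its generating parameters.
#'
#' @param dataset An `ipd_dataset`.
#' @param path CSV file path.
#' @return `write_ipd`: the path, invisibly.  `read_ipd`: an
#'   `ipd_dataset` (without truth attributes if no sidecar is found).
#' @export
write_ipd <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset)[, c("study_id", "y", "group", "x")],
                   path, row.names = FALSE)
  spec <- attr(dataset, "scenario")
  sidecar <- list(scenario = unclass(spec),
                  studies = attr(dataset, "studies"),
                  dropped_studies = attr(dataset, "dropped_studies"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ipd
#' @export
read_ipd <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("study_id", "y", "group", "x") %in% names(df)))
  sidecar_path <- paste0(path, ".json")
  scenario <- studies <- dropped <- NULL
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    scenario <- sc$scenario
    if (!is.null(scenario)) {
      scenario$seed <- if (is.null(scenario$seed)) NULL
                       else as.integer(scenario$seed)
      class(scenario) <- "scenario_spec"
    }
    studies <- sc$studies
    dropped <- sc$dropped_studies
  }
  structure(df, scenario = scenario, studies = studies,
            dropped_studies = dropped,
            class = c("ipd_dataset", "data.frame"))
}

#' Aggregate-data interchange for the two-stage pipeline
#'
#' First-stage study estimates are exportable as
#' `study_id,coef,var,n,estimable` CSV, and the pooling stage can consume
#' externally supplied aggregate rows in the same format — the standard
#' situation where some collaborators share only summary estimates.
#'
#' @param estimates A `study_estimates` data frame.
#' @param path CSV file path.
#' @export
write_study_estimates <- function(estimates, path) {
  utils::write.csv(as.data.frame(estimates)[, c("study_id", "coef", "var",
                                                "n", "estimable")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_study_estimates
#' @export
read_study_estimates <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("study_id", "coef", "var", "estimable") %in% names(df)))
  if (!"n" %in% names(df)) df$n <- NA_integer_
  df$estimable <- as.logical(df$estimable)
  structure(df[, c("study_id", "coef", "var", "n", "estimable")],
            class = c("study_estimates", "data.frame"))
}

#' Read a grid configuration from a JSON file
#'
#' The config may carry `settings`, `n_iterations`, `master_seed`,
#' `models`, and optional `size_grid` / `heterogeneity_grid` tables (lists
#' of rows); omitted parts fall back to the package defaults.
#'
#' @param path JSON config file.
#' @return A [grid_spec()].
#' @export
read_grid_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$settings)) stop("config must name `settings`",
                                  call. = FALSE)
  grid_spec(
    settings = cfg$settings,
    size_grid = if (!is.null(cfg$size_grid)) as.data.frame(cfg$size_grid)
                else default_size_grid(),
    heterogeneity_grid = if (!is.null(cfg$heterogeneity_grid))
                           as.data.frame(cfg$heterogeneity_grid)
                         else default_heterogeneity_grid(),
    n_iterations = if (!is.null(cfg$n_iterations)) cfg$n_iterations
                   else 1000,
    master_seed = if (!is.null(cfg$master_seed)) cfg$master_seed else 1,
    models = cfg$models)
}
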