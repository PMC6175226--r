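#' Default factorial grids
#'
#' The default size grid has nine rows — total patients split across
#' studies as 5000/10, 2000/4, 1000/2 (mean size 500), 5000/20, 2000/8,
#' 1000/4 (mean 250) and 5000/50, 2000/20, 1000/10 (mean 100).  The
#' default heterogeneity grid holds the six (intercept, exposure) I² pairs
#' (0,0), (.5,0), (0,.5), (1/3,1/3), (.5,.5), (2/3,2/3).
#'
#' @return Data frames with the grid rows.
#' @export
default_size_grid <- function() {
  data.frame(total_patients = c(5000, 2000, 1000, 5000, 2000, 1000,
                                5000, 2000, 1000),
             n_studies = c(10, 4, 2, 20, 8, 4, 50, 20, 10),
             mean_size = c(500, 500, 500, 250, 250, 250, 100, 100, 100))
}

#' @rdname default_size_grid
#' @export
default_heterogeneity_grid <- function() {
  data.frame(i2_intercept = c(0, 0.5, 0, 1/3, 0.5, 2/3),
             i2_exposure = c(0, 0, 0.5, 1/3, 0.5, 2/3))
}

# Models analysed by default: a, b, c plus the two-stage model d
# everywhere; the random-interaction models e-g only for setting 8.
default_models <- function(setting) {
  if (setting == 8) c("a", "b", "c", "d", "e", "f", "g")
  else c("a", "b", "c", "d")
}

#' Specify a simulation grid
#'
#' @param settings Subset of `1:8`.
#' @param size_grid Data frame with columns `total_patients`, `n_studies`,
#'   `mean_size`; defaults to the nine standard rows.
#' @param heterogeneity_grid Data frame with columns `i2_intercept`,
#'   `i2_exposure`; defaults to the six standard pairs.
#' @param n_iterations Replications per cell.
#' @param master_seed Master seed; per-(cell, iteration) seeds are derived
#'   deterministically so cells can run in any order or in parallel
#'   without stream overlap.
#' @param models Character subset of `a`–`g` plus `d` (two-stage), or
#'   `NULL` for the per-setting default.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(settings, size_grid = default_size_grid(),
                      heterogeneity_grid = default_heterogeneity_grid(),
                      n_iterations = 1000, master_seed = 1,
                      models = NULL) {
  settings <- as.integer(settings)
  if (length(settings) == 0 || !all(settings %in% 1:8))
    stop("`settings` must be a non-empty subset of 1..8", call. = FALSE)
  if (!all(c("total_patients", "n_studies", "mean_size") %in%
           names(size_grid)))
    stop("malformed size grid", call. = FALSE)
  if (!all(c("i2_intercept", "i2_exposure") %in% names(heterogeneity_grid)))
    stop("malformed heterogeneity grid", call. = FALSE)
  if (!is.null(models) &&
      !all(models %in% c("a", "b", "c", "d", "e", "f", "g")))
    stop("unknown model id", call. = FALSE)
  structure(list(settings = settings, size_grid = size_grid,
                 heterogeneity_grid = heterogeneity_grid,
                 n_iterations = as.integer(n_iterations),
                 master_seed = as.integer(master_seed), models = models),
            class = "grid_spec")
}

# Deterministic per-(cell, iteration) seed below 2^31, mixed so distinct
# cells and iterations get distinct, order-independent streams.
derive_seed <- function(master_seed, cell_index, iteration) {
  m <- 2147483647
  h <- 1
  for (v in c(master_seed, cell_index, iteration))
    h <- ((h * 69069) %% m + (as.numeric(v) %% m)) %% m
  as.integer(((h * 69069) %% m) + 1)
}

# Fit one model id on one dataset, returning a raw-table row.
fit_model_row <- function(dataset, model_id, target, interaction_mode) {
  fr <- if (model_id == "d") {
    fit_twostage(dataset, target = target, method = "REML")
  } else {
    spec <- onestage_model_spec(model_id,
      interaction = if (model_id %in% c("a", "b", "c")) interaction_mode
                    else NULL)
    fit_onestage(dataset, spec, target = target)
  }
  data.frame(model = model_id, target = target,
             estimate = fr$estimate, se = fr$se,
             ci_lo = fr$ci_low, ci_hi = fr$ci_high,
             converged = isTRUE(fr$converged))
}

#' Run one grid cell
#'
#' Executes `n_iterations` replications of one (setting, size,
#' heterogeneity) cell.  Every requested model is fitted on the *same*
#' generated dataset within a replication, so model comparisons are
#' paired.  For the small-study setting the selection filter is applied
#' before any model sees the data.  The analysis target is the exposure
#' effect for settings 1–4 and the interaction effect for settings 5–8
#' (where models a–c gain a common fixed interaction term).
#'
#' @param setting Simulation setting, 1–8.
#' @param n_studies,mean_size Cell size parameters.
#' @param i2_intercept,i2_exposure Cell heterogeneity parameters.
#' @param models Character vector of model ids (`"d"` = two-stage);
#'   `NULL` for the setting default.
#' @param n_iterations Number of replications.
#' @param master_seed Master seed.
#' @param cell_index Integer distinguishing this cell in a larger grid
#'   (enters the per-replication seed derivation).
#' @return List with `raw` (one row per replication x model) and
#'   `summary` (one metrics row per model).  Both carry the cell
#'   descriptors.
#' @export
run_cell <- function(setting, n_studies, mean_size,
                     i2_intercept = 0, i2_exposure = 0,
                     models = NULL, n_iterations = 100,
                     master_seed = 1, cell_index = 1L) {
  setting <- as.integer(setting)
  if (is.null(models)) models <- default_models(setting)
  target <- setting_target(setting)
  interaction_mode <- if (target == "interaction") "common_fixed"
                      else "absent"
  raw <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    seed <- derive_seed(master_seed, cell_index, it)
    spec <- setting_preset(setting, n_studies, mean_size,
                           i2_intercept, i2_exposure, seed = seed)
    ds <- generate_ipd(spec)
    if (spec$selection_fraction > 0)
      ds <- apply_small_study_filter(ds, spec$selection_fraction)
    rows <- lapply(models, function(m)
      fit_model_row(ds, m, target, interaction_mode))
    rows <- do.call(rbind, rows)
    rows <- cbind(data.frame(setting = setting,
                             total_n = n_studies * mean_size,
                             k = n_studies,
                             i2_int = i2_intercept, i2_exp = i2_exposure,
                             iter = it), rows)
    raw[[it]] <- rows
  }
  raw <- do.call(rbind, raw)
  truth <- if (target == "exposure") {
    if (setting <= 4) 0.5 else 1
  } else 0.4
  null_value <- setting_null_value(setting)
  summary <- do.call(rbind, lapply(models, function(m) {
    s <- summarize_fits(raw[raw$model == m, , drop = FALSE], truth,
                        null_value)
    cbind(data.frame(setting = setting, total_n = n_studies * mean_size,
                     k = n_studies, i2_int = i2_intercept,
                     i2_exp = i2_exposure, model = m, target = target,
                     truth = truth, null_value = null_value), s)
  }))
  rownames(raw) <- rownames(summary) <- NULL
  list(raw = raw, summary = summary)
}

#' Run a full simulation grid
#'
#' Iterates [run_cell()] over settings x size-grid x heterogeneity-grid,
#' with cell-index-derived seeds so results are independent of execution
#' order.  Optionally writes `raw.csv`, `summary.csv` and
#' `convergence.csv` to an output directory.
#'
#' @param grid A [grid_spec()].
#' @param out_dir Optional directory for CSV output.
#' @param progress Print one line per completed cell.
#' @return List with `raw`, `summary` and `convergence` data frames.
#' @export
run_grid <- function(grid, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(grid, "grid_spec"))
  cells <- expand.grid(si = seq_len(nrow(grid$size_grid)),
                       hi = seq_len(nrow(grid$heterogeneity_grid)),
                       setting = grid$settings)
  raws <- list(); summaries <- list()
  for (ci in seq_len(nrow(cells))) {
    setting <- cells$setting[ci]
    sz <- grid$size_grid[cells$si[ci], ]
    het <- grid$heterogeneity_grid[cells$hi[ci], ]
    res <- run_cell(setting, sz$n_studies, sz$mean_size,
                    het$i2_intercept, het$i2_exposure,
                    models = grid$models,
                    n_iterations = grid$n_iterations,
                    master_seed = grid$master_seed, cell_index = ci)
    raws[[ci]] <- res$raw
    summaries[[ci]] <- res$summary
    if (progress)
      message(sprintf("cell %d/%d: setting %d, k=%d, n=%d, I2=(%.2f,%.2f), %d/%d fits converged",
                      ci, nrow(cells), setting, sz$n_studies, sz$mean_size,
                      het$i2_intercept, het$i2_exposure,
                      sum(res$raw$converged), nrow(res$raw)))
  }
  raw <- do.call(rbind, raws)
  summary <- do.call(rbind, summaries)
  convergence <- summary[, c("setting", "total_n", "k", "i2_int", "i2_exp",
                             "model", "n_iterations_total", "n_converged",
                             "convergence_rate")]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(raw, file.path(out_dir, "raw.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(convergence, file.path(out_dir, "convergence.csv"),
                     row.names = FALSE)
  }
  list(raw = raw, summary = summary, convergence = convergence)
}
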