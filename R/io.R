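#' Read a run table from CSV
#'
#' The run-table schema is one row per experimental run:
#' `run_id, mixture_no, yeast_pct, cornflour_pct, corncob_pct, n_larvae,
#' pupation, duration_days, pupal_weight_mg, emergence,
#' excluded_responses`.  Empty cells are missing values (never zero);
#' `excluded_responses` is a semicolon-separated list of response names
#' (or `all`) that a run should be ignored for.
#'
#' @param path CSV file path.
#' @param space a [mixture_space()] used to validate blends.
#' @return A validated run table data frame.
#' @export
read_run_table <- function(path, space = ludens_space()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  need <- c("run_id", "yeast_pct", "cornflour_pct", "corncob_pct")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("run table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(raw$run_id))
    stop("run_id values must be unique", call. = FALSE)
  for (col in c("mixture_no", "n_larvae"))
    if (!col %in% names(raw)) raw[[col]] <- NA_integer_
  for (col in c("pupation", "duration_days", "pupal_weight_mg", "emergence"))
    if (!col %in% names(raw)) raw[[col]] <- NA_real_
  if (!"excluded_responses" %in% names(raw)) raw$excluded_responses <- ""
  raw$excluded_responses[is.na(raw$excluded_responses)] <- ""

  validate_blend(run_blends(raw), space)
  for (col in c("pupation", "emergence")) {
    bad <- which(raw[[col]] < 0 | raw[[col]] > 1)
    if (length(bad))
      stop(sprintf("%s outside [0, 1] for run_id %s", col,
                   raw$run_id[bad[1L]]), call. = FALSE)
  }
  for (col in c("duration_days", "pupal_weight_mg")) {
    bad <- which(raw[[col]] <= 0)
    if (length(bad))
      stop(sprintf("%s must be positive (run_id %s)", col,
                   raw$run_id[bad[1L]]), call. = FALSE)
  }
  raw
}

#' Write a run table to CSV
#'
#' @param runs run table data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_run_table <- function(runs, path) {
  utils::write.csv(runs, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize a fitted Scheffe model to JSON
#'
#' Captures everything needed to reconstruct the fitted surface and its
#' published-style summary: term set, coefficients and intervals, the
#' statistic family, transform and excluded runs.
#'
#' @param fit a [scheffe_fit()] or [scheffe_surface()].
#' @return A JSON string (class `json`).
#' @export
fit_to_json <- function(fit) {
  core <- list(response = fit$response, transform = fit$transform,
               model = fit$termset$label,
               terms = term_labels(fit$termset),
               coefficients = as.list(fit$coefficients))
  if (inherits(fit, "scheffe_fit")) {
    core <- c(core, list(
      ci_low = as.list(fit$ci[, "low"]), ci_high = as.list(fit$ci[, "high"]),
      sigma = fit$sigma, df_model = fit$df_model,
      df_residual = fit$df_residual, n = fit$n,
      r2 = fit$r2, r2_adj = fit$r2_adj, r2_pred = fit$r2_pred,
      press = fit$press, adequate_precision = fit$adequate_precision,
      lack_of_fit = fit$lack_of_fit,
      excluded_runs = fit$excluded_runs))
  }
  jsonlite::toJSON(core, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Reconstruct a predictable surface from serialized JSON
#'
#' @param json a JSON string from [fit_to_json()].
#' @param space the [mixture_space()] of the original fit.
#' @return A [scheffe_surface()].
#' @export
surface_from_json <- function(json, space = ludens_space()) {
  obj <- jsonlite::fromJSON(json)
  parent <- sub("^reduced:", "", obj$model)
  scheffe_surface(unlist(obj$coefficients), parent, space,
                  response = obj$response, transform = obj$transform)
}

#' Pipeline configuration
#'
#' @param space design space.
#' @param responses responses to model.
#' @param alpha significance level for selection and elimination.
#' @param exclusion_cap max excluded runs per response.
#' @param diagnostics_thresholds see [residual_diagnostics()].
#' @param costspec a [cost_spec()]; default derives prices from the
#'   packaged cost anchors.
#' @param step optimization lattice step (percentage points).
#' @param criteria_overrides optional named limit overrides.
#' @param seed integer seed recorded with the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(space = ludens_space(),
                            responses = c("pupation", "duration",
                                          "pupal_weight", "emergence"),
                            alpha = 0.05, exclusion_cap = 1L,
                            diagnostics_thresholds = NULL,
                            costspec = solve_unit_prices(),
                            step = 0.01, criteria_overrides = NULL,
                            seed = 1L) {
  structure(list(space = space, responses = responses, alpha = alpha,
                 exclusion_cap = exclusion_cap,
                 diagnostics_thresholds = diagnostics_thresholds,
                 costspec = costspec, step = step,
                 criteria_overrides = criteria_overrides, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a run table
#'
#' For each response: sequential model selection over the Scheffe ladder,
#' the outlier-exclusion workflow on the chosen parent order, and
#' hierarchical backward elimination.  The final fits then define the
#' reference-CI acceptance criteria, the response and cost surfaces are
#' evaluated on the optimization lattice, and the area of operability and
#' maximum-savings blend are extracted.  Deterministic given
#' (config, data, seed).
#'
#' @param runs run table data frame.
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_result`: `selection` and `fits` per
#'   response, `diagnostics` trails, `criteria`, `grid`, `region` and
#'   `savings`.
#' @export
run_pipeline <- function(runs, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!nrow(runs)) stop("empty run table", call. = FALSE)
  selection <- list(); fits <- list(); diagnostics <- list()
  for (resp in config$responses) {
    sel <- sequential_selection(runs, resp, config$space,
                                alpha = config$alpha)
    wf <- exclusion_workflow(
      runs, resp, sel$fit$termset, config$space,
      transform = default_transform(resp),
      thresholds = config$diagnostics_thresholds,
      cap = config$exclusion_cap, alpha = config$alpha)
    selection[[resp]] <- sel
    fits[[resp]] <- wf$fit
    diagnostics[[resp]] <- wf[c("excluded", "trail")]
  }
  criteria <- criteria_from_reference(
    fits, config$costspec$reference_blend,
    overrides = config$criteria_overrides)
  grid <- evaluate_grid(fits, config$costspec, config$space, config$step)
  region <- operability_region(grid, criteria)
  savings <- if (region$empty) NULL
             else max_savings_report(region, config$costspec)
  structure(list(selection = selection, fits = fits,
                 diagnostics = diagnostics, criteria = criteria,
                 grid = grid, region = region, savings = savings,
                 config = config),
            class = "pipeline_result")
}

#' Reproduce the study's optimization from its published models
#'
#' Builds the four response surfaces directly from the packaged published
#' coefficient sets, derives ingredient prices from the published cost
#' anchors, applies the study's acceptance criteria, and runs the grid
#' optimizer.  This is the no-raw-data path: it needs nothing beyond what
#' the package ships.
#'
#' @param step optimization lattice step (percentage points).
#' @param output_dir optional directory; when given, the optimization
#'   report (JSON) and the feasible grid (CSV) are written there.
#' @return A list: `surfaces`, `costspec`, `criteria`, `grid`, `region`,
#'   `savings`, and a `comparison` data frame of headline quantities.
#' @examples
#' \donttest{
#' rep <- reproduce_study(step = 0.05)
#' rep$comparison
#' }
#' @export
reproduce_study <- function(step = 0.01, output_dir = NULL) {
  surfaces <- ludens_surfaces()
  costspec <- solve_unit_prices()
  criteria <- ludens_criteria()
  grid <- evaluate_grid(surfaces, costspec, ludens_space(), step)
  region <- operability_region(grid, criteria)
  savings <- max_savings_report(region, costspec)
  comparison <- data.frame(
    quantity = c("limit_pupation", "limit_duration_days",
                 "limit_pupal_weight_mg", "limit_emergence",
                 "min_yeast_pct", "max_cornflour_pct", "max_corncob_pct",
                 "max_savings_percent", "max_savings_annual_usd",
                 "max_savings_per_ton_usd"),
    value = c(criteria$pupation$limit, criteria$duration$limit,
              criteria$pupal_weight$limit, criteria$emergence$limit,
              region$ranges["yeast_pct", "min"],
              region$ranges["cornflour_pct", "max"],
              region$ranges["corncob_pct", "max"],
              savings$savings_percent, savings$savings_annual,
              savings$savings_per_ton))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(criteria = unclass(criteria),
           ranges = as.data.frame(region$ranges),
           argmax = region$argmax, savings = savings,
           comparison = comparison),
      file.path(output_dir, "optimization_report.json"),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(region$feasible,
                     file.path(output_dir, "operability_grid.csv"),
                     row.names = FALSE)
  }
  list(surfaces = surfaces, costspec = costspec, criteria = criteria,
       grid = grid, region = region, savings = savings,
       comparison = comparison)
}
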