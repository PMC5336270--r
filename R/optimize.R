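#' Multi-response overlay optimization on the mixture simplex
#'
#' The optimizer formalizes graphical overlay optimization: each fitted
#' response surface contributes a one-sided acceptance criterion, the
#' criteria are intersected on a fine lattice of candidate blends, and the
#' cheapest acceptable blend is reported together with the bounding ranges
#' of the acceptable region (the "area of operability").
#'
#' @name optimize-overlay
NULL

new_criteria_set <- function(criteria) {
  for (cr in criteria)
    stopifnot(cr$bound %in% c("min", "max"),
              is.numeric(cr$limit), !is.na(cr$limit))
  structure(criteria, class = "criteria_set")
}

#' @export
print.criteria_set <- function(x, ...) {
  cat("Optimization criteria:\n")
  for (nm in names(x))
    cat(sprintf("  %-13s %s %.4g  (%s)\n", nm,
                if (x[[nm]]$bound == "min") ">=" else "<=",
                x[[nm]]$limit, x[[nm]]$source))
  invisible(x)
}

response_direction <- c(pupation = "min", duration = "max",
                        pupal_weight = "min", emergence = "min")

#' Build acceptance criteria from predictions at the reference blend
#'
#' Each response must stay within the 95% confidence interval predicted
#' for the reference (standard) blend: responses that should stay high
#' (pupation, pupal weight, emergence) get the lower interval endpoint as
#' a minimum limit; larval duration, which should stay low, gets the upper
#' endpoint as a maximum limit.  Limits are on the original response
#' scale (transformed fits are back-transformed first).
#'
#' @param fits named list of [scheffe_fit()] objects (names are response
#'   names).
#' @param reference_blend the standard blend.
#' @param level confidence level of the prediction interval.
#' @param overrides optional named list `response = limit` replacing the
#'   derived limit for selected responses.
#' @return A `criteria_set`.
#' @export
criteria_from_reference <- function(fits, reference_blend, level = 0.95,
                                    overrides = NULL) {
  criteria <- list()
  for (nm in names(fits)) {
    dir <- response_direction[[nm]]
    if (is.null(dir))
      stop("no optimization direction known for response '", nm, "'",
           call. = FALSE)
    pr <- predict(fits[[nm]], reference_blend, interval = "confidence",
                  level = level)
    limit <- if (dir == "min") pr$lwr else pr$upr
    criteria[[nm]] <- list(bound = dir, limit = limit,
                           source = "reference-CI")
  }
  for (nm in names(overrides)) {
    dir <- response_direction[[nm]]
    criteria[[nm]] <- list(bound = dir, limit = overrides[[nm]],
                           source = "user")
  }
  new_criteria_set(criteria)
}

#' Evaluate response surfaces and cost over a simplex lattice
#'
#' Enumerates candidate blends on a regular lattice inside the design
#' space (exact integer arithmetic, so every blend sums to the mixture
#' total exactly) and attaches each surface's prediction on the original
#' response scale plus the cost and savings surfaces.
#'
#' @param fits named list of [scheffe_fit()] or [scheffe_surface()]
#'   objects.
#' @param costspec a [cost_spec()].
#' @param space a [mixture_space()].
#' @param step lattice step in percentage points (default 0.01).
#' @return A data frame: blend columns, one `pred_<response>` column per
#'   surface, `cost_per_ton`, `savings_percent`, `savings_annual`.
#' @export
evaluate_grid <- function(fits, costspec, space = ludens_space(),
                          step = 0.01) {
  grid <- simplex_grid(space, step)
  out <- as.data.frame(grid)
  for (nm in names(fits)) {
    pred <- predict(fits[[nm]], grid)
    # fitted models return a data frame; coefficient-only surfaces a vector
    out[[paste0("pred_", nm)]] <- if (is.data.frame(pred)) pred$fit else pred
  }
  out$cost_per_ton <- blend_cost_per_ton(grid, costspec)
  sav <- savings_vs_reference(grid, costspec)
  out$savings_percent <- sav$savings_percent
  out$savings_annual <- sav$savings_annual
  out
}

#' Area of operability of an annotated grid
#'
#' Intersects all acceptance criteria over the lattice, reports the
#' per-component bounding ranges of the acceptable region, and locates the
#' maximum-savings blend (ties broken deterministically: lowest yeast,
#' then highest corn flour).
#'
#' @param grid an annotated grid from [evaluate_grid()].
#' @param criteria a `criteria_set`.
#' @return An object of class `operability_result`: the feasible subset of
#'   the grid, per-component `ranges` (rounded to 2 decimals), the
#'   `argmax` row, `empty` flag, per-criterion feasibility counts and the
#'   binding constraint at the argmax.
#' @export
operability_region <- function(grid, criteria) {
  masks <- feasibility_masks(grid, criteria)
  feasible <- Reduce(`&`, masks)
  if (!any(feasible)) {
    return(structure(list(feasible = grid[0, ], ranges = NULL,
                          argmax = NULL, empty = TRUE,
                          mask_counts = vapply(masks, sum, 0L),
                          criteria = criteria),
                     class = "operability_result"))
  }
  feas <- grid[feasible, , drop = FALSE]
  comps <- grep("_pct$", names(feas), value = TRUE)
  ranges <- t(vapply(comps, function(cn) round(range(feas[[cn]]), 2L),
                     numeric(2L)))
  colnames(ranges) <- c("min", "max")
  ord <- order(-feas$savings_percent, feas[[comps[1L]]],
               -feas[[comps[2L]]])
  argmax <- feas[ord[1L], , drop = FALSE]
  binding <- binding_constraints(argmax, criteria)
  structure(list(feasible = feas, ranges = ranges, argmax = argmax,
                 empty = FALSE, mask_counts = vapply(masks, sum, 0L),
                 binding = binding, criteria = criteria),
            class = "operability_result")
}

feasibility_masks <- function(grid, criteria) {
  masks <- list()
  for (nm in names(criteria)) {
    col <- paste0("pred_", nm)
    if (!col %in% names(grid))
      stop("grid lacks predictions for criterion response '", nm, "'",
           call. = FALSE)
    cr <- criteria[[nm]]
    masks[[nm]] <- if (cr$bound == "min") grid[[col]] >= cr$limit
                   else grid[[col]] <= cr$limit
  }
  masks
}

# Constraints within half a percent of their limit at a blend row.
binding_constraints <- function(row, criteria, rtol = 0.005) {
  nm <- names(criteria)
  active <- vapply(nm, function(r) {
    cr <- criteria[[r]]
    abs(row[[paste0("pred_", r)]] - cr$limit) <=
      rtol * max(abs(cr$limit), 1)
  }, logical(1L))
  nm[active]
}

#' @export
print.operability_result <- function(x, ...) {
  if (x$empty) {
    cat("Operability region is EMPTY under the given criteria\n")
    return(invisible(x))
  }
  cat("Area of operability:", nrow(x$feasible), "lattice blends\n")
  print(x$ranges)
  cat(sprintf("max savings %.2f%% (%.2f/yr) at blend (%s)\n",
              x$argmax$savings_percent, x$argmax$savings_annual,
              paste(sprintf("%.2f", unlist(
                x$argmax[grep("_pct$", names(x$argmax))])),
                collapse = ", ")))
  if (length(x$binding))
    cat("binding constraints:", paste(x$binding, collapse = ", "), "\n")
  invisible(x)
}

#' Savings report at the optimum of an operability region
#'
#' @param result an `operability_result` from [operability_region()].
#' @param costspec the [cost_spec()] used to build the grid.
#' @return A list: `blend`, `savings_percent`, `savings_annual`,
#'   `savings_per_ton`, and the predicted responses at the optimum.
#' @export
max_savings_report <- function(result, costspec) {
  if (result$empty)
    stop("operability region is empty: no optimum to report", call. = FALSE)
  row <- result$argmax
  comps <- grep("_pct$", names(row), value = TRUE)
  preds <- unlist(row[grep("^pred_", names(row))])
  names(preds) <- sub("^pred_", "", names(preds))
  list(blend = unlist(row[comps]),
       savings_percent = row$savings_percent,
       savings_annual = row$savings_annual,
       savings_per_ton = row$savings_annual / costspec$annual_tonnage,
       predicted_responses = preds)
}

#' Overlay dataset for plotting the operability region
#'
#' Per-response feasibility masks over the grid plus the combined mask and
#' the optimum marker, in a single long-format data frame suitable for
#' contour/ternary plotting.
#'
#' @param grid an annotated grid from [evaluate_grid()].
#' @param criteria a `criteria_set`.
#' @param result optional `operability_result` (recomputed if omitted).
#' @return A list with `masks` (data frame of logical columns per response
#'   plus `all`), the `grid`, the `criteria` and the `argmax` row.
#' @export
overlay_export <- function(grid, criteria, result = NULL) {
  masks <- feasibility_masks(grid, criteria)
  md <- as.data.frame(masks)
  md$all <- Reduce(`&`, masks)
  if (is.null(result)) result <- operability_region(grid, criteria)
  list(masks = md, grid = grid, criteria = criteria,
       argmax = if (result$empty) NULL else result$argmax)
}
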