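#' Ingredient cost specification
#'
#' Holds the per-kilogram prices of the three variable mixture components,
#' the annual production tonnage of finished diet, and the reference
#' (standard) blend that savings are measured against.  Only the variable
#' mixture is costed; the fixed remainder of the diet cancels out of every
#' cost comparison.
#'
#' @param unit_prices numeric length-3, currency per kg of each component
#'   (component order of the space: yeast, corn flour, corncob).
#' @param annual_tonnage tons of finished diet produced per year.
#' @param reference_blend the standard blend (percent of whole diet).
#' @param space a [mixture_space()] used to validate the reference blend.
#' @param currency currency label for reporting.
#' @return An object of class `cost_spec`.
#' @export
cost_spec <- function(unit_prices, annual_tonnage, reference_blend,
                      space = ludens_space(), currency = "USD") {
  stopifnot(length(unit_prices) == 3L, annual_tonnage > 0)
  if (any(unit_prices < 0))
    stop("unit prices must be non-negative", call. = FALSE)
  validate_blend(reference_blend, space)
  structure(
    list(unit_prices = as.numeric(unit_prices),
         annual_tonnage = as.numeric(annual_tonnage),
         reference_blend = as.numeric(reference_blend),
         space = space, currency = currency),
    class = "cost_spec")
}

#' @export
print.cost_spec <- function(x, ...) {
  cat("Cost spec:", paste(sprintf("%s %.4g/kg", x$space$components,
                                  x$unit_prices), collapse = ", "),
      sprintf("; %.2f t/yr (%s)\n", x$annual_tonnage, x$currency))
  invisible(x)
}

#' Ingredient cost of a blend per ton of finished diet
#'
#' A ton of finished diet contains `10 * x_i` kg of component i when `x_i`
#' is its percent of the whole diet, so
#' `cost = 1000 * sum(x_i / 100 * price_i)`.  Linear (affine) in the blend
#' proportions.
#'
#' @param blend numeric length-3 vector or n x 3 matrix of blends
#'   (percent of whole diet).
#' @param spec a [cost_spec()].
#' @return Numeric cost(s) per ton of finished diet.
#' @export
blend_cost_per_ton <- function(blend, spec) {
  stopifnot(inherits(spec, "cost_spec"))
  x <- validate_blend(blend, spec$space)
  drop(10 * x %*% spec$unit_prices)
}

#' Savings of a blend relative to the reference blend
#'
#' @param blend numeric length-3 vector or n x 3 matrix.
#' @param spec a [cost_spec()].
#' @return A data frame with `savings_percent` (of the reference mixture
#'   cost) and `savings_annual` (currency per year at the spec's tonnage).
#' @export
savings_vs_reference <- function(blend, spec) {
  stopifnot(inherits(spec, "cost_spec"))
  ref <- blend_cost_per_ton(spec$reference_blend, spec)
  if (ref <= 0) stop("reference blend cost is zero", call. = FALSE)
  cost <- blend_cost_per_ton(blend, spec)
  data.frame(savings_percent = 100 * (ref - cost) / ref,
             savings_annual = (ref - cost) * spec$annual_tonnage)
}

#' Recover unit prices from published cost anchors
#'
#' When per-kg ingredient prices are not available directly, three
#' independent published cost figures determine them: here, the annual
#' cost of the reference blend, the annual cost of a second blend, and the
#' percent saving of a third.  The three anchor blends must be affinely
#' independent (they span the mixture plane), giving a nonsingular 3x3
#' linear system in the prices.
#'
#' @param anchors a list shaped like [ludens_cost_anchors()]: elements
#'   `reference` and `alt` with `blend` and `annual_cost`, `third` with
#'   `blend` and `savings_percent`, and `annual_tonnage`.
#' @param space a [mixture_space()].
#' @param currency currency label.
#' @return A [cost_spec()] whose `unit_prices` reproduce all three anchors.
#' @examples
#' spec <- solve_unit_prices(ludens_cost_anchors())
#' round(spec$unit_prices, 3)
#' @export
solve_unit_prices <- function(anchors = ludens_cost_anchors(),
                              space = ludens_space(), currency = "USD") {
  tonnage <- anchors$annual_tonnage
  b_ref <- validate_blend(anchors$reference$blend, space)
  b_alt <- validate_blend(anchors$alt$blend, space)
  b_third <- validate_blend(anchors$third$blend, space)
  cost_ref <- anchors$reference$annual_cost / tonnage
  cost_alt <- anchors$alt$annual_cost / tonnage
  cost_third <- cost_ref * (1 - anchors$third$savings_percent / 100)
  M <- 10 * rbind(b_ref, b_alt, b_third)
  if (abs(det(M)) < 1e-8 * max(abs(M))^3)
    stop("anchor blends are affinely dependent: price system is singular",
         call. = FALSE)
  prices <- solve(M, c(cost_ref, cost_alt, cost_third))
  spec <- cost_spec(prices, tonnage, drop(b_ref), space, currency)
  resid <- max(abs(drop(M %*% prices) - c(cost_ref, cost_alt, cost_third)))
  if (resid > 1e-9 * cost_ref)
    stop("anchor system residual unexpectedly large", call. = FALSE)
  spec
}

#' Cost and savings over a simplex grid
#'
#' Evaluates the linear cost surface on a regular lattice of blends inside
#' the design space.
#'
#' @param spec a [cost_spec()].
#' @param space a [mixture_space()].
#' @param step lattice step in percentage points of the whole diet.
#' @return A data frame with the blend columns, `cost_per_ton`,
#'   `savings_percent` and `savings_annual`.
#' @export
cost_surface <- function(spec, space = spec$space, step = 0.01) {
  grid <- simplex_grid(space, step)
  cost <- blend_cost_per_ton(grid, spec)
  sav <- savings_vs_reference(grid, spec)
  data.frame(grid, cost_per_ton = cost, sav)
}

# Regular lattice of blends inside a constrained mixture space.  The first
# two components run over their bounds in integer multiples of `step`
# (computed on an integer scale so grid points are exact), the third is
# the simplex complement; only points inside all bounds are kept.
simplex_grid <- function(space, step = 0.01) {
  stopifnot(step > 0)
  # integer arithmetic at 1e-4 resolution keeps lattice blends exact
  scale <- 10000L
  inc <- round(step * scale)
  if (abs(inc - step * scale) > 1e-6 || inc < 1L)
    stop("step must be a multiple of 0.0001 percentage points",
         call. = FALSE)
  lo <- round(space$lower * scale)
  hi <- round(space$upper * scale)
  tot <- round(space$mixture_total * scale)
  a <- seq.int(lo[1L], hi[1L], by = inc)
  b <- seq.int(lo[2L], hi[2L], by = inc)
  g <- expand.grid(a = a, b = b, KEEP.OUT.ATTRS = FALSE)
  cc <- tot - g$a - g$b
  keep <- cc >= lo[3L] & cc <= hi[3L]
  out <- cbind(g$a[keep], g$b[keep], cc[keep]) / scale
  colnames(out) <- paste0(space$components, "_pct")
  out
}
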