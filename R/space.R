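#' Constrained three-component mixture design space
#'
#' A mixture space describes the region of blend proportions that the
#' variable part of a diet may occupy.  Each of the three components has a
#' lower and upper bound (in percent of the whole diet) and the three
#' proportions always sum to a fixed `mixture_total`.  The remainder of the
#' diet (water, sugar, preservatives, ...) is held constant and is described
#' only informally via `fixed_fraction`.
#'
#' @param lower,upper numeric length-3 bounds, percent of whole diet.
#' @param mixture_total percent of the whole diet occupied by the variable
#'   mixture.
#' @param components character length-3 component labels.
#' @param fixed_fraction optional named numeric describing the constant part
#'   of the diet (purely descriptive; it is not used in any computation).
#'
#' @return An object of class `mixture_space`.
#' @examples
#' sp <- mixture_space(lower = c(3, 5.3, 19), upper = c(6, 8.3, 22),
#'                     mixture_total = 30.3)
#' space_corners(sp)
#' @export
mixture_space <- function(lower, upper, mixture_total,
                          components = c("yeast", "cornflour", "corncob"),
                          fixed_fraction = NULL) {
  stopifnot(length(lower) == 3L, length(upper) == 3L,
            length(components) == 3L, is.numeric(mixture_total))
  if (any(lower <= 0) || any(upper <= 0))
    stop("all bounds must be positive", call. = FALSE)
  if (any(upper < lower))
    stop("upper bounds must not be below lower bounds", call. = FALSE)
  if (!(sum(lower) < mixture_total && mixture_total < sum(upper)))
    stop("mixture_total must lie strictly between sum(lower) and sum(upper)",
         call. = FALSE)
  range_total <- mixture_total - sum(lower)
  if (any(upper - lower > range_total + 1e-9))
    stop("component ranges may not exceed mixture_total - sum(lower)",
         call. = FALSE)
  structure(
    list(components = as.character(components),
         lower = as.numeric(lower), upper = as.numeric(upper),
         mixture_total = as.numeric(mixture_total),
         range_total = range_total,
         fixed_fraction = fixed_fraction),
    class = "mixture_space")
}

#' @export
print.mixture_space <- function(x, ...) {
  cat("Constrained mixture space (", x$mixture_total, "% of whole diet)\n",
      sep = "")
  for (i in seq_len(3L))
    cat(sprintf("  %-10s %5.2f .. %5.2f %%\n",
                x$components[i], x$lower[i], x$upper[i]))
  invisible(x)
}

#' Corner blends of a mixture space
#'
#' The three blends obtained by pushing one component to the top of its
#' feasible range while the other two sit at their lower bounds.  Under
#' pseudo-component coding these map to the unit vectors of the simplex.
#'
#' @param space a [mixture_space()].
#' @return A 3 x 3 matrix, one corner blend per row.
#' @export
space_corners <- function(space) {
  stopifnot(inherits(space, "mixture_space"))
  z <- diag(3)
  from_pseudo(z, space)
}

as_blend_matrix <- function(blend) {
  if (is.data.frame(blend)) blend <- as.matrix(blend)
  if (is.null(dim(blend))) blend <- matrix(blend, nrow = 1L)
  storage.mode(blend) <- "double"
  if (ncol(blend) != 3L)
    stop("a blend must have exactly 3 component proportions", call. = FALSE)
  blend
}

#' Validate blends against a mixture space
#'
#' Checks that each blend sums to the space's `mixture_total` and that every
#' component proportion respects its bounds.  Proportions are percent of the
#' whole diet.
#'
#' @param blend numeric length-3 vector or an n x 3 matrix of blends.
#' @param space a [mixture_space()].
#' @param tol tolerance on the mixture-total sum check.
#' @return The blend(s), invisibly unchanged, as a matrix.
#' @export
validate_blend <- function(blend, space, tol = 1e-9) {
  stopifnot(inherits(space, "mixture_space"))
  x <- as_blend_matrix(blend)
  bad_sum <- abs(rowSums(x) - space$mixture_total) > tol
  if (any(bad_sum))
    stop(sprintf("blend sum %.6g does not equal the mixture total %.6g",
                 rowSums(x)[which(bad_sum)[1L]], space$mixture_total),
         call. = FALSE)
  for (i in seq_len(3L)) {
    off <- x[, i] < space$lower[i] - tol | x[, i] > space$upper[i] + tol
    if (any(off))
      stop(sprintf("component '%s' value %.6g outside bounds [%g, %g]",
                   space$components[i], x[which(off)[1L], i],
                   space$lower[i], space$upper[i]),
           call. = FALSE)
  }
  invisible(x)
}

#' Pseudo-component coding
#'
#' Maps real blend proportions onto the unit simplex by
#' `z_i = (x_i - L_i) / (T - sum(L))` where `L` are the lower bounds and `T`
#' the mixture total (L-pseudocomponent coding).  The three corner blends of
#' the space map to the unit vectors, so linear Scheffe coefficients equal
#' the predicted responses at the corners.
#'
#' @param blend numeric length-3 vector or n x 3 matrix of blends (percent).
#' @param space a [mixture_space()].
#' @return An n x 3 matrix of simplex coordinates.
#' @seealso [from_pseudo()] for the inverse.
#' @export
to_pseudo <- function(blend, space) {
  x <- validate_blend(blend, space)
  z <- sweep(x, 2L, space$lower, "-") / space$range_total
  colnames(z) <- space$components
  z
}

#' Inverse pseudo-component coding
#'
#' @param z numeric length-3 vector or n x 3 matrix of simplex coordinates.
#' @param space a [mixture_space()].
#' @param tol tolerance for the simplex-sum check.
#' @return An n x 3 matrix of blend proportions in percent of whole diet.
#' @export
from_pseudo <- function(z, space, tol = 1e-9) {
  stopifnot(inherits(space, "mixture_space"))
  z <- as_blend_matrix(z)
  if (any(abs(rowSums(z) - 1) > tol))
    stop("pseudo-component coordinates must sum to 1", call. = FALSE)
  if (any(z < -tol))
    stop("pseudo-component coordinates must be non-negative", call. = FALSE)
  x <- sweep(z * space$range_total, 2L, space$lower, "+")
  colnames(x) <- space$components
  x
}

#' Hat-matrix leverages of a run table under a Scheffe term set
#'
#' Computes the diagonal of `H = X (X'X)^{-1} X'` where `X` is the Scheffe
#' design matrix of the runs on the pseudo-component scale.  Used to judge
#' how evenly a design spreads information across its points; the leverages
#' sum to the number of model terms.
#'
#' @param runs a run table (see [read_run_table()] for the schema).
#' @param termset a [scheffe_terms()] term set.
#' @param space a [mixture_space()].
#' @return Numeric vector of leverages, one per run.
#' @export
leverage_profile <- function(runs, termset, space) {
  X <- design_matrix(runs, termset, space)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("term set is aliased (rank-deficient) on this design", call. = FALSE)
  Q <- qr.Q(qx)
  h <- rowSums(Q^2)
  names(h) <- rownames(X)
  h
}
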