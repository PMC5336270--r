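#' Scheffe polynomial term sets for three-component mixtures
#'
#' Builds the canonical (intercept-free) Scheffe model of a given order on
#' the pseudo-component simplex.  The model ladder, from simplest to most
#' complex, is:
#'
#' * `mean` - a single constant term (the null model),
#' * `linear` - A, B, C,
#' * `quadratic` - adds AB, AC, BC,
#' * `special_cubic` - adds ABC,
#' * `cubic` - adds the difference terms AB(A-B), AC(A-C), BC(B-C),
#' * `special_quartic` - quadratic base plus A\eqn{^2}BC, AB\eqn{^2}C, ABC\eqn{^2},
#' * `quartic` - the full degree-4 Scheffe basis (15 terms).
#'
#' Each term is stored as one or more signed monomials in the pseudo
#' coordinates; a difference term such as AB(A-B) expands to
#' A\eqn{^2}B - AB\eqn{^2}.
#'
#' @param order one of `"mean"`, `"linear"`, `"quadratic"`,
#'   `"special_cubic"`, `"cubic"`, `"special_quartic"`, `"quartic"`.
#' @return An object of class `scheffe_terms`: a list of terms, each with a
#'   `label`, an exponent matrix `mono` (one row per monomial) and a `sign`
#'   vector.
#' @examples
#' scheffe_terms("special_quartic")
#' @export
scheffe_terms <- function(order = c("mean", "linear", "quadratic",
                                    "special_cubic", "cubic",
                                    "special_quartic", "quartic")) {
  order <- match.arg(order)
  mono <- function(...) matrix(c(...), ncol = 3L, byrow = TRUE)
  term <- function(label, m, s = rep(1, nrow(m)))
    list(label = label, mono = m, sign = s)

  lin <- list(term("A", mono(1, 0, 0)),
              term("B", mono(0, 1, 0)),
              term("C", mono(0, 0, 1)))
  quad <- list(term("AB", mono(1, 1, 0)),
               term("AC", mono(1, 0, 1)),
               term("BC", mono(0, 1, 1)))
  abc <- list(term("ABC", mono(1, 1, 1)))
  diffs <- list(
    term("AB(A-B)", mono(2, 1, 0, 1, 2, 0), c(1, -1)),
    term("AC(A-C)", mono(2, 0, 1, 1, 0, 2), c(1, -1)),
    term("BC(B-C)", mono(0, 2, 1, 0, 1, 2), c(1, -1)))
  sq <- list(term("A2BC", mono(2, 1, 1)),
             term("AB2C", mono(1, 2, 1)),
             term("ABC2", mono(1, 1, 2)))
  diff2 <- list(
    term("AB(A-B)2", mono(3, 1, 0, 2, 2, 0, 1, 3, 0), c(1, -2, 1)),
    term("AC(A-C)2", mono(3, 0, 1, 2, 0, 2, 1, 0, 3), c(1, -2, 1)),
    term("BC(B-C)2", mono(0, 3, 1, 0, 2, 2, 0, 1, 3), c(1, -2, 1)))

  terms <- switch(order,
    mean            = list(term("(mean)", mono(0, 0, 0))),
    linear          = lin,
    quadratic       = c(lin, quad),
    special_cubic   = c(lin, quad, abc),
    cubic           = c(lin, quad, diffs, abc),
    special_quartic = c(lin, quad, sq),
    quartic         = c(lin, quad, diffs, diff2, sq))
  new_scheffe_terms(order, terms)
}

new_scheffe_terms <- function(label, terms) {
  labels <- vapply(terms, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("duplicate terms in term set", call. = FALSE)
  structure(list(label = label, terms = terms), class = "scheffe_terms")
}

#' @export
print.scheffe_terms <- function(x, ...) {
  cat("Scheffe term set '", x$label, "': ",
      paste(term_labels(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
length.scheffe_terms <- function(x) length(x$terms)

#' Term labels of a Scheffe term set
#' @param termset a [scheffe_terms()] object.
#' @return Character vector of term labels in model order.
#' @export
term_labels <- function(termset) {
  vapply(termset$terms, `[[`, "", "label")
}

#' Restrict a term set to a subset of its terms
#'
#' Used by backward elimination; the result is labelled
#' `"reduced:<parent>"` unless no term was dropped.
#'
#' @param termset a [scheffe_terms()] object.
#' @param keep character vector of term labels to retain.
#' @return A `scheffe_terms` object.
#' @export
subset_terms <- function(termset, keep) {
  labels <- term_labels(termset)
  if (!all(keep %in% labels))
    stop("unknown term label(s): ",
         paste(setdiff(keep, labels), collapse = ", "), call. = FALSE)
  kept <- termset$terms[labels %in% keep]
  label <- if (length(kept) == length(termset$terms)) termset$label
           else paste0("reduced:", sub("^reduced:", "", termset$label))
  new_scheffe_terms(label, kept)
}

# Componentwise maximum exponent of a term (its monomial support envelope).
term_envelope <- function(term) apply(term$mono, 2L, max)

# TRUE if term `inner` is contained in term `outer` under the mixture
# hierarchy: every component power of `inner` fits inside `outer`'s envelope.
term_contained_in <- function(inner, outer) {
  all(term_envelope(inner) <= term_envelope(outer)) &&
    !identical(inner$label, outer$label)
}

# Total polynomial degree of a term.
term_degree <- function(term) max(rowSums(term$mono))

#' Evaluate Scheffe terms on pseudo-component coordinates
#'
#' @param z an n x 3 matrix of simplex coordinates.
#' @param termset a [scheffe_terms()] object.
#' @return An n x p matrix; entry (i, j) is term j evaluated at row i.
#' @export
evaluate_terms <- function(z, termset) {
  z <- as_blend_matrix(z)
  p <- length(termset$terms)
  out <- matrix(0, nrow(z), p,
                dimnames = list(rownames(z), term_labels(termset)))
  for (j in seq_len(p)) {
    tm <- termset$terms[[j]]
    acc <- 0
    for (k in seq_along(tm$sign)) {
      e <- tm$mono[k, ]
      acc <- acc + tm$sign[k] *
        z[, 1L]^e[1L] * z[, 2L]^e[2L] * z[, 3L]^e[3L]
    }
    out[, j] <- acc
  }
  out
}

#' Scheffe design matrix of a run table
#'
#' Converts run blends to pseudo-component coordinates and evaluates every
#' term of the set.  Row names are the run ids.
#'
#' @param runs a run table data frame (blend columns `yeast_pct`,
#'   `cornflour_pct`, `corncob_pct`).
#' @param termset a [scheffe_terms()] object.
#' @param space a [mixture_space()].
#' @return The n x p model matrix.
#' @export
design_matrix <- function(runs, termset, space) {
  z <- to_pseudo(run_blends(runs), space)
  X <- evaluate_terms(z, termset)
  rownames(X) <- runs$run_id
  X
}

run_blends <- function(runs) {
  need <- c("yeast_pct", "cornflour_pct", "corncob_pct")
  if (!all(need %in% names(runs)))
    stop("run table lacks blend columns ",
         paste(setdiff(need, names(runs)), collapse = ", "), call. = FALSE)
  as.matrix(runs[, need])
}
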