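#' @title Scheffe mixture model fitting
#' @description Least-squares fitting of Scheffe polynomial response
#'   surfaces on the pseudo-component scale, with the summary statistics
#'   conventionally used to judge mixture models: sequential (Type I) and
#'   partial (Type III) ANOVA, lack of fit against pure error, PRESS and
#'   predicted R-squared, and adequate precision.
#' @name scheffe_fit
NULL

response_columns <- c(pupation = "pupation",
                      duration = "duration_days",
                      pupal_weight = "pupal_weight_mg",
                      emergence = "emergence")

resolve_response <- function(response, runs) {
  if (response %in% names(response_columns) &&
      response_columns[[response]] %in% names(runs))
    return(response_columns[[response]])
  if (response %in% names(runs)) return(response)
  stop("response '", response, "' not found in run table", call. = FALSE)
}

#' Default modelling transform for a response
#'
#' Adult emergence is modelled on the arcsine square-root scale to
#' stabilize the variance of proportions; all other responses are modelled
#' untransformed.
#'
#' @param response response name.
#' @return `"arcsine_sqrt"` or `"none"`.
#' @export
default_transform <- function(response) {
  if (identical(response, "emergence")) "arcsine_sqrt" else "none"
}

apply_transform <- function(y, transform) {
  switch(transform,
    none = y,
    arcsine_sqrt = {
      if (any(y < 0 | y > 1, na.rm = TRUE))
        stop("arcsine square-root transform requires values in [0, 1]",
             call. = FALSE)
      asin(sqrt(y))
    },
    stop("unknown transform '", transform, "'", call. = FALSE))
}

inverse_transform <- function(eta, transform) {
  switch(transform,
    none = eta,
    arcsine_sqrt = sin(pmin(pmax(eta, 0), pi / 2))^2)
}

#' Back-transform a coefficient for display
#'
#' Coefficients of an arcsine square-root model live on the transformed
#' scale; for display on the proportion scale a signed magnitude
#' convention `sign(b) * sin(min(|b|, pi/2))^2` is used.  This is a
#' reporting convenience only: back-transforming coefficients does not
#' commute with the model sum, so predictions are always formed on the
#' transformed scale and back-transformed afterwards.
#'
#' @param b numeric coefficient(s) on the arcsine square-root scale.
#' @return Numeric of the same length on the proportion scale.
#' @export
back_transform_coef <- function(b) {
  sign(b) * sin(pmin(abs(b), pi / 2))^2
}

#' Construct a response surface from known coefficients
#'
#' Wraps a set of Scheffe coefficients (e.g. published model estimates) as
#' a predictable surface without any attached data.  The term set is the
#' subset of the `parent` model named by `coefficients`.
#'
#' @param coefficients named numeric vector; names are term labels of the
#'   parent model (`A`, `B`, `C`, `AB`, ..., `A2BC`, ...).
#' @param parent parent model order (see [scheffe_terms()]).
#' @param space the [mixture_space()] the pseudo coding refers to.
#' @param response response name (informational).
#' @param transform modelling-scale transform of the coefficients.
#' @param term_ci optional matrix of 95% confidence bounds (rows named by
#'   term, columns low/high) on the original response scale.
#' @return An object of class `scheffe_surface`.
#' @export
scheffe_surface <- function(coefficients, parent, space,
                            response = "response", transform = "none",
                            term_ci = NULL) {
  termset <- subset_terms(scheffe_terms(parent), names(coefficients))
  # preserve the caller's coefficient order via the termset order
  coefficients <- coefficients[term_labels(termset)]
  structure(
    list(response = response, transform = transform, termset = termset,
         space = space, coefficients = coefficients, term_ci = term_ci),
    class = "scheffe_surface")
}

#' @export
print.scheffe_surface <- function(x, ...) {
  cat("Scheffe surface for '", x$response, "' (", x$termset$label,
      if (x$transform != "none") paste0(", ", x$transform), ")\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

pseudo_coords <- function(blend, space, check_bounds = TRUE) {
  x <- as_blend_matrix(blend)
  if (any(abs(rowSums(x) - space$mixture_total) > 1e-6))
    stop("blend proportions must sum to the mixture total ",
         space$mixture_total, call. = FALSE)
  if (check_bounds) {
    out <- sweep(x, 2L, space$lower, "<") | sweep(x, 2L, space$upper, ">")
    if (any(out))
      warning("prediction blend outside the design space (extrapolation)",
              call. = FALSE)
  }
  sweep(x, 2L, space$lower, "-") / space$range_total
}

#' Predict from a coefficient-only Scheffe surface
#'
#' @param object a [scheffe_surface()].
#' @param blends numeric length-3 vector or n x 3 matrix of blend
#'   proportions (percent of whole diet).
#' @param ... unused.
#' @return Numeric vector of predictions on the original response scale.
#' @export
predict.scheffe_surface <- function(object, blends, ...) {
  z <- pseudo_coords(blends, object$space)
  eta <- drop(evaluate_terms(z, object$termset) %*% object$coefficients)
  inverse_transform(eta, object$transform)
}

rows_for_response <- function(runs, response, exclude = NULL) {
  col <- resolve_response(response, runs)
  keep <- !is.na(runs[[col]])
  if ("excluded_responses" %in% names(runs)) {
    marks <- strsplit(ifelse(is.na(runs$excluded_responses), "",
                             runs$excluded_responses), ";")
    hit <- vapply(marks, function(m)
      any(trimws(m) %in% c(response, "all")), logical(1L))
    keep <- keep & !hit
  }
  if (!is.null(exclude)) keep <- keep & !(runs$run_id %in% exclude)
  runs[keep, , drop = FALSE]
}

#' Fit a Scheffe polynomial model to one response of a run table
#'
#' Ordinary least squares on the pseudo-component scale.  Runs with a
#' missing value for the response, runs marked excluded for it, and any
#' run ids passed via `exclude` are dropped from this fit only.
#'
#' The returned object carries the full statistic family: coefficient
#' estimates with 95% confidence intervals (t-based on the residual
#' degrees of freedom), the overall ANOVA (model SS corrected by the mean;
#' `df_model = p - 1` by the mixture-model convention), per-term Type III
#' partial F tests plus the 2-df "linear mixture" test, lack of fit
#' against pure error when replicates exist, PRESS / predicted R-squared,
#' and adequate precision.
#'
#' @param runs run table data frame.
#' @param response one of `"pupation"`, `"duration"`, `"pupal_weight"`,
#'   `"emergence"` (or any numeric column name).
#' @param termset a [scheffe_terms()] term set (or an order name).
#' @param space a [mixture_space()]; defaults to [ludens_space()].
#' @param transform `"none"` or `"arcsine_sqrt"`; default chosen by
#'   [default_transform()].
#' @param exclude run ids to leave out of this fit.
#' @param level confidence level for coefficient intervals.
#' @return An object of classes `scheffe_fit` and `scheffe_surface`.
#' @examples
#' runs <- simulate_runs(ludens_design(seed = 1), ludens_truth(), seed = 2)
#' fit <- scheffe_fit(runs, "pupation", "linear")
#' fit$r2
#' @export
scheffe_fit <- function(runs, response, termset,
                        space = ludens_space(),
                        transform = default_transform(response),
                        exclude = NULL, level = 0.95) {
  if (is.character(termset)) termset <- scheffe_terms(termset)
  stopifnot(inherits(termset, "scheffe_terms"))
  data <- rows_for_response(runs, response, exclude)
  col <- resolve_response(response, data)
  n <- nrow(data)
  p <- length(termset)
  if (n <= 0L) stop("no usable runs for response '", response, "'",
                    call. = FALSE)
  if (n < p) stop("fewer runs (", n, ") than model terms (", p, ")",
                  call. = FALSE)

  X <- design_matrix(data, termset, space)
  qx <- qr(X)
  if (qx$rank < p)
    stop("aliased term set: design matrix is rank-deficient", call. = FALSE)
  y <- apply_transform(data[[col]], transform)
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  df_residual <- n - p
  sigma2 <- if (df_residual > 0L) rss / df_residual else NA_real_
  sigma <- sqrt(sigma2)
  XtXinv <- chol2inv(chol(crossprod(X)))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  hat <- rowSums((X %*% XtXinv) * X)

  ss_total <- sum((y - mean(y))^2)
  ss_model <- ss_total - rss
  df_model <- p - 1L
  r2 <- if (ss_total > 0) 1 - rss / ss_total else NA_real_
  r2_adj <- if (df_residual > 0L && ss_total > 0)
    1 - (rss / df_residual) / (ss_total / (n - 1L)) else NA_real_
  press <- if (all(hat < 1 - 1e-8))
    sum((resid / (1 - hat))^2) else NA_real_
  r2_pred <- if (!is.na(press) && ss_total > 0) 1 - press / ss_total
             else NA_real_

  se <- sqrt(sigma2 * diag(XtXinv))
  tq <- if (df_residual > 0L) stats::qt(1 - (1 - level) / 2, df_residual)
        else NA_real_
  ci <- cbind(low = beta - tq * se, high = beta + tq * se)

  anova_model <- if (df_model > 0L && df_residual > 0L && sigma2 > 0) {
    f <- (ss_model / df_model) / sigma2
    list(F = f, df1 = df_model, df2 = df_residual,
         p = stats::pf(f, df_model, df_residual, lower.tail = FALSE))
  } else NULL

  fit <- structure(
    list(response = response, transform = transform, termset = termset,
         space = space, coefficients = beta, se = se, ci = ci,
         sigma = sigma, df_model = df_model, df_residual = df_residual,
         n = n, X = X, y = y, fitted = fitted, residuals = resid,
         hat = hat, XtXinv = XtXinv, rss = rss, ss_total = ss_total,
         ss_model = ss_model, r2 = r2, r2_adj = r2_adj, press = press,
         r2_pred = r2_pred, anova = anova_model,
         run_id = data$run_id, blends = run_blends(data),
         excluded_runs = exclude, data = data, level = level),
    class = c("scheffe_fit", "scheffe_surface"))
  fit$adequate_precision <- adequate_precision(fit)
  fit$type3 <- type3_anova(fit)
  fit$lack_of_fit <- tryCatch(lack_of_fit(fit), error = function(e) NULL)
  fit
}

#' @export
print.scheffe_fit <- function(x, ...) {
  cat("Scheffe fit: ", x$response, " ~ ", x$termset$label,
      if (x$transform != "none") paste0(" [", x$transform, "]"),
      "  (n = ", x$n, ")\n", sep = "")
  tab <- data.frame(estimate = x$coefficients,
                    low = x$ci[, "low"], high = x$ci[, "high"])
  print(round(tab, 4))
  cat(sprintf("sigma %.4g  R2 %.3f  R2adj %.3f  R2pred %.3f  AdeqPrec %.3f\n",
              x$sigma, x$r2, x$r2_adj, x$r2_pred, x$adequate_precision))
  if (!is.null(x$lack_of_fit))
    cat(sprintf("lack of fit F(%d,%d) = %.3f, p = %.4f\n",
                x$lack_of_fit$df_lof, x$lack_of_fit$df_pe,
                x$lack_of_fit$F, x$lack_of_fit$p))
  invisible(x)
}

refit <- function(fit, termset = fit$termset, exclude = fit$excluded_runs) {
  scheffe_fit(fit$data, fit$response, termset, fit$space, fit$transform,
              exclude = exclude, level = fit$level)
}

# Type III partial F tests: each term against the model with that single
# column removed; linear terms are tested jointly as the "linear mixture"
# (their span minus the implicit intercept, 2 df on the simplex).
type3_anova <- function(fit) {
  if (fit$df_residual <= 0L || is.na(fit$sigma) || fit$sigma == 0)
    return(NULL)
  labels <- term_labels(fit$termset)
  sigma2 <- fit$sigma^2
  rows <- list()
  linear <- labels %in% c("A", "B", "C")
  if (sum(linear) == 3L && length(labels) >= 3L) {
    Xr <- cbind(`(mean)` = 1, fit$X[, !linear, drop = FALSE])
    rss_r <- sum(stats::lsfit(Xr, fit$y, intercept = FALSE)$residuals^2)
    f <- ((rss_r - fit$rss) / 2) / sigma2
    rows[["Linear mixture"]] <- data.frame(
      term = "Linear mixture", df = 2L, F = f,
      p = stats::pf(f, 2L, fit$df_residual, lower.tail = FALSE))
  }
  for (j in which(!linear & labels != "(mean)")) {
    Xr <- fit$X[, -j, drop = FALSE]
    rss_r <- sum(stats::lsfit(Xr, fit$y, intercept = FALSE)$residuals^2)
    f <- (rss_r - fit$rss) / sigma2
    rows[[labels[j]]] <- data.frame(
      term = labels[j], df = 1L, F = f,
      p = stats::pf(f, 1L, fit$df_residual, lower.tail = FALSE))
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

blend_group_key <- function(blends) {
  apply(round(blends, 4L), 1L, paste, collapse = "/")
}

#' Lack-of-fit test of a Scheffe fit
#'
#' Pools pure-error sums of squares within groups of runs sharing an
#' identical blend (proportions matched to 4 decimals) and contrasts the
#' remaining residual variation against it:
#' `F = (SS_lof / df_lof) / (SS_pe / df_pe)` with
#' `df_lof = #distinct blends - #terms` and `df_pe = n - #distinct blends`.
#'
#' @param fit a [scheffe_fit()].
#' @return A list with `F`, `df_lof`, `df_pe`, `p`, `ss_lof`, `ss_pe`.
#' @export
lack_of_fit <- function(fit) {
  stopifnot(inherits(fit, "scheffe_fit"))
  key <- blend_group_key(fit$blends)
  groups <- split(fit$y, key)
  df_pe <- fit$n - length(groups)
  if (df_pe <= 0L)
    stop("no replicate blends: pure error is not estimable", call. = FALSE)
  ss_pe <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  ss_lof <- max(fit$rss - ss_pe, 0)
  df_lof <- length(groups) - length(fit$termset)
  if (df_lof <= 0L)
    stop("model saturates the distinct blends: no lack-of-fit df",
         call. = FALSE)
  ms_pe <- ss_pe / df_pe
  f <- if (ms_pe > 0) (ss_lof / df_lof) / ms_pe
       else if (ss_lof <= 1e-12) 0 else Inf
  p <- if (is.finite(f)) stats::pf(f, df_lof, df_pe, lower.tail = FALSE)
       else 0
  list(F = f, df_lof = df_lof, df_pe = df_pe, p = p,
       ss_lof = ss_lof, ss_pe = ss_pe)
}

#' PRESS and predicted R-squared
#'
#' The predicted residual sum of squares via the hat-matrix identity
#' `PRESS = sum((e_i / (1 - h_ii))^2)`, algebraically equal to refitting
#' without each run in turn, and `R2_pred = 1 - PRESS / SS_total`.
#'
#' @param fit a [scheffe_fit()].
#' @return A list with `press` and `r2_pred`.
#' @export
press_stats <- function(fit) {
  stopifnot(inherits(fit, "scheffe_fit"))
  if (any(fit$hat >= 1 - 1e-8))
    stop("a run with leverage 1 cannot be cross-validated", call. = FALSE)
  press <- sum((fit$residuals / (1 - fit$hat))^2)
  list(press = press,
       r2_pred = if (fit$ss_total > 0) 1 - press / fit$ss_total else NA_real_)
}

#' Adequate precision of a fit
#'
#' Signal-to-noise ratio comparing the range of fitted values at the
#' design points to the average prediction variance:
#' `AP = (max(yhat) - min(yhat)) / sqrt(p * sigma^2 / n)`.  Values above 4
#' are conventionally taken to indicate a model usable for prediction.
#'
#' @param fit a [scheffe_fit()].
#' @return A single number (possibly `Inf` for an exact fit).
#' @export
adequate_precision <- function(fit) {
  stopifnot(inherits(fit, "scheffe_fit"))
  spread <- diff(range(fit$fitted))
  scale0 <- 1e-10 * max(abs(fit$fitted), 1)
  if (spread <= scale0) return(0)
  sigma2 <- if (is.na(fit$sigma)) 0 else fit$sigma^2
  denom <- sqrt(length(fit$termset) * sigma2 / fit$n)
  if (denom == 0) Inf else spread / denom
}

#' Predict from a fitted Scheffe model
#'
#' Predictions (and pointwise confidence intervals) at new blends, on the
#' original response scale.  For an arcsine square-root model the linear
#' predictor and interval endpoints are back-transformed through
#' `sin(.)^2` after clamping to `[0, pi/2]`.  Blends outside the design
#' space trigger an extrapolation warning, not an error.
#'
#' @param object a [scheffe_fit()].
#' @param blends numeric length-3 vector or n x 3 matrix (percent of
#'   whole diet).
#' @param interval `"confidence"` or `"none"`.
#' @param level confidence level.
#' @param ... unused.
#' @return A data frame with columns `fit` and, when requested, `lwr`,
#'   `upr`.
#' @export
predict.scheffe_fit <- function(object, blends,
                                interval = c("confidence", "none"),
                                level = 0.95, ...) {
  interval <- match.arg(interval)
  z <- pseudo_coords(blends, object$space)
  X0 <- evaluate_terms(z, object$termset)
  eta <- drop(X0 %*% object$coefficients)
  out <- data.frame(fit = inverse_transform(eta, object$transform))
  if (interval == "confidence") {
    if (object$df_residual <= 0L || is.na(object$sigma))
      stop("no residual degrees of freedom: intervals unavailable",
           call. = FALSE)
    se <- sqrt(object$sigma^2 * rowSums((X0 %*% object$XtXinv) * X0))
    tq <- stats::qt(1 - (1 - level) / 2, object$df_residual)
    out$lwr <- inverse_transform(eta - tq * se, object$transform)
    out$upr <- inverse_transform(eta + tq * se, object$transform)
  }
  out
}

#' Hierarchical backward elimination of model terms
#'
#' Iteratively removes the non-significant term with the largest Type III
#' p-value at or above `alpha`, refitting after each removal.  The three
#' linear blending terms are never removed, and a term is removable only
#' when no retained higher-order term contains it (mixture-model
#' hierarchy), so e.g. AB survives while A2BC is in the model.
#'
#' @param fit a [scheffe_fit()].
#' @param alpha removal threshold on the Type III p-value.
#' @return The reduced `scheffe_fit` (possibly the input unchanged).
#' @export
backward_eliminate <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "scheffe_fit"))
  repeat {
    t3 <- fit$type3
    if (is.null(t3)) return(fit)
    terms <- fit$termset$terms
    labels <- term_labels(fit$termset)
    removable <- vapply(seq_along(terms), function(j) {
      tm <- terms[[j]]
      if (tm$label %in% c("A", "B", "C", "(mean)")) return(FALSE)
      !any(vapply(terms, function(u) term_contained_in(tm, u), logical(1L)))
    }, logical(1L))
    cand <- t3[t3$term %in% labels[removable] & t3$p >= alpha, , drop = FALSE]
    if (!nrow(cand)) return(fit)
    drop_label <- cand$term[which.max(cand$p)]
    fit <- refit(fit, subset_terms(fit$termset,
                                   setdiff(labels, drop_label)))
  }
}

ladder_orders <- c("mean", "linear", "quadratic", "special_cubic",
                   "cubic", "special_quartic", "quartic")

#' Sequential model selection over the Scheffe ladder
#'
#' Fits the model ladder mean, linear, quadratic, special cubic, cubic,
#' special quartic, quartic, and assesses each step by the Type I
#' sequential F test of its sum-of-squares increment over the previous
#' order, together with lack of fit and the summary-statistic family.
#'
#' The chosen order is the highest non-aliased order whose sequential
#' p-value is below `alpha`; among qualifying orders, those with a
#' non-significant lack of fit are preferred when any exists.  A gap
#' larger than 0.2 between adjusted and predicted R-squared is flagged as
#' a reliability warning.  When no order qualifies, the linear model is
#' chosen.
#'
#' @param runs run table data frame.
#' @param response response name.
#' @param space a [mixture_space()].
#' @param transform modelling transform.
#' @param alpha significance level of the sequential test.
#' @param exclude run ids to drop from all fits.
#' @return A list of class `sequential_selection` with a per-order `table`
#'   (data frame), the `chosen` order, `rationale` codes and the chosen
#'   `fit`.
#' @export
sequential_selection <- function(runs, response,
                                 space = ludens_space(),
                                 transform = default_transform(response),
                                 alpha = 0.05, exclude = NULL) {
  # Each order's Type I increment is measured against its nested base
  # model: the special quartic extends the quadratic directly (its span
  # does not contain the cubic difference terms), all other steps extend
  # the preceding order.
  baseline <- c(linear = "mean", quadratic = "linear",
                special_cubic = "quadratic", cubic = "special_cubic",
                special_quartic = "quadratic", quartic = "cubic")
  fits <- list()
  rows <- list()
  for (ord in ladder_orders) {
    f <- tryCatch(
      scheffe_fit(runs, response, ord, space, transform, exclude = exclude),
      error = function(e) e)
    if (inherits(f, "error")) {
      rows[[ord]] <- data.frame(
        order = ord, n_terms = length(scheffe_terms(ord)), aliased = TRUE,
        seq_ss = NA_real_, seq_F = NA_real_, seq_p = NA_real_,
        lof_F = NA_real_,
        lof_p = NA_real_, sigma = NA_real_, r2 = NA_real_,
        r2_adj = NA_real_, r2_pred = NA_real_, press = NA_real_)
      next
    }
    fits[[ord]] <- f
    seq_F <- seq_p <- NA_real_
    seq_ss <- NA_real_
    base <- if (ord %in% names(baseline)) fits[[baseline[[ord]]]] else NULL
    if (!is.null(base)) {
      seq_ss <- f$ss_model - base$ss_model
      d_df <- length(f$termset) - length(base$termset)
      if (f$df_residual > 0L && !is.na(f$sigma) && f$sigma > 0 &&
          seq_ss >= -1e-8 * max(f$ss_model, 1) && d_df > 0L) {
        seq_ss <- max(seq_ss, 0)
        seq_F <- (seq_ss / d_df) / f$sigma^2
        seq_p <- stats::pf(seq_F, d_df, f$df_residual, lower.tail = FALSE)
      }
    }
    lof <- f$lack_of_fit
    rows[[ord]] <- data.frame(
      order = ord, n_terms = length(f$termset), aliased = FALSE,
      seq_ss = seq_ss, seq_F = seq_F, seq_p = seq_p,
      lof_F = if (is.null(lof)) NA_real_ else lof$F,
      lof_p = if (is.null(lof)) NA_real_ else lof$p,
      sigma = f$sigma, r2 = f$r2, r2_adj = f$r2_adj,
      r2_pred = f$r2_pred, press = f$press)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL

  rationale <- character()
  cand <- table[!table$aliased & !is.na(table$seq_p) &
                  table$seq_p < alpha, , drop = FALSE]
  if (any(table$aliased)) rationale <- c(rationale, "aliased orders excluded")
  if (nrow(cand)) {
    ok_lof <- cand[is.na(cand$lof_p) | cand$lof_p >= alpha, , drop = FALSE]
    if (nrow(ok_lof) && nrow(ok_lof) < nrow(cand))
      rationale <- c(rationale, "orders with significant lack of fit passed over")
    pool <- if (nrow(ok_lof)) ok_lof else cand
    chosen <- pool$order[which.max(match(pool$order, ladder_orders))]
    rationale <- c(rationale,
                   sprintf("highest order with sequential p < %.2f", alpha))
  } else {
    chosen <- "linear"
    rationale <- c(rationale,
                   "no order improved significantly; linear retained")
  }
  chosen_row <- table[table$order == chosen, ]
  if (!is.na(chosen_row$r2_adj) && !is.na(chosen_row$r2_pred) &&
      chosen_row$r2_adj - chosen_row$r2_pred > 0.2)
    rationale <- c(rationale,
                   "warning: adjusted vs predicted R2 gap exceeds 0.2")
  structure(list(table = table, chosen = chosen, rationale = rationale,
                 fit = fits[[chosen]]),
            class = "sequential_selection")
}

#' @export
print.sequential_selection <- function(x, ...) {
  cat("Sequential Scheffe model selection; chosen:", x$chosen, "\n")
  print(transform(x$table,
                  seq_F = round(seq_F, 3), seq_p = round(seq_p, 4),
                  lof_F = round(lof_F, 3), lof_p = round(lof_p, 4),
                  sigma = signif(sigma, 4), r2 = round(r2, 3),
                  r2_adj = round(r2_adj, 3), r2_pred = round(r2_pred, 3),
                  press = signif(press, 4)))
  cat("rationale:", paste(x$rationale, collapse = "; "), "\n")
  invisible(x)
}
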