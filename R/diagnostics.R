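#' Residual and influence diagnostics for a Scheffe fit
#'
#' Closed-form leave-one-out diagnostics computed from the hat matrix:
#' internally studentized residuals `r_i = e_i / (sigma * sqrt(1 - h_ii))`,
#' externally studentized ("outlier-t") residuals
#' `t_i = r_i * sqrt((df - 1) / (df - r_i^2))`, Cook's distance
#' `D_i = r_i^2 h_ii / (p (1 - h_ii))`, `DFFITS_i = t_i sqrt(h_ii / (1 - h_ii))`
#' and DFBETAS from the rank-one downdate identity
#' `beta - beta_(i) = (X'X)^{-1} x_i e_i / (1 - h_ii)` scaled by the
#' deleted-run coefficient standard error.
#'
#' A run is flagged as an outlier when `|t_i|` exceeds
#' `thresholds$outlier_t`, and as influential when Cook's distance,
#' |DFFITS| or any |DFBETAS| exceeds its threshold.  A run is an
#' *exclusion candidate* only when the outlier rule fires together with at
#' least one influence rule.
#'
#' @param fit a [scheffe_fit()].
#' @param thresholds named list of flag thresholds; defaults are
#'   `outlier_t = 3`, `cooks = 1`, `dffits = 2 * sqrt(p / n)`,
#'   `dfbetas = 2 / sqrt(n)`.
#' @return An object of class `diagnostics_report`: a data frame `stats`
#'   (per-run statistics and flags), the `dfbetas` matrix and the
#'   thresholds used.
#' @export
residual_diagnostics <- function(fit, thresholds = NULL) {
  stopifnot(inherits(fit, "scheffe_fit"))
  n <- fit$n
  p <- length(fit$termset)
  df <- fit$df_residual
  if (df < 2L)
    stop("at least 2 residual degrees of freedom are required", call. = FALSE)
  thr <- list(outlier_t = 3, cooks = 1,
              dffits = 2 * sqrt(p / n), dfbetas = 2 / sqrt(n))
  thr[names(thresholds)] <- thresholds

  e <- fit$residuals
  h <- fit$hat
  sigma <- fit$sigma
  if (is.na(sigma) || sigma < 1e-10 * max(abs(fit$y), 1)) {
    # exact interpolation: every statistic is identically zero
    r <- tval <- cooks <- dffits <- rep(0, n)
    dfb <- matrix(0, n, p, dimnames = list(fit$run_id,
                                           term_labels(fit$termset)))
  } else {
    r <- e / (sigma * sqrt(1 - h))
    # deleted residual variance: s_(i)^2 = sigma^2 (df - r_i^2) / (df - 1)
    s_i2 <- sigma^2 * (df - r^2) / (df - 1)
    s_i2 <- pmax(s_i2, 0)
    tval <- ifelse(s_i2 > 0, e / sqrt(s_i2 * (1 - h)), Inf * sign(e))
    cooks <- r^2 * h / (p * (1 - h))
    dffits <- tval * sqrt(h / (1 - h))
    delta <- (fit$XtXinv %*% t(fit$X)) * rep(e / (1 - h), each = p)
    dfb <- t(delta) / rep(sqrt(diag(fit$XtXinv)), each = n) /
      rep(sqrt(s_i2), times = p)
    dimnames(dfb) <- list(fit$run_id, term_labels(fit$termset))
  }

  outlier <- abs(tval) > thr$outlier_t
  influence <- cooks > thr$cooks | abs(dffits) > thr$dffits |
    apply(abs(dfb) > thr$dfbetas, 1L, any)
  stats <- data.frame(
    run_id = fit$run_id, leverage = h, rstandard = r, rstudent = tval,
    cooks = cooks, dffits = dffits,
    flag_outlier = outlier, flag_influence = influence,
    exclusion_candidate = outlier & influence)
  structure(list(stats = stats, dfbetas = dfb, thresholds = thr,
                 response = fit$response),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("Diagnostics for '", x$response, "' (", nrow(x$stats), " runs)\n",
      sep = "")
  flagged <- x$stats[x$stats$flag_outlier | x$stats$flag_influence, ]
  if (nrow(flagged)) {
    cat("flagged runs:\n")
    print(round_df(flagged, 3))
  } else cat("no runs flagged\n")
  invisible(x)
}

round_df <- function(d, digits) {
  num <- vapply(d, is.numeric, logical(1L))
  d[num] <- lapply(d[num], round, digits)
  d
}

#' Box-Cox transformation profile
#'
#' Profile log-likelihood of the Box-Cox power family over a lambda grid,
#' using the geometric-mean-scaled transform so likelihoods are comparable
#' across lambda.  The 95% confidence region is the set of lambdas whose
#' profile lies within chi-squared(1)/2 of the maximum; no transform is
#' recommended when lambda = 1 falls inside it.
#'
#' Only meaningful for responses modelled untransformed and strictly
#' positive.
#'
#' @param fit a [scheffe_fit()] with `transform = "none"`.
#' @param lambda numeric grid of exponents.
#' @param level confidence level of the profile interval.
#' @return A list with the `lambda` grid, `loglik` profile, `best` lambda,
#'   the confidence interval `ci`, and `recommendation` (`"none"` or
#'   `"power"`).
#' @export
box_cox_profile <- function(fit, lambda = seq(-3, 3, by = 0.1),
                            level = 0.95) {
  stopifnot(inherits(fit, "scheffe_fit"))
  if (fit$transform != "none")
    stop("Box-Cox applies to untransformed responses only", call. = FALSE)
  y <- fit$y
  if (any(y <= 0))
    stop("Box-Cox requires strictly positive response values", call. = FALSE)
  n <- length(y)
  gm <- exp(mean(log(y)))
  loglik <- vapply(lambda, function(l) {
    yt <- if (abs(l) < 1e-12) gm * log(y)
          else (y^l - 1) / (l * gm^(l - 1))
    rss <- sum(stats::lsfit(fit$X, yt, intercept = FALSE)$residuals^2)
    -n / 2 * log(rss / n)
  }, 0)
  best <- lambda[which.max(loglik)]
  if (length(lambda) == 1L)
    return(list(lambda = lambda, loglik = loglik, best = best,
                ci = c(best, best), recommendation = "none"))
  cut <- max(loglik) - stats::qchisq(level, 1L) / 2
  inside <- lambda[loglik >= cut]
  ci <- range(inside)
  list(lambda = lambda, loglik = loglik, best = best, ci = ci,
       recommendation = if (ci[1L] <= 1 && 1 <= ci[2L]) "none" else "power")
}

#' Outlier-exclusion workflow
#'
#' Mirrors the study's handling of aberrant runs: fit the parent model,
#' flag runs that are simultaneously outliers (externally studentized
#' residual) and influential (Cook's distance, DFFITS or DFBETAS), exclude
#' the single worst such run, refit, and repeat until nothing is flagged
#' or the exclusion cap is reached.  The default cap of one exclusion per
#' response reflects how sparingly exclusion should be used.
#'
#' @param runs run table data frame.
#' @param response response name.
#' @param termset parent term set (order name or [scheffe_terms()]).
#' @param space a [mixture_space()].
#' @param transform modelling transform.
#' @param thresholds see [residual_diagnostics()].
#' @param cap maximum number of runs to exclude.
#' @param alpha significance level used by the final backward elimination.
#' @param reduce if `TRUE` (default), backward-eliminate the final fit.
#' @return A list with the final `fit`, `excluded` run ids, and a `trail`
#'   data frame recording each decision.
#' @export
exclusion_workflow <- function(runs, response, termset,
                               space = ludens_space(),
                               transform = default_transform(response),
                               thresholds = NULL, cap = 1L,
                               alpha = 0.05, reduce = TRUE) {
  excluded <- integer()
  trail <- list()
  repeat {
    fit <- scheffe_fit(runs, response, termset, space, transform,
                       exclude = excluded)
    diag <- residual_diagnostics(fit, thresholds)
    cand <- diag$stats[diag$stats$exclusion_candidate, , drop = FALSE]
    if (!nrow(cand) || length(excluded) >= cap) break
    worst <- cand$run_id[which.max(abs(cand$rstudent))]
    trail[[length(trail) + 1L]] <- data.frame(
      step = length(excluded) + 1L, run_id = worst,
      rstudent = cand$rstudent[cand$run_id == worst],
      cooks = cand$cooks[cand$run_id == worst])
    excluded <- c(excluded, worst)
  }
  if (reduce) fit <- backward_eliminate(fit, alpha)
  list(fit = fit, excluded = excluded,
       trail = if (length(trail)) do.call(rbind, trail)
               else data.frame(step = integer(), run_id = integer(),
                               rstudent = numeric(), cooks = numeric()))
}
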