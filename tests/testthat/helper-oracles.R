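# Brute-force leave-one-out oracles, independent of the closed forms in
# the package: every statistic is recomputed by literally refitting
# without each run.

ols <- function(X, y) {
  beta <- qr.coef(qr(X), y)
  list(beta = beta, resid = y - drop(X %*% beta))
}

loo_oracle <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  full <- ols(X, y)
  rss <- sum(full$resid^2)
  sigma2 <- rss / (n - p)
  XtXinv <- solve(crossprod(X))
  press <- 0
  rstudent <- cooks <- dffits <- numeric(n)
  dfbetas <- matrix(0, n, p)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    fi <- ols(Xi, yi)
    s_i2 <- sum(fi$resid^2) / (nrow(Xi) - p)
    pred_i <- drop(X[i, , drop = FALSE] %*% fi$beta)
    e_loo <- y[i] - pred_i
    press <- press + e_loo^2
    v <- drop(X[i, , drop = FALSE] %*%
                solve(crossprod(Xi)) %*% t(X[i, , drop = FALSE]))
    rstudent[i] <- e_loo / sqrt(s_i2 * (1 + v))
    db <- full$beta - fi$beta
    cooks[i] <- drop(t(db) %*% crossprod(X) %*% db) / (p * sigma2)
    h_i <- drop(X[i, , drop = FALSE] %*% XtXinv %*% t(X[i, , drop = FALSE]))
    dffits[i] <- (drop(X[i, , drop = FALSE] %*% full$beta) - pred_i) /
      sqrt(s_i2 * h_i)
    dfbetas[i, ] <- db / sqrt(s_i2 * diag(XtXinv))
  }
  list(press = press, rstudent = rstudent, cooks = cooks,
       dffits = dffits, dfbetas = dfbetas)
}

# A small replicated design usable for randomized fits: corners four-fold
# plus duplicated edge/interior blends.
small_design <- function(seed = 1L) {
  plan <- rep(1L, 19L)
  plan[c(1L, 15L, 19L)] <- 2L
  ludens_design(replicates = plan, seed = seed)
}

# Random run table with a smooth quadratic-ish response plus noise.
random_runs <- function(seed, design = ludens_design(seed = seed)) {
  set.seed(seed)
  z <- to_pseudo(design[, c("yeast_pct", "cornflour_pct", "corncob_pct")],
                 ludens_space())
  design$duration_days <- 9 + 2 * z[, 2] + 2.5 * z[, 3] -
    1.5 * z[, 1] * z[, 2] + rnorm(nrow(design), 0, 0.4)
  design
}

expect_all_equal <- function(a, b, tol) {
  expect_true(max(abs(a - b)) < tol,
              label = sprintf("max deviation %.3g < %g", max(abs(a - b)), tol))
}
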