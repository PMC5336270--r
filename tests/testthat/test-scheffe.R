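sp <- ludens_space()
corner_runs <- function(y = c(1, 2, 3)) {
  data.frame(run_id = 1:3,
             yeast_pct = c(6, 3, 3),
             cornflour_pct = c(5.3, 8.3, 5.3),
             corncob_pct = c(19, 19, 22),
             resp = y)
}

test_that("design matrix evaluates Scheffe terms on the pseudo scale", {
  X <- design_matrix(corner_runs(), scheffe_terms("linear"), sp)
  expect_equal(unname(X), diag(3))
  ts <- scheffe_terms("special_quartic")
  v <- evaluate_terms(c(0.5, 0.25, 0.25), ts)
  expect_equal(v[, "A2BC"], c(0.015625), ignore_attr = TRUE)
  vq <- evaluate_terms(rep(1, 3) / 3, scheffe_terms("quadratic"))
  expect_equal(vq[, "AB"], 1 / 9, ignore_attr = TRUE)
})

test_that("a saturated corner fit interpolates exactly", {
  fit <- scheffe_fit(corner_runs(), "resp", "linear", sp, transform = "none")
  expect_equal(unname(fit$coefficients), c(1, 2, 3))
  expect_equal(fit$rss, 0)
  expect_equal(fit$r2, 1)
})

test_that("noise-free simulated data returns the generating coefficients", {
  truth <- ludens_truth()
  runs <- simulate_runs(ludens_design(seed = 4), truth, noise = FALSE)
  for (resp in names(truth$surfaces)) {
    surf <- truth$surfaces[[resp]]
    fit <- scheffe_fit(runs, resp, surf$termset, sp, surf$transform)
    expect_all_equal(fit$coefficients, surf$coefficients, 1e-9)
    expect_lt(fit$rss, 1e-18)
  }
})

test_that("linear coefficients equal predictions at the corner blends", {
  runs <- random_runs(21)
  fit <- scheffe_fit(runs, "duration", "quadratic", sp, "none")
  corners <- space_corners(sp)
  pr <- predict(fit, corners, interval = "confidence")
  expect_all_equal(pr$fit, unname(fit$coefficients[c("A", "B", "C")]), 1e-10)
  expect_all_equal(pr$lwr, unname(fit$ci[c("A", "B", "C"), "low"]), 1e-10)
  expect_all_equal(pr$upr, unname(fit$ci[c("A", "B", "C"), "high"]), 1e-10)
})

test_that("PRESS via the hat identity equals explicit leave-one-out refits", {
  for (seed in c(7, 31)) {
    runs <- random_runs(seed)
    fit <- scheffe_fit(runs, "duration", "quadratic", sp, "none")
    oracle <- loo_oracle(fit$X, fit$y)
    expect_all_equal(fit$press, oracle$press, 1e-8)
    expect_all_equal(press_stats(fit)$press, oracle$press, 1e-8)
  }
  # leverage-1 points cannot be cross-validated
  sat <- scheffe_fit(corner_runs(), "resp", "linear", sp, transform = "none")
  expect_error(press_stats(sat), "leverage")
})

test_that("Type I sequential SS telescopes to the largest model SS", {
  # conservation along the nested chain (the special quartic branches
  # off the quadratic and is not part of the telescoping sum)
  runs <- random_runs(13)
  sel <- sequential_selection(runs, "duration", sp, "none")
  chain <- sel$table[!sel$table$aliased &
                       sel$table$order != "special_quartic", ]
  top <- scheffe_fit(runs, "duration", chain$order[nrow(chain)], sp, "none")
  expect_equal(sum(chain$seq_ss, na.rm = TRUE), top$ss_model,
               tolerance = 1e-8)
})

test_that("lack of fit splits residual SS into model and pure-error parts", {
  runs <- random_runs(5)
  fit <- scheffe_fit(runs, "duration", "linear", sp, "none")
  lof <- fit$lack_of_fit
  expect_equal(lof$df_lof, 19 - 3)
  expect_equal(lof$df_pe, 40 - 19)
  expect_equal(lof$ss_lof + lof$ss_pe, fit$rss, tolerance = 1e-10)
  # direct pure-error recomputation
  key <- paste(runs$yeast_pct, runs$cornflour_pct, runs$corncob_pct)
  ss_pe <- sum(tapply(runs$duration_days, key,
                      function(g) sum((g - mean(g))^2)))
  expect_equal(lof$ss_pe, ss_pe, tolerance = 1e-10)
  # degenerate: identical replicate values and an interpolating model
  # (4 distinct blends, linear response surface, so SS_pe = SS_lof = 0)
  d <- corner_runs()
  d <- rbind(d, data.frame(run_id = 4L, yeast_pct = 4, cornflour_pct = 6.3,
                           corncob_pct = 20, resp = 2))
  d <- rbind(d, d); d$run_id <- 1:8
  fit2 <- scheffe_fit(d, "resp", "linear", sp, "none")
  lof2 <- lack_of_fit(fit2)
  expect_equal(lof2$ss_pe, 0)
  expect_equal(lof2$F, 0)
})

test_that("no-replicate designs refuse a lack-of-fit test", {
  runs <- random_runs(9, ludens_design(replicates = rep(1L, 19L)))
  fit <- scheffe_fit(runs, "duration", "linear", sp, "none")
  expect_error(lack_of_fit(fit), "replicate")
  expect_null(fit$lack_of_fit)
})

test_that("adequate precision is a scaled fitted-value range", {
  runs <- random_runs(17)
  fit <- scheffe_fit(runs, "duration", "linear", sp, "none")
  expect_equal(fit$adequate_precision,
               diff(range(fit$fitted)) / sqrt(3 * fit$sigma^2 / fit$n))
  runs$duration_days <- 10  # constant response
  flat <- scheffe_fit(runs, "duration", "linear", sp, "none")
  expect_equal(adequate_precision(flat), 0)
})

test_that("backward elimination respects the mixture hierarchy", {
  # strong special-quartic signal, tiny noise: the quartic terms are
  # retained, so their nested two-way terms survive even if insignificant
  surf <- ludens_surfaces()$duration
  truth <- ludens_truth()
  set.seed(42)
  runs <- simulate_runs(ludens_design(seed = 8), truth, noise = FALSE)
  runs$duration_days <- runs$duration_days + rnorm(40, 0, 0.05)
  fit <- scheffe_fit(runs, "duration", "special_quartic", sp, "none")
  red <- backward_eliminate(fit)
  kept <- term_labels(red$termset)
  expect_true(all(c("A2BC", "AB2C") %in% kept))
  expect_true(all(c("AB", "AC", "BC") %in% kept))

  # no real interactions: a quadratic parent collapses to linear
  runs2 <- random_runs(3)
  set.seed(3)
  z <- to_pseudo(runs2[, c("yeast_pct", "cornflour_pct", "corncob_pct")], sp)
  runs2$duration_days <- 9 + 2 * z[, 2] + 2.5 * z[, 3] + rnorm(40, 0, 0.3)
  red2 <- backward_eliminate(
    scheffe_fit(runs2, "duration", "quadratic", sp, "none"))
  expect_equal(sort(term_labels(red2$termset)), c("A", "B", "C"))
})

test_that("sequential selection picks the generating order", {
  # a clear quadratic signal: the quadratic step must qualify, and the
  # choice must be the highest qualifying order of the recorded ladder
  d <- ludens_design(seed = 19)
  z <- to_pseudo(d[, c("yeast_pct", "cornflour_pct", "corncob_pct")], sp)
  set.seed(19)
  d$duration_days <- 9 + 2 * z[, 2] + 2.5 * z[, 3] - 6 * z[, 1] * z[, 2] +
    rnorm(40, 0, 0.1)
  sel <- sequential_selection(d, "duration", sp, "none")
  tab <- sel$table
  expect_lt(tab$seq_p[tab$order == "quadratic"], 0.05)
  qualifying <- tab$order[!tab$aliased & !is.na(tab$seq_p) &
                            tab$seq_p < 0.05]
  expect_equal(sel$chosen, tail(qualifying, 1))
  expect_s3_class(sel$fit, "scheffe_fit")
  expect_gte(tab$r2_pred[tab$order == sel$chosen],
             tab$r2_pred[tab$order == "linear"])
  # saturated corners: every order above linear is aliased
  sel2 <- sequential_selection(corner_runs(), "resp", sp, "none")
  expect_equal(sel2$chosen, "linear")
  higher <- !sel2$table$order %in% c("mean", "linear")
  expect_true(all(sel2$table$aliased[higher]))
})

test_that("published duration surface crosses its limit near the region corner", {
  dur <- ludens_surfaces()$duration
  expect_equal(predict(dur, c(5.27, 6.03, 19.0)), 9.46, tolerance = 0.001)
  expect_equal(predict(dur, c(6.0, 5.3, 19.0)), 9.10, tolerance = 1e-12)
})

test_that("arcsine square-root models predict on the proportion scale", {
  em <- ludens_surfaces()$emergence
  expect_equal(predict(em, c(6.0, 5.3, 19.0)), 0.90, tolerance = 1e-12)
  expect_equal(predict(em, c(3.0, 5.3, 22.0)), 0.99, tolerance = 1e-12)
  expect_equal(back_transform_coef(asin(sqrt(0.81))), 0.81)
  expect_equal(back_transform_coef(-asin(sqrt(0.81))), -0.81)
  runs <- corner_runs(c(0.9, 0.8, 1.2))
  expect_error(scheffe_fit(runs, "resp", "linear", sp, "arcsine_sqrt"),
               "\\[0, 1\\]")
})

test_that("rank deficiency and short data are rejected", {
  expect_error(scheffe_fit(corner_runs(), "resp", "quadratic", sp, "none"),
               "fewer runs")
  d <- corner_runs(); d <- rbind(d, d, d); d$run_id <- 1:9
  expect_error(scheffe_fit(d, "resp", "quadratic", sp, "none"), "aliased")
})

test_that("extrapolated predictions warn instead of failing", {
  runs <- random_runs(23)
  fit <- scheffe_fit(runs, "duration", "linear", sp, "none")
  outside <- c(7, 5.3, 18)  # sums to 30.3 but breaks the yeast bound
  expect_warning(predict(fit, outside), "extrapolation")
})
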