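sp <- ludens_space()

test_that("closed-form influence statistics equal brute-force LOO refits", {
  for (seed in c(2, 29)) {
    runs <- random_runs(seed)
    fit <- scheffe_fit(runs, "duration", "quadratic", sp, "none")
    dg <- residual_diagnostics(fit)
    oracle <- loo_oracle(fit$X, fit$y)
    expect_all_equal(dg$stats$rstudent, oracle$rstudent, 1e-8)
    expect_all_equal(dg$stats$cooks, oracle$cooks, 1e-8)
    expect_all_equal(dg$stats$dffits, oracle$dffits, 1e-8)
    expect_all_equal(dg$dfbetas, oracle$dfbetas, 1e-8)
  }
})

test_that("a gross single-run contamination gets the maximum outlier-t", {
  runs <- random_runs(37)
  victim <- runs$run_id[12]
  bad <- contaminate(runs, victim, "duration", 10 * 0.4)
  fit <- scheffe_fit(bad, "duration", "quadratic", sp, "none")
  dg <- residual_diagnostics(fit)
  worst <- dg$stats$run_id[which.max(abs(dg$stats$rstudent))]
  expect_equal(worst, victim)
  expect_true(dg$stats$exclusion_candidate[dg$stats$run_id == victim])
})

test_that("an exact interpolation yields all-zero diagnostics", {
  runs <- simulate_runs(ludens_design(seed = 6), ludens_truth(),
                        noise = FALSE)
  fit <- scheffe_fit(runs, "duration",
                     ludens_surfaces()$duration$termset, sp, "none")
  dg <- residual_diagnostics(fit)
  expect_all_equal(dg$stats$rstudent, rep(0, 40), 1e-10)
  expect_all_equal(dg$stats$cooks, rep(0, 40), 1e-10)
  expect_false(any(dg$stats$flag_outlier | dg$stats$flag_influence))
})

test_that("inflating the contamination never clears the flags", {
  runs <- random_runs(41)
  victim <- runs$run_id[20]
  flagged <- logical()
  for (shift in c(3, 6, 12, 24) * 0.4) {
    bad <- contaminate(runs, victim, "duration", shift)
    fit <- scheffe_fit(bad, "duration", "quadratic", sp, "none")
    dg <- residual_diagnostics(fit)
    flagged <- c(flagged,
                 dg$stats$exclusion_candidate[dg$stats$run_id == victim])
  }
  expect_true(all(diff(flagged) >= 0))  # once flagged, stays flagged
  expect_true(tail(flagged, 1))
})

test_that("Box-Cox profile matches MASS and finds the generating transform", {
  runs <- random_runs(15)
  fit <- scheffe_fit(runs, "duration", "linear", sp, "none")
  bc <- box_cox_profile(fit)
  expect_equal(bc$recommendation, "none")
  # independent cross-check of the profile shape against MASS::boxcox
  mb <- MASS::boxcox(fit$y ~ fit$X - 1, lambda = bc$lambda, plotit = FALSE)
  expect_equal(bc$lambda[which.max(bc$loglik)],
               mb$x[which.max(mb$y)])
  expect_all_equal(bc$loglik - max(bc$loglik), mb$y - max(mb$y), 1e-6)

  # log-normal response with a wide dynamic range: maximum near lambda = 0
  set.seed(77)
  z <- to_pseudo(runs[, c("yeast_pct", "cornflour_pct", "corncob_pct")], sp)
  runs$duration_days <- exp(1 + 3 * z[, 2] + 5 * z[, 3] +
                              rnorm(40, 0, 0.15))
  lfit <- scheffe_fit(runs, "duration", "linear", sp, "none")
  bcl <- box_cox_profile(lfit)
  expect_lt(abs(bcl$best), 0.5)

  expect_equal(box_cox_profile(fit, lambda = 0.5)$best, 0.5)
  runs$duration_days[1] <- -1
  nfit <- scheffe_fit(runs, "duration", "linear", sp, "none")
  expect_error(box_cox_profile(nfit), "positive")
  efit <- scheffe_fit(simulate_runs(ludens_design(seed = 1),
                                    ludens_truth(), seed = 1),
                      "emergence", "quadratic")
  expect_error(box_cox_profile(efit), "untransformed")
})

test_that("the exclusion workflow removes exactly the contaminated run", {
  truth <- ludens_truth()
  runs <- simulate_runs(ludens_design(seed = 10), truth, seed = 10)
  victim <- runs$run_id[33]
  bad <- contaminate(runs, victim, "duration", 10 * truth$duration_sd)
  wf <- exclusion_workflow(bad, "duration", "special_quartic")
  expect_equal(wf$excluded, victim)
  expect_false(victim %in% wf$fit$run_id)

  clean <- exclusion_workflow(runs, "duration", "special_quartic")
  expect_length(clean$excluded, 0)
})

test_that("contaminate guards its inputs", {
  runs <- simulate_runs(ludens_design(seed = 2), ludens_truth(), seed = 2)
  expect_identical(contaminate(runs, 1, "duration", 0), runs)
  expect_error(contaminate(runs, 999, "duration", 1), "not found")
  runs$duration_days[runs$run_id == 4] <- NA
  expect_error(contaminate(runs, 4, "duration", 1), "no recorded")
})
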