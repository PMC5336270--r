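sp <- ludens_space()

study_setup <- function(step = 0.05) {
  surfaces <- ludens_surfaces()
  costspec <- solve_unit_prices()
  criteria <- ludens_criteria()
  grid <- evaluate_grid(surfaces, costspec, sp, step)
  list(surfaces = surfaces, costspec = costspec, criteria = criteria,
       grid = grid)
}

test_that("criteria derive from prediction intervals at the reference blend", {
  truth <- ludens_truth()
  runs <- simulate_runs(ludens_design(seed = 14), truth, seed = 14)
  fits <- list(
    pupation = scheffe_fit(runs, "pupation", "linear"),
    duration = scheffe_fit(runs, "duration", "special_quartic"),
    pupal_weight = scheffe_fit(runs, "pupal_weight", "quadratic"),
    emergence = scheffe_fit(runs, "emergence", "quadratic"))
  ref <- c(6, 5.3, 19)
  crit <- criteria_from_reference(fits, ref)
  for (nm in names(fits)) {
    pr <- predict(fits[[nm]], ref, interval = "confidence")
    expected <- if (nm == "duration") pr$upr else pr$lwr
    expect_equal(crit[[nm]]$limit, expected)
  }
  expect_equal(crit$duration$bound, "max")
  expect_equal(crit$pupation$bound, "min")
  # overrides replace only the named limit
  crit2 <- criteria_from_reference(fits, ref,
                                   overrides = list(pupation = 0.5))
  expect_equal(crit2$pupation$limit, 0.5)
  expect_equal(crit2$pupation$source, "user")
  expect_equal(crit2$duration$limit, crit$duration$limit)
})

test_that("a coarse lattice enumerates exactly the in-bounds blends", {
  s <- study_setup(step = 1.5)
  grid <- s$grid
  # independent exhaustive enumeration of the 1.5-point lattice
  cand <- expand.grid(a = c(3, 4.5, 6), b = c(5.3, 6.8, 8.3))
  cand$c <- 30.3 - cand$a - cand$b
  cand <- cand[cand$c >= 19 & cand$c <= 22, ]
  expect_equal(nrow(grid), nrow(cand))
  expect_setequal(paste(grid$yeast_pct, grid$cornflour_pct),
                  paste(cand$a, cand$b))
  corners <- space_corners(sp)
  for (i in 1:3)
    expect_true(any(grid$yeast_pct == corners[i, 1] &
                      grid$cornflour_pct == corners[i, 2]))
  expect_equal(rowSums(grid[, 1:3]), rep(30.3, nrow(grid)))
  # corner predictions equal the linear coefficients (coding property)
  top <- grid[grid$yeast_pct == 6, ]
  expect_equal(top$pred_pupation, 0.83)
  expect_equal(top$pred_duration, 9.10)
  expect_equal(top$pred_pupal_weight, 17.98)
  expect_equal(top$pred_emergence, 0.90)
})

test_that("the operability region reproduces the published corner", {
  s <- study_setup(step = 0.01)
  region <- operability_region(s$grid, s$criteria)
  expect_false(region$empty)
  expect_equal(region$ranges["yeast_pct", "min"], 5.27)
  expect_equal(region$ranges["cornflour_pct", "max"], 6.03)
  expect_equal(region$ranges["corncob_pct", "min"], 19)
  # ranges nest inside the design space
  expect_true(all(region$ranges[, "min"] >= sp$lower - 1e-9))
  expect_true(all(region$ranges[, "max"] <= sp$upper + 1e-9))
  # optimum sits on the duration boundary at the corncob floor
  expect_equal(region$argmax$corncob_pct, 19)
  expect_true("duration" %in% region$binding)
  # argmax beats every feasible grid point (exhaustive scan)
  expect_gte(region$argmax$savings_percent,
             max(region$feasible$savings_percent))
  msr <- max_savings_report(region, s$costspec)
  expect_gte(msr$savings_percent, 5.9)
  expect_equal(msr$savings_annual, 47496, tolerance = 0.005)
})

test_that("impossible and vacuous criteria behave as flagged limits", {
  s <- study_setup(step = 0.25)
  impossible <- s$criteria
  impossible$pupation$limit <- 1.1
  r <- operability_region(s$grid, impossible)
  expect_true(r$empty)
  expect_error(max_savings_report(r, s$costspec), "empty")

  vacuous <- structure(list(
    pupation = list(bound = "min", limit = -Inf, source = "user"),
    duration = list(bound = "max", limit = Inf, source = "user")),
    class = "criteria_set")
  rv <- operability_region(s$grid, vacuous)
  expect_equal(nrow(rv$feasible), nrow(s$grid))
  # with no biological constraint the optimum is the cheapest vertex
  expect_equal(unname(unlist(
    rv$argmax[c("yeast_pct", "cornflour_pct", "corncob_pct")])),
    c(3, 8.3, 19))
})

test_that("relaxing any single criterion never shrinks the region", {
  s <- study_setup(step = 0.25)
  base <- operability_region(s$grid, s$criteria)
  for (nm in names(s$criteria)) {
    relaxed <- s$criteria
    bump <- if (relaxed[[nm]]$bound == "min") -0.5 else 0.5
    relaxed[[nm]]$limit <- relaxed[[nm]]$limit + bump
    r <- operability_region(s$grid, relaxed)
    expect_gte(nrow(r$feasible), nrow(base$feasible))
  }
})

test_that("halving the lattice step moves the ranges by at most one step", {
  coarse <- study_setup(step = 0.1)
  fine <- study_setup(step = 0.05)
  rc <- operability_region(coarse$grid, coarse$criteria)$ranges
  rf <- operability_region(fine$grid, fine$criteria)$ranges
  expect_true(all(abs(rc - rf) <= 0.1 + 1e-9))
})

test_that("overlay masks combine by logical AND and duration binds hardest", {
  s <- study_setup(step = 0.1)
  region <- operability_region(s$grid, s$criteria)
  ov <- overlay_export(s$grid, s$criteria, region)
  expect_equal(ov$masks$all,
               ov$masks$pupation & ov$masks$duration &
                 ov$masks$pupal_weight & ov$masks$emergence)
  counts <- colSums(ov$masks[names(s$criteria)])
  expect_equal(names(which.min(counts)), "duration")
  # mask boundaries hug the criterion contour: a feasible point with an
  # infeasible lattice neighbour must predict close to the limit
  dur <- s$grid$pred_duration
  lim <- s$criteria$duration$limit
  key <- paste(s$grid$yeast_pct, s$grid$cornflour_pct)
  neighbour_of <- function(i, da, db)
    match(paste(s$grid$yeast_pct[i] + da, s$grid$cornflour_pct[i] + db), key)
  feas <- which(ov$masks$duration)
  for (i in feas) {
    for (d in list(c(0.1, 0), c(-0.1, 0), c(0, 0.1), c(0, -0.1))) {
      j <- neighbour_of(i, d[1], d[2])
      if (!is.na(j) && !ov$masks$duration[j]) {
        # the contour passes between i and j
        expect_lte(dur[i], lim)
        expect_gt(dur[j], lim)
      }
    }
  }
})
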