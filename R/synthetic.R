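#' Generating ("truth") model for synthetic run tables
#'
#' Bundles one response surface per biological response with a noise
#' specification so that complete run tables with the statistical
#' structure assumed by the analysis can be simulated.  Proportion
#' responses (pupation, adult emergence) receive binomial sampling noise
#' with the larval cohort as denominator; duration and pupal weight
#' receive additive Gaussian noise.
#'
#' @param surfaces named list of [scheffe_surface()] objects for
#'   `pupation`, `duration`, `pupal_weight`, `emergence`.
#' @param duration_sd Gaussian sd of larval duration (days).
#' @param pupal_weight_sd Gaussian sd of pupal weight (mg).
#' @param clamp probability clamp applied to proportion surfaces before
#'   binomial sampling (guards against values leaking outside (0, 1)).
#' @return An object of class `truth_model`.
#' @export
truth_model <- function(surfaces, duration_sd = 0.45,
                        pupal_weight_sd = 1.6,
                        clamp = c(0.001, 0.999)) {
  need <- c("pupation", "duration", "pupal_weight", "emergence")
  if (!all(need %in% names(surfaces)))
    stop("surfaces must cover: ", paste(need, collapse = ", "),
         call. = FALSE)
  stopifnot(duration_sd > 0, pupal_weight_sd > 0)
  structure(list(surfaces = surfaces, duration_sd = duration_sd,
                 pupal_weight_sd = pupal_weight_sd, clamp = clamp),
            class = "truth_model")
}

truth_probability <- function(truth, response, blends) {
  p <- predict(truth$surfaces[[response]], blends)
  if (is.data.frame(p)) p <- p$fit
  bad <- p < 0 | p > 1
  if (any(bad & (p < truth$clamp[1L] - 0.5 | p > truth$clamp[2L] + 0.5)))
    stop("truth surface for '", response,
         "' yields probabilities far outside [0, 1]", call. = FALSE)
  pmin(pmax(p, truth$clamp[1L]), truth$clamp[2L])
}

#' Simulate responses onto a design run table
#'
#' Pupation is drawn as `Binomial(n_larvae, p(z)) / n_larvae`; adult
#' emergence as a binomial fraction of the simulated pupal count
#' (emergence is defined per pupa recovered, not per larva); duration and
#' pupal weight as their surfaces plus Gaussian noise.  With
#' `noise = FALSE` every response equals its truth surface exactly, which
#' is the interpolation oracle used throughout the test-suite.
#'
#' @param design run table with blends (responses are overwritten); see
#'   [ludens_design()].
#' @param truth a [truth_model()].
#' @param seed integer seed; the simulation is a pure function of
#'   (design, truth, seed).
#' @param noise set `FALSE` for the noise-free limit.
#' @return The run table with the four response columns filled.
#' @examples
#' runs <- simulate_runs(ludens_design(seed = 1), ludens_truth(), seed = 42)
#' head(runs)
#' @export
simulate_runs <- function(design, truth, seed = NULL, noise = TRUE) {
  stopifnot(inherits(truth, "truth_model"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  blends <- run_blends(design)
  n <- nrow(design)
  n_larvae <- if ("n_larvae" %in% names(design)) design$n_larvae
              else rep(25L, n)

  p_pup <- truth_probability(truth, "pupation", blends)
  p_em <- truth_probability(truth, "emergence", blends)
  mu_dur <- predict(truth$surfaces$duration, blends)
  mu_wt <- predict(truth$surfaces$pupal_weight, blends)

  out <- design
  if (noise) {
    pupae <- stats::rbinom(n, n_larvae, p_pup)
    out$pupation <- pupae / n_larvae
    out$duration_days <- mu_dur + stats::rnorm(n, 0, truth$duration_sd)
    out$pupal_weight_mg <- mu_wt + stats::rnorm(n, 0, truth$pupal_weight_sd)
    emerged <- ifelse(pupae > 0, stats::rbinom(n, pupae, p_em), NA_integer_)
    out$emergence <- ifelse(pupae > 0, emerged / pupae, NA_real_)
  } else {
    out$pupation <- p_pup
    out$duration_days <- mu_dur
    out$pupal_weight_mg <- mu_wt
    out$emergence <- p_em
  }
  out
}

#' Shift one response of one run (known-contamination helper)
#'
#' Adds `shift` to a single recorded response value, leaving everything
#' else untouched.  Used to verify that the influence diagnostics flag
#' exactly the contaminated run.
#'
#' @param runs run table.
#' @param run_id the run to contaminate.
#' @param response response name.
#' @param shift numeric shift to add.
#' @return The modified run table.
#' @export
contaminate <- function(runs, run_id, response, shift) {
  col <- resolve_response(response, runs)
  i <- which(runs$run_id == run_id)
  if (length(i) != 1L)
    stop("run_id ", run_id, " not found", call. = FALSE)
  if (is.na(runs[[col]][i]))
    stop("run ", run_id, " has no recorded '", response, "' to contaminate",
         call. = FALSE)
  runs[[col]][i] <- runs[[col]][i] + shift
  runs
}

#' Coefficient-recovery experiment
#'
#' Monte-Carlo validation harness: repeatedly simulates a run table from
#' the truth model, refits each response with its own (true) term set, and
#' summarizes per-coefficient bias, RMSE and 95% CI coverage.  Terms of a
#' truth surface that are aliased on the design are reported as
#' non-identifiable rather than estimated.
#'
#' @param truth a [truth_model()].
#' @param design run table of blends (see [ludens_design()]).
#' @param n_reps number of Monte-Carlo replicates (>= 2).
#' @param seed integer seed.
#' @param responses which responses to include.
#' @param space a [mixture_space()].
#' @return A data frame with one row per response x coefficient:
#'   `truth`, `mean_est`, `bias`, `mc_se` (Monte-Carlo standard error of
#'   the bias), `rmse`, `coverage`, `identifiable`.
#' @export
recovery_experiment <- function(truth, design, n_reps = 200L, seed = 1L,
                                responses = c("pupation", "duration",
                                              "pupal_weight", "emergence"),
                                space = ludens_space()) {
  stopifnot(n_reps >= 2L)
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, n_reps)
  out <- list()
  for (resp in responses) {
    surf <- truth$surfaces[[resp]]
    termset <- surf$termset
    X <- design_matrix(design, termset, space)
    identifiable <- qr(X)$rank == ncol(X)
    truth_beta <- surf$coefficients
    if (!identifiable) {
      out[[resp]] <- data.frame(
        response = resp, term = names(truth_beta), truth = truth_beta,
        mean_est = NA_real_, bias = NA_real_, mc_se = NA_real_,
        rmse = NA_real_, coverage = NA_real_, identifiable = FALSE)
      next
    }
    est <- matrix(NA_real_, n_reps, length(truth_beta))
    cover <- matrix(NA, n_reps, length(truth_beta))
    for (r in seq_len(n_reps)) {
      runs <- simulate_runs(design, truth, seed = seeds[r])
      fit <- scheffe_fit(runs, resp, termset, space, surf$transform)
      est[r, ] <- fit$coefficients
      cover[r, ] <- fit$ci[, "low"] <= truth_beta &
        truth_beta <= fit$ci[, "high"]
    }
    out[[resp]] <- data.frame(
      response = resp, term = names(truth_beta), truth = truth_beta,
      mean_est = colMeans(est),
      bias = colMeans(est) - truth_beta,
      mc_se = apply(est, 2L, stats::sd) / sqrt(n_reps),
      rmse = sqrt(colMeans(sweep(est, 2L, truth_beta)^2)),
      coverage = colMeans(cover),
      identifiable = TRUE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
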