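#' Design space of the Anastrepha ludens diet study
#'
#' The variable part of the larval diet is a mixture of inactive dried
#' yeast, corn flour and corncob fractions occupying 30.3% (by weight) of
#' the whole diet, constrained to 3-6% yeast, 5.3-8.3% corn flour and
#' 19-22% corncob fractions.  The remaining 69.7% (sugar 8.2%, sodium
#' benzoate 0.4%, methylparaben 0.1%, citric acid 0.44%, guar gum 0.1%,
#' water 60.46%) is fixed.
#'
#' @return A [mixture_space()].
#' @export
ludens_space <- function() {
  mixture_space(
    lower = c(3, 5.3, 19), upper = c(6, 8.3, 22), mixture_total = 30.3,
    components = c("yeast", "cornflour", "corncob"),
    fixed_fraction = c(sugar = 8.2, sodium_benzoate = 0.4,
                       methylparaben = 0.1, citric_acid = 0.44,
                       guar_gum = 0.1, water = 60.46))
}

#' The 19 diet blends of the A. ludens mixture experiment
#'
#' Blend proportions in percent of the whole diet.  Mixture 1 is the
#' standard mass-rearing formulation (the top vertex of the design space);
#' mixtures 15 and 19 are the other two corners.
#'
#' @return A data frame with columns `mixture_no`, `yeast_pct`,
#'   `cornflour_pct`, `corncob_pct`.
#' @export
ludens_blends <- function() {
  data.frame(
    mixture_no = 1:19,
    yeast_pct = c(6, 5, 5, 5, 4.5, 4.5, 4.3, 4.3, 4, 4, 4, 3.5, 3.5, 3.5,
                  3, 3, 3, 3, 3),
    cornflour_pct = c(5.3, 5.3, 5.8, 6.3, 5.3, 6.8, 5.7, 6.5, 5.3, 6.3,
                      7.3, 5.8, 6.5, 7.3, 5.3, 6.3, 6.8, 7.3, 8.3),
    corncob_pct = c(19, 20, 19.5, 19, 20.5, 19, 20.3, 19.5, 21, 20, 19,
                    21, 20.3, 19.5, 22, 21, 20.5, 20, 19))
}

default_replicate_plan <- function() {
  # 40 runs from 19 blends: the three corner blends four-fold, twelve of
  # the edge/interior blends duplicated, the rest single.  Any plan with
  # this structure leaves 21 pure-error degrees of freedom.
  reps <- rep(1L, 19L)
  reps[c(1L, 15L, 19L)] <- 4L
  reps[c(2L, 4L, 5L, 7L, 9L, 10L, 11L, 12L, 14L, 16L, 17L, 18L)] <- 2L
  reps
}

#' Build the study run table (responses empty)
#'
#' Expands the 19 study blends into experimental runs according to a
#' replicate plan and randomizes the run order.  With the default plan the
#' table has 40 runs: corners replicated four times, twelve further blends
#' twice, leaving 21 pure-error degrees of freedom (40 - 19).
#'
#' @param replicates integer vector of replicate counts, one per mixture
#'   number 1..19 (all >= 1), or a named vector/list keyed by mixture
#'   number to override the default plan selectively.
#' @param seed integer seed controlling run-order randomization; `NULL`
#'   keeps mixture order.
#' @param n_larvae larvae per run (cohort size used as the binomial
#'   denominator of the proportion responses).
#' @return A run table data frame with empty response columns.
#' @examples
#' d <- ludens_design(seed = 1)
#' nrow(d)  # 40
#' @export
ludens_design <- function(replicates = default_replicate_plan(),
                          seed = NULL, n_larvae = 25L) {
  blends <- ludens_blends()
  if (!is.null(names(replicates))) {
    plan <- default_replicate_plan()
    idx <- as.integer(names(replicates))
    if (any(is.na(idx)) || any(idx < 1L | idx > 19L))
      stop("unknown mixture number in replicate plan", call. = FALSE)
    plan[idx] <- as.integer(unlist(replicates))
    replicates <- plan
  }
  replicates <- as.integer(replicates)
  if (length(replicates) != 19L || any(replicates < 1L))
    stop("replicate plan must give a count >= 1 for each of the 19 mixtures",
         call. = FALSE)
  rows <- rep(seq_len(19L), times = replicates)
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    rows <- sample(rows)
  }
  out <- blends[rows, , drop = FALSE]
  out <- data.frame(run_id = seq_along(rows), out, row.names = NULL)
  out$n_larvae <- as.integer(n_larvae)
  out$pupation <- NA_real_
  out$duration_days <- NA_real_
  out$pupal_weight_mg <- NA_real_
  out$emergence <- NA_real_
  out$excluded_responses <- ""
  validate_blend(run_blends(out), ludens_space())
  out
}

#' Published response surfaces of the A. ludens diet study
#'
#' The final fitted models for the four biological responses, as Scheffe
#' coefficient sets on the pseudo-component scale.  Pupation, duration and
#' pupal weight are on their original scales (proportion, days, mg); adult
#' emergence was modelled after an arcsine square-root transform and its
#' published proportion-scale coefficients are converted back onto the
#' transformed scale here (signed `asin(sqrt(|b|))`), so that predictions
#' are made on the modelling scale and back-transformed.
#'
#' Each surface carries the published 95% confidence interval of its linear
#' terms (where available), which equal the predicted responses at the
#' corner blends under the pseudo-component coding.
#'
#' @return A named list of `scheffe_surface` objects for `pupation`,
#'   `duration`, `pupal_weight` and `emergence`.
#' @seealso [scheffe_surface()], [ludens_criteria()]
#' @export
ludens_surfaces <- function() {
  sp <- ludens_space()
  tr <- function(p) asin(sqrt(p))
  list(
    pupation = scheffe_surface(
      coefficients = c(A = 0.83, B = 0.70, C = 0.42),
      parent = "linear", space = sp, response = "pupation",
      term_ci = rbind(A = c(0.70, 0.96), B = c(0.57, 0.84),
                      C = c(0.29, 0.55))),
    duration = scheffe_surface(
      coefficients = c(A = 9.10, B = 10.81, C = 11.30,
                       AB = -0.32, AC = -0.92, BC = -0.70,
                       A2BC = 59.32, AB2C = -52.62),
      parent = "special_quartic", space = sp, response = "duration",
      term_ci = rbind(A = c(8.47, 9.46), B = c(10.45, 11.17),
                      C = c(10.93, 11.66))),
    pupal_weight = scheffe_surface(
      coefficients = c(A = 17.98, B = 17.59, C = 15.64,
                       AC = 3.94, BC = -8.44),
      parent = "quadratic", space = sp, response = "pupal_weight",
      term_ci = rbind(A = c(16.39, 19.56), B = c(15.84, 19.35),
                      C = c(13.89, 17.39))),
    emergence = scheffe_surface(
      coefficients = c(A = tr(0.90), B = tr(0.83), C = tr(0.99),
                       BC = -tr(0.81)),
      parent = "quadratic", space = sp, response = "emergence",
      transform = "arcsine_sqrt"))
}

#' Cost anchors of the A. ludens diet study
#'
#' Three published cost figures that pin down the three ingredient unit
#' prices: the annual ingredient cost of the standard blend (USD 791,716),
#' the annual cost of the high-corn-flour corner blend (USD 596,525), and
#' the percent saving of the high-corncob corner blend (21.29%), all for an
#' annual production of 1,730.29 tons of finished diet.
#'
#' @return A list with elements `reference`, `alt`, `third` (each holding a
#'   blend and its anchor value) and `annual_tonnage`.
#' @seealso [solve_unit_prices()]
#' @export
ludens_cost_anchors <- function() {
  list(
    reference = list(blend = c(6, 5.3, 19), annual_cost = 791716),
    alt       = list(blend = c(3, 8.3, 19), annual_cost = 596525),
    third     = list(blend = c(3, 5.3, 22), savings_percent = 21.29),
    annual_tonnage = 1730.29)
}

#' Optimization criteria of the A. ludens diet study
#'
#' The acceptance limits used in the study's overlay optimization: each
#' biological response must stay within the 95% confidence limit predicted
#' for the standard mass-rearing blend.  Because the standard blend is the
#' yeast corner of the design space, those limits are the confidence bounds
#' of the linear yeast term: pupation >= 0.70, larval duration <= 9.46
#' days, pupal weight >= 16.39 mg.  For adult emergence the published
#' interval at the corner is degenerate on the proportion scale, and the
#' study's stated operational limit of 0.80 is used directly.
#'
#' @return A `criteria_set` (see [criteria_from_reference()]).
#' @export
ludens_criteria <- function() {
  new_criteria_set(list(
    pupation     = list(bound = "min", limit = 0.70, source = "reference-CI"),
    duration     = list(bound = "max", limit = 9.46, source = "reference-CI"),
    pupal_weight = list(bound = "min", limit = 16.39, source = "reference-CI"),
    emergence    = list(bound = "min", limit = 0.80, source = "stated-limit")))
}

#' Generating model for synthetic study data
#'
#' A [truth_model()] whose response surfaces are the published study fits,
#' with binomial sampling noise for the two proportion responses (cohorts
#' of 25 larvae) and Gaussian noise for duration (sd 0.45 days) and pupal
#' weight (sd 1.6 mg).
#'
#' @return A `truth_model`.
#' @export
ludens_truth <- function() {
  truth_model(surfaces = ludens_surfaces(),
              duration_sd = 0.45, pupal_weight_sd = 1.6)
}
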