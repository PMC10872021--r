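# The twelve-model family of Bayesian hierarchical variance models.
#
# Three model sets, each fit separately to thermal tolerance (CTmax) and to
# fitness (per-day r):
#
#  M1 (20 degC individuals only) -- microgeographic adaptation / fluctuating
#    selection:
#    M1-0 null (year fixed effect; trial random effect for CTmax only);
#    M1-1 adds a clone random effect (genetic variation);
#    M1-2 adds a pool random effect (among-pool differences);
#    M1-3 adds the pool thermal covariate as a fixed effect
#         (CTmax: hottest-month mean daily maximum; fitness: |mean pool
#          temperature - 20 degC|);
#    M1-4 = M1-1 with a separate clone variance per pool (fluctuating
#          selection: genetic variance differs among pools).
#
#  M2 (both developmental temperatures) -- developmental plasticity:
#    M2-0 null (year; clone + pool [+ trial] random effects, no temperature
#          term); M2-1 adds the developmental-temperature fixed effect
#          (plasticity); M2-2 adds daily temperature variation and its
#          interaction with developmental temperature; M2-3 likewise with
#          daily temperature predictability.
#
#  M3 (both temperatures; built from M1-1, no pool term) -- temperature
#    effects on heritability components. Intercept and year effect are
#    temperature-specific throughout:
#    M3-0 shared genetic and residual variance; M3-1 residual variance by
#    temperature; M3-2 genetic variance by temperature (clone deviations
#    drawn independently per temperature); M3-3 both by temperature.

MODEL_IDS <- c("M1-0", "M1-1", "M1-2", "M1-3", "M1-4",
               "M2-0", "M2-1", "M2-2", "M2-3",
               "M3-0", "M3-1", "M3-2", "M3-3")

#' The frozen model registry
#'
#' Returns the declarative specification of one of the twelve hierarchical
#' models for a given response. The registry is data: every downstream step
#' (design construction, sampling, likelihood evaluation) is driven by the
#' returned spec.
#'
#' @param model_id one of `"M1-0"`..`"M1-4"`, `"M2-0"`..`"M2-3"`,
#'   `"M3-0"`..`"M3-3"`.
#' @param response `"ctmax"` or `"fitness"`. Fitness models never include the
#'   thermal-trial random effect; the M3 family never includes the pool term.
#' @return an object of class `model_spec`: list with `model_id`, `response`,
#'   `data_subset` (`"dev20_only"` or `"both_temps"`), `fixed_terms`,
#'   `by_temp_intercept` (logical), `covariate` (pool covariate name or NA),
#'   `covariate_interaction` (logical), `random_terms` (named list term ->
#'   variance grouping `"shared"`, `"by_pool"` or `"by_dev_temp"`),
#'   `clone_by_temp_levels` (logical: clone deviations independent per
#'   temperature), `error_variance_grouping`.
#' @export
model_registry <- function(model_id, response = c("ctmax", "fitness")) {
  response <- match.arg(response)
  if (!model_id %in% MODEL_IDS) {
    stop("unknown model id '", model_id, "'; valid ids: ",
         paste(MODEL_IDS, collapse = ", "))
  }
  fam <- substr(model_id, 1, 2)
  idx <- as.integer(substr(model_id, 4, 4))

  spec <- list(
    model_id = model_id, response = response,
    data_subset = if (fam == "M1") "dev20_only" else "both_temps",
    by_temp_intercept = fam == "M3",
    dev_temp_effect = FALSE,
    covariate = NA_character_, covariate_interaction = FALSE,
    random_terms = list(),
    clone_by_temp_levels = FALSE,
    error_variance_grouping = "shared"
  )
  trial <- response == "ctmax"

  if (fam == "M1") {
    if (trial) spec$random_terms$trial <- "shared"
    if (idx >= 1) spec$random_terms$clone <- "shared"
    if (idx %in% c(2, 3)) spec$random_terms$pool <- "shared"
    if (idx == 3) {
      spec$covariate <- if (response == "ctmax")
        "hottest_month_mean_daily_max" else "abs_mean_minus_20"
    }
    if (idx == 4) spec$random_terms$clone <- "by_pool"
  } else if (fam == "M2") {
    if (trial) spec$random_terms$trial <- "shared"
    spec$random_terms$clone <- "shared"
    spec$random_terms$pool <- "shared"
    if (idx >= 1) spec$dev_temp_effect <- TRUE
    if (idx == 2) {
      spec$covariate <- "daily_sd"; spec$covariate_interaction <- TRUE
    }
    if (idx == 3) {
      spec$covariate <- "predictability_days"; spec$covariate_interaction <- TRUE
    }
  } else { # M3: built from M1-1, no pool term, temperature-specific location
    if (trial) spec$random_terms$trial <- "shared"
    spec$random_terms$clone <- if (idx %in% c(2, 3)) "by_dev_temp" else "shared"
    spec$clone_by_temp_levels <- idx %in% c(2, 3)
    spec$error_variance_grouping <-
      if (idx %in% c(1, 3)) "by_dev_temp" else "shared"
  }
  structure(spec, class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model", x$model_id, "for response", x$response, "\n")
  cat("  data:", x$data_subset, "\n")
  fx <- c("intercept", "year")
  if (x$by_temp_intercept) fx <- paste0(fx, " (by dev temp)")
  if (x$dev_temp_effect) fx <- c(fx, "dev_temp")
  if (!is.na(x$covariate)) {
    fx <- c(fx, x$covariate)
    if (x$covariate_interaction) fx <- c(fx, paste0("dev_temp:", x$covariate))
  }
  cat("  fixed:", paste(fx, collapse = ", "), "\n")
  if (length(x$random_terms)) {
    cat("  random:", paste(names(x$random_terms),
                           paste0("(", unlist(x$random_terms), ")"),
                           collapse = ", "), "\n")
  } else cat("  random: none\n")
  cat("  error variance:", x$error_variance_grouping, "\n")
  invisible(x)
}

#' All valid model identifiers
#' @return character vector of the twelve model ids in registry order.
#' @export
model_ids <- function() MODEL_IDS

#' Default MCMC settings per model, as used in the original analyses
#'
#' Simpler models (M1-0..M1-3) use 10,000 iterations with 5,000 burn-in and
#' thinning of 5; M1-4 uses 30,000 iterations with 25,000 burn-in and
#' thinning of 5; the M2 and M3 families use 75,000 iterations with 25,000
#' burn-in and thinning of 50.
#'
#' @param model_id a valid model id.
#' @param n_chains number of chains (>= 2 so convergence can be assessed).
#' @return list with `n_iterations`, `n_burn_in`, `thin`, `n_chains`.
#' @export
default_mcmc_settings <- function(model_id, n_chains = 3) {
  if (!model_id %in% MODEL_IDS) stop("unknown model id '", model_id, "'")
  if (model_id %in% c("M1-0", "M1-1", "M1-2", "M1-3")) {
    list(n_iterations = 10000L, n_burn_in = 5000L, thin = 5L,
         n_chains = n_chains)
  } else if (model_id == "M1-4") {
    list(n_iterations = 30000L, n_burn_in = 25000L, thin = 5L,
         n_chains = n_chains)
  } else {
    list(n_iterations = 75000L, n_burn_in = 25000L, thin = 50L,
         n_chains = n_chains)
  }
}
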