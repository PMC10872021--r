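# Synthetic-study generator with known ground truth.
#
# Emulates the field design: 10 rock pools differing in thermal regime,
# ~13 clones per pool collected over two years, 2-3 replicate individuals
# per clone at each developmental temperature (20 / 25 degC), CTmax measured
# in trial batches of ~15 individuals, and per-individual life histories
# (first and second broods) constructed by inverting the Lotka-Euler map so
# that the realized intrinsic rate of increase matches the latent fitness up
# to integer brood-size rounding.
#
# Everything is driven by a config + master seed and is bit-for-bit
# reproducible.

#' Default synthetic-study configuration
#'
#' Defaults mirror the field study's structure and scale: 10 pools (4 sampled
#' in both years, 2 only in the first, 4 only in the second), 13 clones per
#' pool, 2-3 individuals per clone per developmental temperature, CTmax trial
#' batches of ~15. Phenotype parameters are on the scales observed in such
#' assays: CTmax intercept 37.5 degC with a +0.9 degC later-year effect and a
#' +0.4 degC developmental-plasticity effect; genetic SDs 0.4 (20 degC) and
#' 0.2 (25 degC); residual SD 0.45; fitness intercept 0.189 per day with
#' +0.056 year and +0.029 plasticity effects.
#'
#' @param ... named overrides of any default (nested lists are replaced
#'   wholesale).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    n_pools = 10,
    clones_per_pool = 13,
    individuals_per_clone_per_temp = c(2, 3),
    years = c(2017, 2018),
    # pools sampled: 1-4 both years, 5-6 first year only, 7-10 second only
    pool_years = list(both = 1:4, first_only = 5:6, second_only = 7:10),
    trial_batch_size = 15,
    climate = list(
      window = c(166, 288),            # day-of-year, Jun 15 - Oct 15
      peak_day = 215,                  # trend peaks early August
      peak_daily_max = seq(24, 33, length.out = 10), # per-pool trend peak, degC
      curvature = 1.5e-3,              # degC per day^2 decline off-peak
      residual_sd = seq(0.6, 2.4, length.out = 10),  # degC
      variogram_range = seq(2, 9, length.out = 10),  # days
      diurnal_offset = 3               # daily mean = daily max - offset
    ),
    ctmax = list(
      intercept = 37.5, year_effect = 0.9, dev_temp_effect = 0.4,
      sigma_clone = c(`20` = 0.4, `25` = 0.2), clone_by_temp = TRUE,
      sigma_pool = 0, sigma_trial = 0.2, sigma_resid = c(`20` = 0.45, `25` = 0.45),
      covariate = NA_character_, covariate_slope = 0, interaction_slope = 0
    ),
    fitness = list(
      intercept = 0.189, year_effect = 0.056, dev_temp_effect = 0.029,
      sigma_clone = c(`20` = 0.02, `25` = 0.03), clone_by_temp = TRUE,
      sigma_pool = 0.01, sigma_trial = 0, sigma_resid = c(`20` = 0.03, `25` = 0.04),
      covariate = NA_character_, covariate_slope = 0, interaction_slope = 0
    ),
    life_history = list(
      age_first_brood = 8:12,          # days
      brood_gap = 3:5,                 # days between broods
      first_brood_share = 0.45,        # share of reproductive value in brood 1
      max_retries = 20
    )
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(over[[nm]])) cfg[[nm]][[k]] <- over[[nm]][[k]]
    } else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate one pool's daily temperature series
#'
#' Daily maxima are a quadratic seasonal trend plus multivariate-normal
#' deviations with Gaussian temporal correlation `exp(-(h/range)^2)`
#' (generated through a Cholesky decomposition of the correlation matrix,
#' jittered if numerically non-positive-definite). Daily means are the maxima
#' minus a positive diurnal offset.
#'
#' @param config a `synthetic_config`.
#' @param pool pool index (1-based) selecting the per-pool climate knobs.
#' @param seed integer seed.
#' @return a temperature series data frame (see
#'   [validate_temperature_series()]).
#' @export
generate_temperature <- function(config, pool, seed) {
  cl <- config$climate
  days <- cl$window[1]:cl$window[2]
  nd <- length(days)
  if (nd < 30) stop("temperature window must span at least 30 days")
  trend <- cl$peak_daily_max[pool] - cl$curvature * (days - cl$peak_day)^2
  rng <- cl$variogram_range[pool]
  sdr <- cl$residual_sd[pool]
  set.seed(seed)
  if (sdr > 0) {
    h <- abs(outer(days, days, "-"))
    C <- exp(-(h / rng)^2)
    ch <- NULL
    for (jit in c(0, 1e-8, 1e-6, 1e-4)) {
      ch <- tryCatch(chol(C + diag(jit, nd)), error = function(e) NULL)
      if (!is.null(ch)) {
        if (jit > 0) message("correlation matrix jittered (", jit,
                             ") for positive definiteness")
        break
      }
    }
    if (is.null(ch)) stop("correlation matrix not positive definite")
    dev <- as.numeric(crossprod(ch, rnorm(nd))) * sdr
  } else dev <- rep(0, nd)
  daily_max <- trend + dev
  data.frame(
    pool_id = sprintf("pool%02d", pool),
    day = days,
    daily_max = daily_max,
    daily_mean = daily_max - cl$diurnal_offset,
    stringsAsFactors = FALSE
  )
}

# the generating (true) pool climate, no fitting involved
true_pool_climate <- function(config) {
  cl <- config$climate
  days <- cl$window[1]:cl$window[2]
  aug <- days[month_from_doy(days) == 8]
  rows <- lapply(seq_len(config$n_pools), function(k) {
    trend <- function(d) cl$peak_daily_max[k] - cl$curvature * (d - cl$peak_day)^2
    data.frame(
      pool_id = sprintf("pool%02d", k),
      mean_daily_mean = mean(trend(days)) - cl$diurnal_offset,
      hottest_month_mean_daily_max = mean(trend(aug)),
      daily_sd = cl$residual_sd[k],
      predictability_days = cl$variogram_range[k],
      seasonal_range = max(trend(days)) - min(trend(days)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$abs_mean_minus_20 <- abs(out$mean_daily_mean - 20)
  out
}

# invert the Euler map: choose brood ages and integer sizes so the realized
# r is close to the latent target
invert_euler <- function(r_target, lh) {
  r <- max(r_target, 0)
  for (try in seq_len(lh$max_retries)) {
    a1 <- sample(lh$age_first_brood, 1)
    a2 <- a1 + sample(lh$brood_gap, 1)
    m1 <- round(lh$first_brood_share * exp(r * a1))
    m2 <- round((1 - lh$first_brood_share) * exp(r * a2))
    if (m1 + m2 >= 1) {
      sol <- solve_euler(c(a1, a2)[c(m1, m2) > 0], c(m1, m2)[c(m1, m2) > 0])
      return(list(age1 = a1, size1 = m1, age2 = a2, size2 = m2,
                  realized_r = sol$r, rounding_error = sol$r - r))
    }
  }
  stop("could not attain r = ", r_target, " with integer brood sizes")
}

#' Generate a complete synthetic clonal study
#'
#' Draws pool, clone (optionally per-temperature), trial and residual effects
#' per the config for both responses; assigns CTmax trials in batches;
#' constructs per-individual life histories by inverting the Euler map from
#' each individual's latent fitness.
#'
#' @param config a `synthetic_config`.
#' @param seed integer master seed.
#' @param life_history build brood-level records by Euler inversion (default
#'   `TRUE`; turn off to skip that cost when only the observation tables are
#'   needed).
#' @return a `synthetic_study`: list with `config`, `seed`, `pool_climate`
#'   (generating truth), `individuals` (phenotype records, one row per
#'   individual), `observations` (`$ctmax` and `$fitness` observation
#'   tables), and `truth` (generating parameters and per-individual latent
#'   values).
#' @export
generate_phenotypes <- function(config, seed, life_history = TRUE) {
  set.seed(seed)
  climate <- true_pool_climate(config)
  yr1 <- config$years[1]; yr2 <- config$years[2]
  pool_year <- lapply(seq_len(config$n_pools), function(k) {
    if (k %in% config$pool_years$both) c(yr1, yr2)
    else if (k %in% config$pool_years$first_only) yr1
    else yr2
  })

  # clones: each belongs to one pool and one collection year
  clones <- do.call(rbind, lapply(seq_len(config$n_pools), function(k) {
    yrs <- pool_year[[k]]
    nc <- config$clones_per_pool
    data.frame(
      clone = sprintf("p%02dc%02d", k, seq_len(nc)),
      pool = sprintf("pool%02d", k),
      year = rep(yrs, length.out = nc),
      stringsAsFactors = FALSE
    )
  }))

  # individuals: 2-3 per clone per developmental temperature
  reps <- config$individuals_per_clone_per_temp
  ind <- do.call(rbind, lapply(seq_len(nrow(clones)), function(i) {
    n20 <- if (length(reps) > 1) sample(reps, 1) else reps
    n25 <- if (length(reps) > 1) sample(reps, 1) else reps
    data.frame(
      clone = clones$clone[i], pool = clones$pool[i], year = clones$year[i],
      dev_temp = c(rep(20, n20), rep(25, n25)),
      stringsAsFactors = FALSE
    )
  }))
  n <- nrow(ind)
  ind$individual_id <- sprintf("ind%04d", seq_len(n))

  # CTmax trial batches: haphazard assortment across temperatures
  perm <- sample(n)
  trial_of <- integer(n)
  trial_of[perm] <- (seq_len(n) - 1) %/% config$trial_batch_size + 1
  ind$trial <- sprintf("trial%02d", trial_of)

  draw_response <- function(par) {
    pool_eff <- setNames(rnorm(config$n_pools, 0, par$sigma_pool),
                         sprintf("pool%02d", seq_len(config$n_pools)))
    if (isTRUE(par$clone_by_temp)) {
      c20 <- setNames(rnorm(nrow(clones), 0, par$sigma_clone["20"]), clones$clone)
      c25 <- setNames(rnorm(nrow(clones), 0, par$sigma_clone["25"]), clones$clone)
      clone_eff <- ifelse(ind$dev_temp == 20, c20[ind$clone], c25[ind$clone])
    } else {
      c1 <- setNames(rnorm(nrow(clones), 0, par$sigma_clone[1]), clones$clone)
      clone_eff <- c1[ind$clone]
    }
    trial_eff <- if (par$sigma_trial > 0) {
      te <- setNames(rnorm(length(unique(ind$trial)), 0, par$sigma_trial),
                     sort(unique(ind$trial)))
      te[ind$trial]
    } else rep(0, n)
    dev25 <- as.numeric(ind$dev_temp == 25)
    covar <- 0
    if (!is.na(par$covariate)) {
      x <- climate[[par$covariate]][match(ind$pool, climate$pool_id)]
      covar <- par$covariate_slope * x + par$interaction_slope * x * dev25
    }
    sig_e <- par$sigma_resid[as.character(ind$dev_temp)]
    mu <- par$intercept + par$year_effect * as.numeric(ind$year == yr2) +
      par$dev_temp_effect * dev25 + pool_eff[ind$pool] + clone_eff +
      trial_eff + covar
    list(latent_mu = unname(mu), value = unname(mu + rnorm(n, 0, sig_e)))
  }

  ct <- draw_response(config$ctmax)
  fit <- draw_response(config$fitness)
  ind$ctmax <- ct$value
  ind$latent_r <- fit$value

  # life histories by Euler inversion
  if (life_history) {
    lh <- config$life_history
    inv <- lapply(ind$latent_r, invert_euler, lh = lh)
    ind$age_first_brood_d <- vapply(inv, `[[`, numeric(1), "age1")
    ind$size_first_brood <- vapply(inv, `[[`, numeric(1), "size1")
    ind$age_second_brood_d <- vapply(inv, `[[`, numeric(1), "age2")
    ind$size_second_brood <- vapply(inv, `[[`, numeric(1), "size2")
    ind$days_monitored <- pmax(15, ind$age_second_brood_d + sample(1:5, n, TRUE))
    ind$realized_r <- vapply(inv, `[[`, numeric(1), "realized_r")
    ind$rounding_error <- vapply(inv, `[[`, numeric(1), "rounding_error")
  }

  obs_from <- function(resp_col) {
    o <- data.frame(
      response = ind[[resp_col]], clone = ind$clone, pool = ind$pool,
      year = ind$year, dev_temp = ind$dev_temp,
      trial = if (resp_col == "ctmax") ind$trial else NA_character_,
      stringsAsFactors = FALSE
    )
    cbind(o, climate[match(ind$pool, climate$pool_id),
                     c("hottest_month_mean_daily_max", "abs_mean_minus_20",
                       "daily_sd", "predictability_days"), drop = FALSE],
          row.names = NULL)
  }
  fitness_col <- if (life_history) "realized_r" else "latent_r"

  structure(list(
    config = config, seed = seed,
    pool_climate = climate,
    individuals = ind,
    observations = list(ctmax = obs_from("ctmax"),
                        fitness = obs_from(fitness_col)),
    truth = list(ctmax = config$ctmax, fitness = config$fitness,
                 latent_mu_ctmax = ct$latent_mu,
                 latent_mu_fitness = fit$latent_mu,
                 latent_r = ind$latent_r)
  ), class = "synthetic_study")
}

#' Generate a full synthetic study including temperature series
#'
#' @inheritParams generate_phenotypes
#' @return a `synthetic_study` with an extra `temperature` element: a list of
#'   per-pool temperature series (seeds derived from the master seed).
#' @export
generate_study <- function(config, seed, life_history = TRUE) {
  study <- generate_phenotypes(config, seed, life_history = life_history)
  study$temperature <- lapply(seq_len(config$n_pools), function(k)
    generate_temperature(config, k, seed = (seed %% 1000000L) * 100L + k))
  study
}

#' Power and design-sensitivity simulation harness
#'
#' For each grid point, generates replicate synthetic studies, fits the
#' scenario's target model with reduced MCMC settings, and records whether
#' the 95% credible interval of the target coefficient excludes zero,
#' together with the bias and RMSE of the posterior-median estimate.
#' Replicate seeds are derived deterministically from the master seed.
#'
#' Scenarios:
#' * `"m13_slope"` -- slope of the hottest-month pool temperature on CTmax
#'   (model M1-3); grid = true slope values (degC CTmax per degC pool).
#' * `"m22_interaction"` -- interaction of daily temperature variation with
#'   developmental temperature (model M2-2); grid = true interaction slopes.
#' * `"m23_interaction"` -- likewise for predictability (model M2-3).
#' * `"inds_per_clone"` -- design sensitivity: grid = individuals per clone
#'   per temperature, at a fixed true slope given by `effect_size`
#'   (model M1-3).
#'
#' @param scenario one of the scenario names above.
#' @param grid numeric grid of true values (effect sizes, or individuals per
#'   clone for `"inds_per_clone"`).
#' @param n_replicates replicates per grid point.
#' @param seed master seed.
#' @param config base `synthetic_config` (scaled down by default for the
#'   harness: 6 clones per pool, 2 individuals per clone per temperature).
#' @param settings reduced MCMC settings used for every fit.
#' @param effect_size fixed true slope for `"inds_per_clone"`.
#' @return data frame with one row per grid point: `grid_value`, `power`
#'   (CI-exclusion fraction), `bias`, `rmse`, `n_replicates`.
#' @export
run_power_sim <- function(scenario = c("m13_slope", "m22_interaction",
                                       "m23_interaction", "inds_per_clone"),
                          grid, n_replicates, seed,
                          config = synthetic_config(
                            clones_per_pool = 6,
                            individuals_per_clone_per_temp = 2),
                          settings = list(n_iterations = 1200L,
                                          n_burn_in = 400L, thin = 2L,
                                          n_chains = 2L),
                          effect_size = 0.1) {
  scenario <- match.arg(scenario)
  if (length(grid) == 0) stop("grid must be non-empty")
  target <- switch(scenario,
    m13_slope = , inds_per_clone = list(
      model = "M1-3", coef = "hottest_month_mean_daily_max"),
    m22_interaction = list(model = "M2-2", coef = "dev_temp25:daily_sd"),
    m23_interaction = list(model = "M2-3",
                           coef = "dev_temp25:predictability_days"))
  spec <- model_registry(target$model, "ctmax")

  rows <- lapply(seq_along(grid), function(gi) {
    g <- grid[gi]
    cfg <- config
    if (scenario == "inds_per_clone") {
      cfg$individuals_per_clone_per_temp <- g
      true_val <- effect_size
      cfg$ctmax$covariate <- "hottest_month_mean_daily_max"
      cfg$ctmax$covariate_slope <- true_val
    } else if (scenario == "m13_slope") {
      true_val <- g
      cfg$ctmax$covariate <- "hottest_month_mean_daily_max"
      cfg$ctmax$covariate_slope <- g
    } else {
      true_val <- g
      cfg$ctmax$covariate <- if (scenario == "m22_interaction")
        "daily_sd" else "predictability_days"
      cfg$ctmax$interaction_slope <- g
    }
    est <- excl <- numeric(n_replicates)
    for (j in seq_len(n_replicates)) {
      rep_seed <- ((seed %% 100000L) * 1000L + gi * 311L + j) %% .Machine$integer.max
      study <- generate_phenotypes(cfg, rep_seed, life_history = FALSE)
      fit <- sample_posterior(spec, study$observations$ctmax,
                              settings = settings, seed = rep_seed)
      d <- fit$draws[, target$coef]
      ci <- quantile(d, c(0.025, 0.975))
      excl[j] <- as.numeric(ci[1] > 0 || ci[2] < 0)
      est[j] <- median(d)
    }
    data.frame(scenario = scenario, grid_value = g, power = mean(excl),
               bias = mean(est) - true_val,
               rmse = sqrt(mean((est - true_val)^2)),
               n_replicates = n_replicates, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
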