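# synthetic-study generator: determinism, construction identities,
# statistical faithfulness, and the power harness plumbing

test_that("identical config and seed reproduce a study bit-for-bit", {
  cfg <- synthetic_config(clones_per_pool = 4)
  s1 <- generate_phenotypes(cfg, seed = 33)
  s2 <- generate_phenotypes(cfg, seed = 33)
  expect_identical(s1$individuals, s2$individuals)
  expect_identical(s1$observations, s2$observations)
  t1 <- generate_temperature(cfg, 2, seed = 12)
  t2 <- generate_temperature(cfg, 2, seed = 12)
  expect_identical(t1, t2)
})

test_that("zero residual SD reproduces the seasonal trend exactly", {
  cfg <- synthetic_config(climate = list(residual_sd = rep(0, 10)))
  ser <- generate_temperature(cfg, 4, seed = 9)
  cl <- cfg$climate
  trend <- cl$peak_daily_max[4] - cl$curvature * (ser$day - cl$peak_day)^2
  expect_equal(ser$daily_max, trend)
  expect_equal(ser$daily_mean, trend - cl$diurnal_offset)
})

test_that("the empirical hottest month matches the trend's peak month", {
  cfg <- synthetic_config(climate = list(residual_sd = rep(0, 10)))
  ser <- generate_temperature(cfg, 7, seed = 1)
  fit <- fit_gls_quadratic(ser)
  mu <- tapply(ser$daily_max, thermoclone:::month_from_doy(ser$day), mean)
  expect_equal(as.integer(names(mu)[which.max(mu)]), 8) # peak day 215 = August
  pc <- summarize_pool(ser, fit, hottest_month = "empirical")
  pc8 <- summarize_pool(ser, fit, hottest_month = 8)
  expect_equal(pc$hottest_month_mean_daily_max, pc8$hottest_month_mean_daily_max)
})

test_that("with all variances and effects zeroed every phenotype is the intercept", {
  cfg <- synthetic_config(
    clones_per_pool = 3,
    ctmax = list(year_effect = 0, dev_temp_effect = 0,
                 sigma_clone = c(`20` = 0, `25` = 0), sigma_pool = 0,
                 sigma_trial = 0, sigma_resid = c(`20` = 0, `25` = 0)))
  st <- generate_phenotypes(cfg, seed = 2, life_history = FALSE)
  expect_true(all(st$individuals$ctmax == cfg$ctmax$intercept))
})

test_that("a large generated study matches its variance components", {
  # clone-only variance: the SD across 20 degC phenotypes is sigma_clone(20)
  cfg <- synthetic_config(
    n_pools = 10, clones_per_pool = 100, individuals_per_clone_per_temp = 1,
    ctmax = list(sigma_clone = c(`20` = 0.4, `25` = 0.2), sigma_pool = 0,
                 sigma_trial = 0, sigma_resid = c(`20` = 0, `25` = 0),
                 year_effect = 0, dev_temp_effect = 0))
  st <- generate_phenotypes(cfg, seed = 41, life_history = FALSE)
  x20 <- st$individuals$ctmax[st$individuals$dev_temp == 20]
  x25 <- st$individuals$ctmax[st$individuals$dev_temp == 25]
  expect_equal(sd(x20), 0.4, tolerance = 0.05)
  expect_equal(sd(x25), 0.2, tolerance = 0.05)
  # residual-only variance likewise
  cfg2 <- synthetic_config(
    n_pools = 10, clones_per_pool = 100, individuals_per_clone_per_temp = 1,
    ctmax = list(sigma_clone = c(`20` = 0, `25` = 0), sigma_pool = 0,
                 sigma_trial = 0, sigma_resid = c(`20` = 0.45, `25` = 0.45),
                 year_effect = 0, dev_temp_effect = 0))
  st2 <- generate_phenotypes(cfg2, seed = 42, life_history = FALSE)
  expect_equal(sd(st2$individuals$ctmax), 0.45, tolerance = 0.05)
})

test_that("study structure mirrors the field design", {
  cfg <- synthetic_config()
  st <- generate_phenotypes(cfg, seed = 3, life_history = FALSE)
  ind <- st$individuals
  expect_equal(length(unique(ind$pool)), 10)
  expect_equal(length(unique(ind$clone)), 130)
  reps <- table(ind$clone, ind$dev_temp)
  expect_true(all(reps %in% 2:3))
  # trial batches near the configured size
  tb <- table(ind$trial)
  expect_true(all(tb <= 15))
  expect_equal(length(unique(ind$year)), 2)
  # covariates constant within pool
  for (cv in c("hottest_month_mean_daily_max", "daily_sd")) {
    expect_true(all(tapply(st$observations$ctmax[[cv]],
                           st$observations$ctmax$pool,
                           function(v) length(unique(v))) == 1))
  }
})

test_that("unattainable integer brood schedules fail after bounded retries", {
  lh <- list(age_first_brood = 8, brood_gap = 3, first_brood_share = 0.5,
             max_retries = 5)
  set.seed(1)
  # r = 0 with a 50/50 split rounds both broods to zero every time
  expect_error(thermoclone:::invert_euler(0, lh), "could not attain")
})

test_that("the power harness validates its grid and reports the schema", {
  expect_error(run_power_sim("m13_slope", numeric(0), 2, seed = 1),
               "non-empty")
  tab <- run_power_sim("m13_slope", grid = c(0.5), n_replicates = 2, seed = 2,
                       config = synthetic_config(
                         clones_per_pool = 3,
                         individuals_per_clone_per_temp = 2),
                       settings = list(n_iterations = 400L, n_burn_in = 100L,
                                       thin = 1L, n_chains = 2L))
  expect_equal(names(tab), c("scenario", "grid_value", "power", "bias",
                             "rmse", "n_replicates"))
  expect_true(tab$power >= 0 && tab$power <= 1)
})

test_that("a huge effect is always detected by the CI criterion", {
  tab <- run_power_sim("m13_slope", grid = 10, n_replicates = 3, seed = 5,
                       config = synthetic_config(
                         clones_per_pool = 4,
                         individuals_per_clone_per_temp = 2),
                       settings = list(n_iterations = 600L, n_burn_in = 200L,
                                       thin = 1L, n_chains = 2L))
  expect_equal(tab$power, 1)
})
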