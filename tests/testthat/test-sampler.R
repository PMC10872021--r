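# Gibbs sampler: conjugate correctness, determinism, shrinkage, invariances

test_that("degenerate data drives the error SD towards zero", {
  obs <- data.frame(response = rep(37, 60), clone = sprintf("c%02d", 1:60),
                    pool = "pool01", year = 2018, dev_temp = 20,
                    trial = NA_character_)
  fit <- sample_posterior(model_registry("M1-0", "fitness"), obs,
                          settings = quick_settings(), seed = 3)
  expect_lt(median(fit$draws[, "sigma_resid"]), 0.05)
})

test_that("identical seed and settings give identical draws", {
  obs <- clone_obs(n_clones = 15, reps = 2, seed = 8)
  spec <- model_registry("M1-1", "fitness")
  f1 <- sample_posterior(spec, obs, settings = quick_settings(), seed = 99)
  f2 <- sample_posterior(spec, obs, settings = quick_settings(), seed = 99)
  expect_identical(f1$draws, f2$draws)
})

test_that("draws are invariant to the input row order", {
  obs <- clone_obs(n_clones = 15, reps = 2, seed = 8)
  spec <- model_registry("M1-1", "fitness")
  set.seed(1); perm <- sample(nrow(obs))
  f1 <- sample_posterior(spec, obs, settings = quick_settings(), seed = 99)
  f2 <- sample_posterior(spec, obs[perm, ], settings = quick_settings(),
                         seed = 99)
  expect_identical(f1$draws, f2$draws)
})

test_that("every SD draw respects the uniform prior support", {
  obs <- clone_obs(n_clones = 20, reps = 2, seed = 12)
  fit <- sample_posterior(model_registry("M1-1", "fitness"), obs,
                          settings = quick_settings(), seed = 4)
  sds <- fit$draws[, c(fit$par_groups$sd, fit$par_groups$err)]
  expect_true(all(sds > 0 & sds < 100))
  expect_true(all(is.finite(fit$draws[, fit$par_groups$beta])))
})

test_that("clone effects shrink the raw clone means towards zero", {
  obs <- clone_obs(n_clones = 25, reps = 5, intercept = 10,
                   sigma_clone = 1, sigma_resid = 0.5, seed = 21)
  fit <- sample_posterior(model_registry("M1-1", "fitness"), obs,
                          settings = quick_settings(), seed = 31)
  u_cols <- fit$par_groups$u
  u_hat <- colMeans(fit$draws[, u_cols])
  b0 <- mean(fit$draws[, "intercept"])
  raw <- tapply(obs$response, obs$clone, mean)[sub("clone\\[(.*)\\]", "\\1",
                                                   u_cols)] - b0
  # weighted shrinkage: each effect keeps its sign but moves towards zero
  # (clones with tiny raw deviations are allowed intercept-noise slack)
  strong <- abs(raw) > 0.3
  expect_true(all(sign(u_hat[strong]) == sign(raw[strong])))
  expect_true(all(abs(u_hat) <= abs(raw) + 0.05))
  slope <- sum(u_hat * raw) / sum(raw^2)
  expect_gt(slope, 0)
  expect_lt(slope, 1)
})

test_that("rescaling the response rescales variances and leaves H2 draws fixed", {
  cfg <- synthetic_config(clones_per_pool = 6)
  st <- generate_phenotypes(cfg, seed = 5, life_history = FALSE)
  spec <- model_registry("M3-3", "fitness")
  k <- 3
  obs <- st$observations$ctmax
  obs$trial <- NA_character_
  obs2 <- obs
  obs2$response <- k * obs2$response
  f1 <- sample_posterior(spec, obs, settings = quick_settings(), seed = 77,
                         priors = list(coef_var = 1000, sd_upper = 100))
  f2 <- sample_posterior(spec, obs2, settings = quick_settings(), seed = 77,
                         priors = list(coef_var = 1000 * k^2,
                                       sd_upper = 100 * k))
  h1 <- heritability(f1, "20")
  h2 <- heritability(f2, "20")
  expect_equal(h2$draws$V_G, k^2 * h1$draws$V_G, tolerance = 1e-9)
  expect_equal(h2$draws$V_E, k^2 * h1$draws$V_E, tolerance = 1e-9)
  expect_equal(h2$draws$H2, h1$draws$H2, tolerance = 1e-9)
})

test_that("a variance group with one level warns but still fits", {
  obs <- clone_obs(n_clones = 12, reps = 2, seed = 2)
  obs$pool <- c("pool01", "pool02")[c(rep(1, 22), 2, 2)] # pool02: 1 clone
  spec <- model_registry("M1-4", "fitness")
  expect_warning(frame <- build_model_frame(spec, obs), "weakly identified")
})

test_that("misshapen inputs are rejected with clear errors", {
  obs <- clone_obs(n_clones = 5, reps = 2, seed = 3)
  spec <- model_registry("M1-1", "fitness")
  bad <- obs; bad$response[1] <- NA
  expect_error(build_model_frame(spec, bad), "non-finite")
  bad2 <- obs; bad2$dev_temp[1] <- 30
  expect_error(build_model_frame(spec, bad2), "20 or 25")
  bad3 <- obs; bad3$pool[1] <- "pool09" # clone c001 now in two pools
  expect_error(build_model_frame(spec, bad3), "more than one pool")
  expect_error(sample_posterior(spec, obs, seed = 1,
                                settings = list(n_iterations = 100L,
                                                n_burn_in = 10L, thin = 1L,
                                                n_chains = 1L)),
               "at least 2 chains")
})

test_that("the sampler agrees with an independent JAGS fit", {
  obs <- clone_obs(n_clones = 50, reps = 3, intercept = 37.5,
                   sigma_clone = 0.4, sigma_resid = 0.45, seed = 14)
  spec <- model_registry("M1-1", "fitness")
  fit <- sample_posterior(spec, obs, seed = 6,
                          settings = list(n_iterations = 4000L,
                                          n_burn_in = 1000L, thin = 3L,
                                          n_chains = 2L))
  library(rjags)
  model_str <- "model {
    for (i in 1:N) { y[i] ~ dnorm(b0 + u[cl[i]], tau_e) }
    for (j in 1:C) { u[j] ~ dnorm(0, tau_c) }
    b0 ~ dnorm(0, 0.001)
    sd_c ~ dunif(0, 100); tau_c <- pow(sd_c, -2)
    sd_e ~ dunif(0, 100); tau_e <- pow(sd_e, -2)
  }"
  jm <- jags.model(textConnection(model_str),
                   data = list(y = obs$response,
                               cl = as.integer(factor(obs$clone)),
                               N = nrow(obs), C = 50),
                   n.chains = 2, quiet = TRUE,
                   inits = list(.RNG.name = "base::Wichmann-Hill",
                                .RNG.seed = 7))
  update(jm, 1000, progress.bar = "none")
  js <- coda.samples(jm, c("b0", "sd_c", "sd_e"), n.iter = 6000, thin = 3,
                     progress.bar = "none")
  jd <- as.matrix(js)
  expect_equal(median(fit$draws[, "intercept"]), median(jd[, "b0"]),
               tolerance = 0.05)
  expect_equal(median(fit$draws[, "sigma_clone"]), median(jd[, "sd_c"]),
               tolerance = 0.08)
  expect_equal(median(fit$draws[, "sigma_resid"]), median(jd[, "sd_e"]),
               tolerance = 0.05)
})
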