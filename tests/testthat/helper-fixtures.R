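# shared fixtures: small observation tables and reduced MCMC settings

quick_settings <- function(n_chains = 2L) {
  list(n_iterations = 1200L, n_burn_in = 400L, thin = 2L, n_chains = n_chains)
}

# intercept + clone structure: n_clones clones, reps observations each
clone_obs <- function(n_clones = 40, reps = 3, intercept = 37.5,
                      sigma_clone = 0.4, sigma_resid = 0.45, seed = 1,
                      year = 2018, dev_temp = 20) {
  set.seed(seed)
  clone <- rep(sprintf("c%03d", seq_len(n_clones)), each = reps)
  ce <- rnorm(n_clones, 0, sigma_clone)
  data.frame(
    response = intercept + ce[rep(seq_len(n_clones), each = reps)] +
      rnorm(n_clones * reps, 0, sigma_resid),
    clone = clone, pool = "pool01", year = year, dev_temp = dev_temp,
    trial = NA_character_, stringsAsFactors = FALSE
  )
}

# fake posterior_draws carrying given named draw columns (for diagnostics and
# heritability tests that do not need a real model fit)
fake_draws <- function(draws_mat, chain = NULL) {
  structure(list(
    draws = draws_mat,
    chain = chain %||% rep(1:2, each = nrow(draws_mat) / 2),
    par_groups = list(beta = character(0),
                      sd = grep("^sigma_", colnames(draws_mat), value = TRUE),
                      err = character(0), u = character(0)),
    frame = NULL, settings = NULL, seed = NA
  ), class = "posterior_draws")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
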