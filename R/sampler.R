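# Gibbs sampler for the Gaussian hierarchical variance models.
#
# Observation model:
#   y_i = x_i' beta + c_clone(i) + p_pool(i) + t_trial(i) + e_i,
#   e_i ~ N(0, sigma_e[g(i)]^2)
# with random-effect SDs grouped "shared", "by_pool" (fluctuating-selection
# model) or "by_dev_temp" (heritability models), and the error SD optionally
# grouped by developmental temperature.
#
# Priors: N(0, 1000) on every coefficient (precision 0.001), Uniform(0, 100)
# on every standard deviation. Under the uniform SD prior the full
# conditional of a variance given its k effect values with sum of squares SS
# is inverse-gamma(shape = (k-1)/2, rate = SS/2) truncated to sd < 100; when
# the shape is not positive (k = 1) a stepping-out slice sampler on log(sd)
# is used instead.
#
# Updates: conjugate multivariate-normal draw for beta (weighted by the
# per-observation error precision), conjugate normal draws per random-effect
# level, truncated inverse-gamma / slice draws for the SDs. Chains are
# initialized overdispersed from the chain-specific seed.

#' Build the design and grouping structure for a model
#'
#' Continuous pool covariates are centred and scaled internally for mixing;
#' the affine map back to the raw-covariate basis is stored so reported
#' coefficients are on the original scale.
#'
#' @param spec a `model_spec` from [model_registry()].
#' @param data observation table: data frame with columns `response`,
#'   `clone`, `pool`, `year`, `dev_temp`, `trial` (CTmax only) and any pool
#'   covariate column the spec needs (constant within pool).
#' @return an object of class `model_frame` (internal structure consumed by
#'   [sample_posterior()] and [pointwise_loglik()]).
#' @export
build_model_frame <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  req <- c("response", "clone", "pool", "year", "dev_temp")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("observation table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(data$response))) stop("non-finite response values")
  if (!all(data$dev_temp %in% c(20, 25))) {
    stop("dev_temp must be 20 or 25 degC")
  }
  # every clone must map to exactly one pool
  cp <- unique(data[, c("clone", "pool")])
  if (anyDuplicated(cp$clone)) {
    stop("clone(s) mapped to more than one pool: ",
         paste(unique(cp$clone[duplicated(cp$clone)]), collapse = ", "))
  }
  if (spec$data_subset == "dev20_only") {
    data <- data[data$dev_temp == 20, , drop = FALSE]
    if (nrow(data) == 0) stop("no observations at 20 degC")
  }
  # canonical observation order: the sampler's draws (and the pointwise
  # log-likelihood order) are then invariant to the input row order
  ord <- order(data$clone, data$pool,
               if ("trial" %in% names(data)) as.character(data$trial) else
                 rep("", nrow(data)),
               data$year, data$dev_temp, data$response)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  n <- nrow(data)
  y <- as.numeric(data$response)
  dev25 <- as.numeric(data$dev_temp == 25)
  yr <- as.numeric(data$year == max(data$year)) # indicator for the later year
  if (length(unique(data$year)) == 1) yr <- rep(0, n)

  # ---- fixed-effect design (scaled basis) + affine map to raw basis ----
  cols <- list(); cn <- character(0)
  if (spec$by_temp_intercept) {
    cols <- list(`intercept[20]` = 1 - dev25, `intercept[25]` = dev25,
                 `year[20]` = yr * (1 - dev25), `year[25]` = yr * dev25)
  } else {
    cols <- list(intercept = rep(1, n), year = yr)
  }
  if (spec$dev_temp_effect) cols$dev_temp25 <- dev25
  cov_scale <- NULL
  if (!is.na(spec$covariate)) {
    if (!spec$covariate %in% names(data)) {
      stop("observation table lacks covariate column '", spec$covariate, "'")
    }
    x <- as.numeric(data[[spec$covariate]])
    m <- mean(x); s <- sd(x)
    if (!is.finite(s) || s == 0) stop("covariate '", spec$covariate,
                                      "' is constant; cannot be scaled")
    z <- (x - m) / s
    cols[[spec$covariate]] <- z
    if (spec$covariate_interaction) {
      cols[[paste0("dev_temp25:", spec$covariate)]] <- z * dev25
    }
    cov_scale <- list(center = m, scale = s)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  p <- ncol(X)
  # beta_raw = A %*% beta_scaled
  A <- diag(p)
  dimnames(A) <- list(colnames(X), colnames(X))
  if (!is.null(cov_scale)) {
    j <- spec$covariate
    base <- if (spec$by_temp_intercept) "intercept[20]" else "intercept"
    A[j, j] <- 1 / cov_scale$scale
    A[base, j] <- -cov_scale$center / cov_scale$scale
    if (spec$covariate_interaction) {
      ji <- paste0("dev_temp25:", spec$covariate)
      A[ji, ji] <- 1 / cov_scale$scale
      A["dev_temp25", ji] <- -cov_scale$center / cov_scale$scale
    }
  }

  # ---- random-effect blocks ----
  blocks <- list()
  for (term in names(spec$random_terms)) {
    grouping <- spec$random_terms[[term]]
    if (term == "trial") {
      if (!"trial" %in% names(data) || all(is.na(data$trial))) {
        stop("spec requires a trial term but the data has no trial column")
      }
      val <- as.character(data$trial)
    } else if (term == "clone" && spec$clone_by_temp_levels) {
      val <- paste0(data$clone, ":", data$dev_temp)
    } else {
      val <- as.character(data[[term]])
    }
    levels <- sort(unique(val))
    idx <- match(val, levels)
    vg_label <- switch(grouping,
      shared = rep("all", length(levels)),
      by_pool = {
        lv_pool <- data$pool[match(levels, val)]
        as.character(lv_pool)
      },
      by_dev_temp = sub("^.*:", "", levels) # clone:temp levels
    )
    vgs <- sort(unique(vg_label))
    vg <- match(vg_label, vgs)
    counts <- tabulate(vg, length(vgs))
    if (any(counts < 2)) {
      warning("random term '", term, "': variance group(s) ",
              paste(vgs[counts < 2], collapse = ", "),
              " have < 2 levels; variance weakly identified")
    }
    blocks[[term]] <- list(
      term = term, grouping = grouping, idx = idx, levels = levels,
      n_levels = length(levels), var_group = vg, var_group_labels = vgs,
      n_var_groups = length(vgs)
    )
  }

  # ---- error-variance groups ----
  if (spec$error_variance_grouping == "by_dev_temp") {
    err_labels <- c("20", "25")
    err_group <- ifelse(dev25 == 1, 2L, 1L)
  } else {
    err_labels <- "all"
    err_group <- rep(1L, n)
  }

  structure(list(
    spec = spec, y = y, X = X, A = A, n = n, p = p,
    blocks = blocks, err_group = err_group, err_labels = err_labels,
    n_err_groups = length(err_labels), cov_scale = cov_scale,
    data = data
  ), class = "model_frame")
}

# truncated inverse-gamma draw for a variance given k effects with sum of
# squares SS, under the Uniform(0, upper) SD prior; slice fallback when the
# conjugate shape is not positive
draw_sd <- function(k, SS, upper = 100, current = 1) {
  shape <- (k - 1) / 2
  rate <- SS / 2
  if (shape > 0 && rate > 0) {
    for (i in 1:100) {
      tau <- 1 / rgamma(1, shape = shape, rate = rate)
      if (tau < upper^2) return(sqrt(tau))
    }
  }
  slice_sd(k, SS, upper, current)
}

# stepping-out slice sampler on log(sd) for target
#   log p(sd) = -k*log(sd) - SS/(2 sd^2),  sd in (0, upper)
slice_sd <- function(k, SS, upper, current) {
  logpost <- function(ls) {
    s <- exp(ls)
    if (s <= 0 || s >= upper) return(-Inf)
    -k * ls - SS / (2 * s^2) + ls # + Jacobian of the log transform
  }
  x0 <- log(min(max(current, 1e-6), upper * 0.99))
  ly <- logpost(x0) + log(runif(1))
  w <- 1
  lo <- x0 - w * runif(1); hi <- lo + w
  for (i in 1:50) { if (logpost(lo) < ly) break; lo <- lo - w }
  for (i in 1:50) { if (logpost(hi) < ly) break; hi <- hi + w }
  for (i in 1:100) {
    x1 <- runif(1, lo, hi)
    if (logpost(x1) >= ly) return(exp(x1))
    if (x1 < x0) lo <- x1 else hi <- x1
  }
  exp(x0)
}

#' Draw from the posterior of a hierarchical variance model
#'
#' Runs the built-in Gibbs sampler: conjugate normal updates for coefficients
#' and random-effect levels, truncated inverse-gamma/slice updates for the
#' standard deviations under their Uniform(0, 100) prior. Chains start from
#' overdispersed, seed-determined positions; identical seed and settings give
#' identical draws.
#'
#' @param spec a `model_spec`, or a `model_frame` from [build_model_frame()].
#' @param data observation table (ignored if `spec` is already a frame).
#' @param settings list with `n_iterations`, `n_burn_in`, `thin`, `n_chains`
#'   (see [default_mcmc_settings()]).
#' @param seed integer master seed.
#' @param priors list with `coef_var` (prior variance of coefficients,
#'   default 1000) and `sd_upper` (upper bound of the uniform SD prior,
#'   default 100).
#' @param fixed_error_sd optionally fix the error SD(s) at known value(s)
#'   instead of sampling them (used for conjugate checks).
#' @return an object of class `posterior_draws`: list with `draws` (matrix,
#'   retained draws by named parameters, coefficients on the raw-covariate
#'   basis), `chain` (chain index per draw), `frame`, `settings`, `seed`.
#' @export
sample_posterior <- function(spec, data = NULL, settings, seed,
                             priors = list(coef_var = 1000, sd_upper = 100),
                             fixed_error_sd = NULL) {
  frame <- if (inherits(spec, "model_frame")) spec else
    build_model_frame(spec, data)
  stopifnot(settings$n_iterations > settings$n_burn_in, settings$thin >= 1)
  if (settings$n_chains < 2) stop("use at least 2 chains")
  coef_var <- priors$coef_var %||% 1000
  sd_upper <- priors$sd_upper %||% 100

  y <- frame$y; X <- frame$X; n <- frame$n; p <- frame$p
  blocks <- frame$blocks
  n_keep <- floor((settings$n_iterations - settings$n_burn_in) /
                    settings$thin)

  # parameter naming
  beta_names <- colnames(X)
  sd_names <- character(0); u_names <- character(0)
  for (b in blocks) {
    sd_names <- c(sd_names, if (b$n_var_groups == 1)
      paste0("sigma_", b$term) else
      paste0("sigma_", b$term, "[", b$var_group_labels, "]"))
    u_names <- c(u_names, paste0(b$term, "[", b$levels, "]"))
  }
  err_names <- if (frame$n_err_groups == 1) "sigma_resid" else
    paste0("sigma_resid[", frame$err_labels, "]")
  par_names <- c(beta_names, sd_names, err_names, u_names)

  ols <- tryCatch(lm.fit(X, y)$coefficients, error = function(e) rep(0, p))
  ols[!is.finite(ols)] <- 0
  sy <- max(sd(y), 1e-3)

  # precomputed grouping structures: per-level sums via one cumsum over a
  # fixed ordering instead of rowsum's per-call sort
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    b$ord <- order(b$idx)
    b$counts <- tabulate(b$idx, b$n_levels)
    b$ends <- cumsum(b$counts)
    blocks[[bi]] <- b
  }
  group_sum <- function(v, b) {
    cs <- cumsum(v[b$ord])[b$ends]
    c(cs[1], diff(cs))
  }
  shared_err <- frame$n_err_groups == 1
  XtX <- crossprod(X)
  err_idx <- lapply(seq_len(frame$n_err_groups),
                    function(g) which(frame$err_group == g))

  all_draws <- vector("list", settings$n_chains)
  all_scaled <- vector("list", settings$n_chains)
  for (chain in seq_len(settings$n_chains)) {
    set.seed((seed %% 1000000L) * 1000L + chain)
    beta <- ols + rnorm(p, 0, sy)               # overdispersed start
    u <- lapply(blocks, function(b) rep(0, b$n_levels))
    sigma_u <- lapply(blocks, function(b)
      runif(b$n_var_groups, 0.2 * sy, 3 * sy))
    sigma_e <- if (is.null(fixed_error_sd))
      runif(frame$n_err_groups, 0.2 * sy, 3 * sy)
    else rep(fixed_error_sd, length.out = frame$n_err_groups)

    draws <- matrix(NA_real_, n_keep, length(par_names),
                    dimnames = list(NULL, par_names))
    scaled <- matrix(NA_real_, n_keep, p)
    keep_i <- 0L
    fitted_re <- rep(0, n)
    for (b in blocks) fitted_re <- fitted_re + 0 # zeros at start

    for (iter in seq_len(settings$n_iterations)) {
      # beta | rest
      r <- y - fitted_re
      if (shared_err) {
        wsc <- 1 / sigma_e[1]^2
        Aq <- wsc * XtX
        bvec <- wsc * crossprod(X, r)
      } else {
        w <- 1 / sigma_e[frame$err_group]^2
        Aq <- crossprod(X, X * w)
        bvec <- crossprod(X, w * r)
      }
      diag(Aq) <- diag(Aq) + 1 / coef_var
      ch <- chol(Aq)
      mu_b <- backsolve(ch, forwardsolve(t(ch), bvec))
      beta <- as.numeric(mu_b + backsolve(ch, rnorm(p)))
      xb <- as.numeric(X %*% beta)

      # random-effect levels and SDs, block by block
      for (bi in seq_along(blocks)) {
        b <- blocks[[bi]]
        fitted_re <- fitted_re - u[[bi]][b$idx]
        rb <- y - xb - fitted_re
        if (shared_err) {
          sw <- wsc * b$counts
          swy <- wsc * group_sum(rb, b)
        } else {
          sw <- group_sum(w, b)
          swy <- group_sum(w * rb, b)
        }
        prec <- sw + 1 / sigma_u[[bi]][b$var_group]^2
        mean_u <- swy / prec
        u[[bi]] <- mean_u + rnorm(b$n_levels) / sqrt(prec)
        fitted_re <- fitted_re + u[[bi]][b$idx]
        for (g in seq_len(b$n_var_groups)) {
          in_g <- b$var_group == g
          sigma_u[[bi]][g] <- draw_sd(sum(in_g), sum(u[[bi]][in_g]^2),
                                      sd_upper, sigma_u[[bi]][g])
        }
      }

      # error SD(s)
      if (is.null(fixed_error_sd)) {
        e <- y - xb - fitted_re
        for (g in seq_len(frame$n_err_groups)) {
          sigma_e[g] <- draw_sd(length(err_idx[[g]]), sum(e[err_idx[[g]]]^2),
                                sd_upper, sigma_e[g])
        }
        if (shared_err) wsc <- 1 / sigma_e[1]^2
      }

      if (iter > settings$n_burn_in &&
          (iter - settings$n_burn_in) %% settings$thin == 0 &&
          keep_i < n_keep) {
        keep_i <- keep_i + 1L
        draws[keep_i, seq_len(p)] <- as.numeric(frame$A %*% beta)
        scaled[keep_i, ] <- beta
        draws[keep_i, sd_names] <- unlist(sigma_u)
        draws[keep_i, err_names] <- sigma_e
        draws[keep_i, u_names] <- unlist(u)
      }
    }
    all_draws[[chain]] <- draws[seq_len(keep_i), , drop = FALSE]
    all_scaled[[chain]] <- scaled[seq_len(keep_i), , drop = FALSE]
  }

  structure(list(
    draws = do.call(rbind, all_draws),
    beta_scaled = do.call(rbind, all_scaled),
    chain = rep(seq_len(settings$n_chains),
                vapply(all_draws, nrow, integer(1))),
    par_groups = list(beta = beta_names, sd = sd_names, err = err_names,
                      u = u_names),
    frame = frame, settings = settings, seed = seed,
    fixed_error_sd = fixed_error_sd
  ), class = "posterior_draws")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws for model", x$frame$spec$model_id,
      "(", x$frame$spec$response, ")\n")
  cat("  ", nrow(x$draws), "retained draws,",
      length(unique(x$chain)), "chains,",
      x$frame$n, "observations\n")
  show <- c(x$par_groups$beta, x$par_groups$sd, x$par_groups$err)
  s <- t(apply(x$draws[, show, drop = FALSE], 2, function(v)
    c(median = median(v), lo95 = quantile(v, 0.025),
      hi95 = quantile(v, 0.975))))
  colnames(s) <- c("median", "2.5%", "97.5%")
  print(round(s, 4))
  invisible(x)
}

# posterior mean response surface per draw: n x S matrix
posterior_mu <- function(fit) {
  frame <- fit$frame
  mu <- tcrossprod(frame$X, fit$beta_scaled) # n x S
  for (bi in seq_along(frame$blocks)) {
    b <- frame$blocks[[bi]]
    un <- paste0(b$term, "[", b$levels, "]")
    u_draws <- fit$draws[, un, drop = FALSE] # S x L
    mu <- mu + t(u_draws)[b$idx, , drop = FALSE]
  }
  mu
}

# error sd per observation per draw: n x S matrix
posterior_sigma_obs <- function(fit) {
  frame <- fit$frame
  se <- fit$draws[, fit$par_groups$err, drop = FALSE] # S x G
  t(se)[frame$err_group, , drop = FALSE]
}

#' Pointwise conditional log-likelihood matrix
#'
#' Entry (s, i) is the log normal density of observation i under draw s's
#' coefficients, its sampled random-effect levels, and the error SD of the
#' observation's variance group -- the conditional likelihood conventionally
#' exported to LOO machinery.
#'
#' @param fit a `posterior_draws` object.
#' @return matrix, draws by observations.
#' @export
pointwise_loglik <- function(fit) {
  stopifnot(inherits(fit, "posterior_draws"))
  mu <- posterior_mu(fit)          # n x S
  sdo <- posterior_sigma_obs(fit)  # n x S
  y <- fit$frame$y
  t(dnorm(y, mu, sdo, log = TRUE)) # S x n
}
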