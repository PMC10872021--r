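# Pareto smoothed importance sampling leave-one-out cross-validation.
#
# For each observation the raw importance ratios are proportional to
# exp(-loglik). The largest M = min(ceil(0.2 S), ceil(3 sqrt(S))) ratios are
# replaced by the expected order statistics of a generalized Pareto
# distribution fitted to the tail (Zhang-Stephens profile-posterior
# estimator), then all weights are truncated at the raw maximum. The
# pointwise expected log predictive density is the log of the
# importance-weighted average of exp(loglik), computed with log-sum-exp
# stability.

# Zhang & Stephens (2009) estimator for the generalized Pareto distribution
# fitted to exceedances x > 0. Returns shape k and scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  j <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  bs <- 1 / x[n] + (1 - sqrt(m / (j - 0.5))) / (prior_bs * xstar)
  ks <- vapply(bs, function(b) -mean(log1p(-b * x)), numeric(1))
  L <- n * (log(bs / ks) + ks - 1)
  wts <- 1 / vapply(seq_len(m), function(i)
    sum(exp(L - L[i])), numeric(1))
  b_hat <- sum(bs * wts)
  k_hat <- -mean(log1p(-b_hat * x))
  sigma_hat <- k_hat / b_hat
  # weakly-informative regularization of k towards 0.5 (stabilizes small tails)
  k_hat <- (n * k_hat + 5) / (n + 10)
  list(k = k_hat, sigma = sigma_hat)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma * expm1(-k * log1p(-p)) / k
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# smooth one vector of log importance ratios; returns list(log_weights, k)
psis_smooth <- function(lw) {
  S <- length(lw)
  M <- min(ceiling(0.2 * S), ceiling(3 * sqrt(S)))
  lw_max <- max(lw)
  if (M < 5) return(list(log_weights = lw, k = Inf))
  ord <- order(lw) # stable ties
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exceed <- exp(lw[tail_ids] - lw_max) - exp(cutoff - lw_max)
  if (all(exceed <= 0) || length(unique(lw[tail_ids])) == 1) {
    return(list(log_weights = lw, k = -Inf)) # degenerate flat tail
  }
  fit <- gpd_fit(exceed)
  if (!is.finite(fit$k)) return(list(log_weights = lw, k = fit$k))
  pr <- (seq_len(M) - 0.5) / M
  qs <- vapply(pr, gpd_quantile, numeric(1), k = fit$k, sigma = fit$sigma)
  smoothed <- log(exp(cutoff - lw_max) + qs) + lw_max
  lw2 <- lw
  lw2[tail_ids] <- pmin(smoothed, lw_max) # truncate at the raw maximum
  list(log_weights = lw2, k = fit$k)
}

#' PSIS-LOO from a pointwise log-likelihood matrix
#'
#' @param loglik matrix, posterior draws (rows) by observations (columns),
#'   of conditional log-likelihood values (see [pointwise_loglik()]).
#' @return an object of class `loo_result`: list with `elpd_loo`, `p_eff`,
#'   `se_elpd`, `pointwise_elpd`, `pointwise_lpd`, `pareto_k`, `n_obs`,
#'   `n_draws`, and `warnings` (observations with Pareto k > 0.7, whose
#'   estimates are unreliable).
#' @export
psis_loo <- function(loglik) {
  if (!is.matrix(loglik) || any(!is.finite(loglik))) {
    stop("loglik must be a finite draws-by-observations matrix")
  }
  S <- nrow(loglik); n <- ncol(loglik)
  if (S < 100) stop("need at least 100 draws, got ", S)
  elpd <- numeric(n); lpd <- numeric(n); k <- numeric(n)
  for (i in seq_len(n)) {
    ll <- loglik[, i]
    sm <- psis_smooth(-ll)
    lw <- sm$log_weights
    k[i] <- sm$k
    elpd[i] <- log_sum_exp(lw + ll) - log_sum_exp(lw)
    lpd[i] <- log_sum_exp(ll) - log(S)
  }
  res <- list(
    elpd_loo = sum(elpd), p_eff = sum(lpd - elpd),
    se_elpd = sqrt(n * var(elpd)),
    pointwise_elpd = elpd, pointwise_lpd = lpd, pareto_k = k,
    n_obs = n, n_draws = S,
    warnings = which(k > 0.7)
  )
  if (length(res$warnings)) {
    warning(length(res$warnings),
            " observation(s) with Pareto k > 0.7; LOO estimate unreliable ",
            "for those observations")
  }
  structure(res, class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd = %.1f (SE %.2f), p_eff = %.1f, n = %d\n",
              x$elpd_loo, x$se_elpd, x$p_eff, x$n_obs))
  if (length(x$warnings)) {
    cat("  ", length(x$warnings), "observation(s) with Pareto k > 0.7\n")
  }
  invisible(x)
}

#' Compare models by expected log predictive density
#'
#' Rows are sorted by decreasing `elpd_loo`; each model's `delta_elpd` is its
#' ELPD minus the top model's, with the SE of the pointwise ELPD difference.
#' A model is `supported` when the magnitude of its ELPD deficit is within
#' twice the SE of the difference (models essentially tied with the best).
#'
#' @param results named list of `loo_result` objects (names = model ids), or
#'   a list of `list(model_id =, loo =)` pairs.
#' @return data frame with columns `model_id`, `elpd_loo`, `p_eff`,
#'   `delta_elpd`, `se_delta`, `supported`, sorted by `elpd_loo` descending
#'   (ties broken by input order).
#' @export
compare_models <- function(results) {
  if (is.null(names(results)) || any(names(results) == "")) {
    stop("results must be a named list (names are model ids)")
  }
  ns <- vapply(results, function(r) r$n_obs, numeric(1))
  if (length(unique(ns)) != 1) {
    stop("models were evaluated on different observation counts: ",
         paste(ns, collapse = ", "))
  }
  elpds <- vapply(results, function(r) r$elpd_loo, numeric(1))
  ord <- order(-elpds) # stable: ties keep input order
  top <- results[[ord[1]]]
  n <- top$n_obs
  rows <- lapply(seq_along(ord), function(j) {
    r <- results[[ord[j]]]
    d <- r$pointwise_elpd - top$pointwise_elpd
    se_d <- if (j == 1) 0 else sqrt(n * var(d))
    data.frame(
      model_id = names(results)[ord[j]],
      elpd_loo = r$elpd_loo, p_eff = r$p_eff,
      delta_elpd = sum(d), se_delta = se_d,
      supported = abs(sum(d)) <= 2 * se_d | j == 1,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Support rule on printed comparison values
#'
#' Applies the two-SE support rule directly to a (delta ELPD, SE) pair:
#' supported iff `|delta| <= 2 * se`.
#'
#' @param delta_elpd ELPD difference from the top model (<= 0).
#' @param se_delta standard error of the difference.
#' @return logical.
#' @export
is_supported <- function(delta_elpd, se_delta) {
  abs(delta_elpd) <= 2 * se_delta
}

#' Split-chain Gelman-Rubin convergence diagnostic
#'
#' Each chain is split in half and the classic potential scale reduction
#' factor is computed across the resulting half-chains. Values below 1.1 were
#' taken as converged in the original analyses; below 1.01 is a stricter
#' modern threshold.
#'
#' @param fit a `posterior_draws` object (needs >= 2 chains).
#' @param params parameter names (default: coefficients and SDs).
#' @return named numeric vector of R-hat values; parameters with zero
#'   within-chain variance are returned as `NA` with a `"degenerate"`
#'   attribute listing them.
#' @export
gelman_rubin <- function(fit, params = NULL) {
  stopifnot(inherits(fit, "posterior_draws"))
  chains <- unique(fit$chain)
  if (length(chains) < 2) stop("Gelman-Rubin needs at least 2 chains")
  if (is.null(params)) {
    params <- c(fit$par_groups$beta, fit$par_groups$sd, fit$par_groups$err)
  }
  rhat_one <- function(v) {
    pieces <- list()
    for (c in chains) {
      vc <- v[fit$chain == c]
      h <- floor(length(vc) / 2)
      pieces <- c(pieces, list(vc[1:h], vc[(h + 1):(2 * h)]))
    }
    m <- length(pieces); nn <- length(pieces[[1]])
    means <- vapply(pieces, mean, numeric(1))
    vars <- vapply(pieces, var, numeric(1))
    W <- mean(vars)
    B <- nn * var(means)
    if (W <= 0) return(NA_real_)
    sqrt(((nn - 1) / nn * W + B / nn) / W)
  }
  out <- vapply(params, function(pn) rhat_one(fit$draws[, pn]), numeric(1))
  degen <- names(out)[is.na(out)]
  if (length(degen)) attr(out, "degenerate") <- degen
  out
}

#' Posterior predictive checks of the mean and variance
#'
#' For each retained draw a replicate response vector is simulated from the
#' fitted observation model (by default re-drawing only the residual error,
#' conditional on the sampled random effects); the Bayesian p-value for a
#' statistic is the fraction of replicates whose statistic is at least the
#' observed one. Values near 0.5 indicate the model reproduces the statistic
#' well; values near 0 or 1 indicate misfit.
#'
#' @param fit a `posterior_draws` object.
#' @param seed integer seed for the replicate simulation.
#' @param redraw_random also re-draw the random-effect levels from their
#'   sampled SDs (a stricter check of the full hierarchy); default `FALSE`.
#' @return list with `p_mean` and `p_var`, both in `[0, 1]`.
#' @export
ppc_pvalues <- function(fit, seed = 1, redraw_random = FALSE) {
  stopifnot(inherits(fit, "posterior_draws"))
  frame <- fit$frame
  set.seed(seed)
  if (redraw_random) {
    mu <- tcrossprod(frame$X, fit$beta_scaled)
    for (bi in seq_along(frame$blocks)) {
      b <- frame$blocks[[bi]]
      sn <- if (b$n_var_groups == 1) paste0("sigma_", b$term) else
        paste0("sigma_", b$term, "[", b$var_group_labels, "]")
      sd_draws <- fit$draws[, sn, drop = FALSE] # S x G
      S <- nrow(sd_draws)
      u_new <- matrix(rnorm(b$n_levels * S), b$n_levels, S) *
        t(sd_draws)[b$var_group, , drop = FALSE]
      mu <- mu + u_new[b$idx, , drop = FALSE]
    }
  } else {
    mu <- posterior_mu(fit)
  }
  sdo <- posterior_sigma_obs(fit)
  n <- frame$n; S <- ncol(mu)
  yrep <- mu + matrix(rnorm(n * S), n, S) * sdo
  obs_mean <- mean(frame$y); obs_var <- var(frame$y)
  rep_mean <- colMeans(yrep)
  rep_var <- apply(yrep, 2, var)
  list(p_mean = mean(rep_mean >= obs_mean), p_var = mean(rep_var >= obs_var))
}
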