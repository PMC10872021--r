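# Broad-sense heritability and temperature contrasts from posterior draws.
#
# In a clonal design the among-clone variance is the total genetic variance,
# so heritability is broad-sense:
#   H^2 = sigma_clone^2 / (sigma_clone^2 + sigma_resid^2),
# computed draw-wise. The trial variance (CTmax assay batches), where
# present, is excluded from the denominator: H^2 refers to the
# assay-adjusted phenotype.

# locate the sigma draw vector for a term and group label
sigma_draws <- function(fit, term, group) {
  shared <- paste0("sigma_", term)
  grouped <- paste0("sigma_", term, "[", group, "]")
  cn <- colnames(fit$draws)
  if (grouped %in% cn) return(fit$draws[, grouped])
  if (shared %in% cn) return(fit$draws[, shared])
  avail <- grep(paste0("^sigma_", term), cn, value = TRUE)
  stop("no ", term, " SD draws for group '", group, "'; available: ",
       if (length(avail)) paste(avail, collapse = ", ") else "none")
}

ci95 <- function(v) unname(quantile(v, c(0.025, 0.975)))

#' Broad-sense heritability for one variance group
#'
#' @param fit a `posterior_draws` object containing clone and residual SD
#'   draws for the requested group.
#' @param group variance-group label: `"20"` or `"25"` for
#'   temperature-specific models, `"all"` for shared-variance models.
#' @return an object of class `heritability_estimate`: list with `group`,
#'   and posterior `median` + `ci95` for `V_G` (genetic variance), `V_E`
#'   (nongenetic variance) and `H2`, plus the raw per-draw vectors.
#' @export
heritability <- function(fit, group = "all") {
  stopifnot(inherits(fit, "posterior_draws"))
  vg <- sigma_draws(fit, "clone", group)^2
  ve <- sigma_draws(fit, "resid", group)^2
  h2 <- vg / (vg + ve)
  structure(list(
    group = group,
    V_G = list(median = median(vg), ci95 = ci95(vg)),
    V_E = list(median = median(ve), ci95 = ci95(ve)),
    H2 = list(median = median(h2), ci95 = ci95(h2)),
    draws = list(V_G = vg, V_E = ve, H2 = h2)
  ), class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat("Broad-sense heritability, group", x$group, "\n")
  f <- function(e) sprintf("%.4g [%.4g, %.4g]", e$median, e$ci95[1], e$ci95[2])
  cat("  V_G:", f(x$V_G), "\n  V_E:", f(x$V_E), "\n  H2: ", f(x$H2), "\n")
  invisible(x)
}

#' Temperature contrast of variance components and heritability
#'
#' Summarises per-draw differences between developmental temperatures
#' (20 degC value minus 25 degC value, and the reverse) for the genetic
#' variance, nongenetic variance and heritability, and reports the percent
#' change of the posterior medians from 20 to 25 degC.
#'
#' @param fit a `posterior_draws` object from a model whose clone or residual
#'   variance is grouped by developmental temperature (M3-1..M3-3).
#' @param percent_change_draws also report a per-draw percent-change CI
#'   (default `FALSE`: percent change is a point statement about medians,
#'   paired with the difference CI).
#' @return object of class `temperature_contrast`: for each of `V_G`, `V_E`,
#'   `H2` a list with the two group summaries, `diff_20_minus_25` (median and
#'   95% CI of the per-draw difference), and `percent_change` (of medians,
#'   from 20 to 25 degC).
#' @export
temperature_contrast <- function(fit, percent_change_draws = FALSE) {
  stopifnot(inherits(fit, "posterior_draws"))
  spec <- fit$frame$spec
  grouped_clone <- any(grepl("^sigma_clone\\[", colnames(fit$draws)))
  grouped_resid <- any(grepl("^sigma_resid\\[", colnames(fit$draws)))
  if (!grouped_clone && !grouped_resid) {
    stop("no contrast exists under this spec: model ", spec$model_id,
         " shares all variances across temperatures")
  }
  h20 <- heritability(fit, "20")
  h25 <- heritability(fit, "25")
  one <- function(comp) {
    d20 <- h20$draws[[comp]]; d25 <- h25$draws[[comp]]
    dd <- d20 - d25
    m20 <- median(d20); m25 <- median(d25)
    out <- list(
      at20 = list(median = m20, ci95 = ci95(d20)),
      at25 = list(median = m25, ci95 = ci95(d25)),
      diff_20_minus_25 = list(median = median(dd), ci95 = ci95(dd)),
      percent_change = (m25 - m20) / m20 * 100
    )
    if (percent_change_draws) {
      pc <- (d25 - d20) / d20 * 100
      out$percent_change_ci95 <- ci95(pc)
    }
    out
  }
  structure(list(V_G = one("V_G"), V_E = one("V_E"), H2 = one("H2")),
            class = "temperature_contrast")
}

#' @export
print.temperature_contrast <- function(x, ...) {
  cat("Temperature contrast (20 vs 25 degC)\n")
  for (comp in c("V_G", "V_E", "H2")) {
    e <- x[[comp]]
    cat(sprintf(
      "  %-3s 20: %.4g  25: %.4g  diff(20-25): %.4g [%.4g, %.4g]  change: %+.1f%%\n",
      comp, e$at20$median, e$at25$median, e$diff_20_minus_25$median,
      e$diff_20_minus_25$ci95[1], e$diff_20_minus_25$ci95[2],
      e$percent_change))
  }
  invisible(x)
}

#' Heritability table across groups
#'
#' @param fit a `posterior_draws` object.
#' @param groups group labels (default: inferred from the SD parameter names).
#' @return data frame with columns `group`, `Vg_med`, `Vg_lo`, `Vg_hi`,
#'   `Ve_med`, `Ve_lo`, `Ve_hi`, `H2_med`, `H2_lo`, `H2_hi`.
#' @export
heritability_table <- function(fit, groups = NULL) {
  if (is.null(groups)) {
    cn <- grep("^sigma_clone", colnames(fit$draws), value = TRUE)
    groups <- if (any(grepl("\\[", cn)))
      sub("^sigma_clone\\[(.*)\\]$", "\\1", cn) else "all"
  }
  rows <- lapply(groups, function(g) {
    h <- heritability(fit, g)
    data.frame(group = g,
               Vg_med = h$V_G$median, Vg_lo = h$V_G$ci95[1], Vg_hi = h$V_G$ci95[2],
               Ve_med = h$V_E$median, Ve_lo = h$V_E$ci95[1], Ve_hi = h$V_E$ci95[2],
               H2_med = h$H2$median, H2_lo = h$H2$ci95[1], H2_hi = h$H2$ci95[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
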