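# Individual fitness as the intrinsic rate of natural increase (r, per day)
# from the first and second brood events, via the Lotka-Euler equation
#   sum_k l_k m_k exp(-r x_k) = 1,
# with survivorship l_k fixed at 1 (the female was demonstrably alive at each
# observed brood) and all offspring counted (clonal, all-female reproduction).

#' Inclusion filter for the fitness analysis
#'
#' An individual enters the fitness analysis only if she matured (produced at
#' least one non-empty brood) and was monitored for at least 15 days, giving
#' every female ample opportunity to produce two broods.
#'
#' @param brood_sizes integer vector of brood sizes (possibly empty).
#' @param days_monitored days the individual was followed.
#' @return `TRUE` iff the individual is included.
#' @export
include_for_fitness <- function(brood_sizes, days_monitored) {
  any(brood_sizes >= 1) && days_monitored >= 15
}

#' Solve the Lotka-Euler equation for the intrinsic rate of increase
#'
#' Finds the unique root of `f(r) = sum_k m_k exp(-r x_k) - 1`, which is
#' strictly decreasing in `r`, by bracketed bisection refined with
#' [stats::uniroot()]. Ages are in days, so `r` is per day.
#'
#' @param ages brood ages in days (strictly increasing, > 0).
#' @param sizes brood sizes (integer >= 0, at least one >= 1).
#' @param lower,upper initial bracket for `r` (per day).
#' @param tol tolerance on `|f(r)|` at the returned root.
#' @return list with `r` and `solver_residual` (= `f(r)` at the solution).
#' @export
solve_euler <- function(ages, sizes, lower = -1, upper = 5, tol = 1e-12) {
  if (length(ages) != length(sizes)) stop("ages and sizes differ in length")
  if (any(ages <= 0)) stop("brood ages must be positive")
  if (is.unsorted(ages, strictly = TRUE)) stop("brood ages must be strictly increasing")
  if (all(sizes < 1)) stop("all brood sizes are zero; filter such records first")

  f <- function(r) sum(sizes * exp(-r * ages)) - 1
  # expand the bracket if needed; f is strictly decreasing
  while (f(lower) < 0) lower <- lower - 1
  while (f(upper) > 0) upper <- upper + 1
  root <- uniroot(f, c(lower, upper), tol = 1e-14)$root
  # polish by bisection until the residual meets tol
  lo <- root - 1e-6; hi <- root + 1e-6
  while (f(lo) < 0) lo <- lo - 1e-6
  while (f(hi) > 0) hi <- hi + 1e-6
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) < tol || (hi - lo) < 1e-15) break
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  r <- (lo + hi) / 2
  if (abs(f(r)) > abs(f(root))) r <- root
  list(r = r, solver_residual = f(r))
}

#' Per-individual fitness table
#'
#' Applies the inclusion filter and the Lotka-Euler solver to a phenotype
#' table, keeping only the first and second brood events. Records excluded by
#' the filter are counted by reason.
#'
#' @param records data frame with columns `individual_id`, `clone_id`,
#'   `pool_id`, `year`, `dev_temp`, `age_first_brood_d`, `size_first_brood`,
#'   `age_second_brood_d`, `size_second_brood`, `days_monitored` (NA cells =
#'   absent broods).
#' @return data frame of included individuals with their grouping factors and
#'   per-day `r`; attribute `"exclusions"` holds named counts
#'   (`no_brood`, `short_monitoring`).
#' @export
fitness_table <- function(records) {
  out_cols <- c("individual_id", "clone_id", "pool_id", "year", "dev_temp", "r")
  excl <- c(no_brood = 0L, short_monitoring = 0L)
  if (nrow(records) == 0) {
    out <- records[, intersect(names(records), out_cols), drop = FALSE]
    out$r <- numeric(0)
    attr(out, "exclusions") <- excl
    return(out)
  }
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    ages <- c(rec$age_first_brood_d, rec$age_second_brood_d)
    sizes <- c(rec$size_first_brood, rec$size_second_brood)
    keep <- !is.na(ages) & !is.na(sizes)
    ages <- ages[keep]; sizes <- sizes[keep]
    if (length(sizes) == 0 || !any(sizes >= 1)) {
      excl["no_brood"] <- excl["no_brood"] + 1L
      next
    }
    if (is.na(rec$days_monitored) || rec$days_monitored < 15) {
      excl["short_monitoring"] <- excl["short_monitoring"] + 1L
      next
    }
    sol <- solve_euler(ages, sizes)
    rows[[i]] <- data.frame(
      individual_id = rec$individual_id, clone_id = rec$clone_id,
      pool_id = rec$pool_id, year = rec$year, dev_temp = rec$dev_temp,
      r = sol$r, stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(individual_id = character(0), clone_id = character(0),
               pool_id = character(0), year = integer(0),
               dev_temp = numeric(0), r = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}
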