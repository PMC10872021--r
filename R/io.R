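# File readers/writers, schema validation, and the umbrella pipeline.
#
# All tabular I/O is comma-separated UTF-8 CSV with a mandatory header row;
# dates are ISO-8601; day-of-year is 1-based. Columns beyond the documented
# schema are tolerated and ignored with a notice (field exports often carry
# extra columns). Readers fail with file/line context on invalid rows.

#' Read per-pool temperature-logger series from CSV
#'
#' Expected columns: `pool_id`, `date` (ISO-8601 `YYYY-MM-DD`), `daily_max_c`
#' and `daily_mean_c`. Day-of-year is derived from the date (1-based).
#'
#' @param path CSV file path.
#' @return list of validated temperature series data frames, one per pool,
#'   named by pool id.
#' @export
read_temperature_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("pool_id", "date", "daily_max_c", "daily_mean_c")
  miss <- setdiff(req, names(raw))
  if (length(miss)) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  }
  extra <- setdiff(names(raw), req)
  if (length(extra)) {
    message(path, ": ignoring extra column(s): ", paste(extra, collapse = ", "))
  }
  d <- as.Date(raw$date, format = "%Y-%m-%d")
  bad <- which(is.na(d))
  if (length(bad)) {
    stop(path, ":", bad[1] + 1, ": unparseable date '", raw$date[bad[1]], "'")
  }
  key <- paste(raw$pool_id, raw$date)
  if (anyDuplicated(key)) {
    line <- which(duplicated(key))[1]
    stop(path, ":", line + 1, ": duplicate (pool, date) row: ", key[line])
  }
  raw$day <- as.POSIXlt(d)$yday + 1L
  out <- lapply(split(raw, raw$pool_id), function(g) {
    validate_temperature_series(data.frame(
      pool_id = g$pool_id, day = g$day,
      daily_max = g$daily_max_c, daily_mean = g$daily_mean_c,
      stringsAsFactors = FALSE
    ))
  })
  out[order(names(out))]
}

#' Read individual phenotype/life-history records from CSV
#'
#' Expected columns: `individual_id`, `clone_id`, `pool_id`, `year`,
#' `dev_temp_c`, `age_first_brood_d`, `size_first_brood`,
#' `age_second_brood_d`, `size_second_brood`, `days_monitored`, `trial_id`,
#' `ctmax_c`. Empty cells become `NA` (absent). Brood columns beyond the
#' second are ignored.
#'
#' @param path CSV file path.
#' @return data frame of typed records (one per individual).
#' @export
read_phenotype_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("individual_id", "clone_id", "pool_id", "year", "dev_temp_c",
           "age_first_brood_d", "size_first_brood", "age_second_brood_d",
           "size_second_brood", "days_monitored", "trial_id", "ctmax_c")
  miss <- setdiff(req, names(raw))
  if (length(miss)) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  }
  extra <- setdiff(names(raw), req)
  if (length(extra)) {
    message(path, ": ignoring extra column(s): ", paste(extra, collapse = ", "))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- data.frame(
    individual_id = as.character(raw$individual_id),
    clone_id = as.character(raw$clone_id),
    pool_id = as.character(raw$pool_id),
    year = as.integer(raw$year),
    dev_temp = num(raw$dev_temp_c),
    age_first_brood_d = num(raw$age_first_brood_d),
    size_first_brood = num(raw$size_first_brood),
    age_second_brood_d = num(raw$age_second_brood_d),
    size_second_brood = num(raw$size_second_brood),
    days_monitored = num(raw$days_monitored),
    trial_id = ifelse(is.na(raw$trial_id) | raw$trial_id == "",
                      NA_character_, as.character(raw$trial_id)),
    ctmax = num(raw$ctmax_c),
    stringsAsFactors = FALSE
  )
  bad_temp <- which(!out$dev_temp %in% c(20, 25))
  if (length(bad_temp)) {
    stop(path, ":", bad_temp[1] + 1, ": dev_temp_c must be 20 or 25, got '",
         raw$dev_temp_c[bad_temp[1]], "'")
  }
  neg <- which(out$age_first_brood_d <= 0 | out$size_first_brood < 0 |
                 out$age_second_brood_d <= 0 | out$size_second_brood < 0)
  if (length(neg)) {
    stop(path, ":", neg[1] + 1, ": negative or zero age / negative size")
  }
  rev_brood <- which(!is.na(out$age_first_brood_d) &
                       !is.na(out$age_second_brood_d) &
                       out$age_second_brood_d <= out$age_first_brood_d)
  if (length(rev_brood)) {
    stop(path, ":", rev_brood[1] + 1,
         ": second brood not after first (ages must strictly increase)")
  }
  out
}

#' Write individual records to the phenotype CSV schema
#'
#' Inverse of [read_phenotype_csv()]; round-trips every field.
#'
#' @param records data frame in the [read_phenotype_csv()] layout.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotype_csv <- function(records, path) {
  out <- data.frame(
    individual_id = records$individual_id, clone_id = records$clone_id,
    pool_id = records$pool_id, year = records$year,
    dev_temp_c = records$dev_temp,
    age_first_brood_d = records$age_first_brood_d,
    size_first_brood = records$size_first_brood,
    age_second_brood_d = records$age_second_brood_d,
    size_second_brood = records$size_second_brood,
    days_monitored = records$days_monitored,
    trial_id = records$trial_id, ctmax_c = records$ctmax,
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a synthetic study's individuals to the phenotype CSV schema
#' @param study a `synthetic_study` with life histories.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_study_phenotypes <- function(study, path) {
  ind <- study$individuals
  write_phenotype_csv(data.frame(
    individual_id = ind$individual_id, clone_id = ind$clone,
    pool_id = ind$pool, year = ind$year, dev_temp = ind$dev_temp,
    age_first_brood_d = ind$age_first_brood_d,
    size_first_brood = ind$size_first_brood,
    age_second_brood_d = ind$age_second_brood_d,
    size_second_brood = ind$size_second_brood,
    days_monitored = ind$days_monitored, trial_id = ind$trial,
    ctmax = ind$ctmax, stringsAsFactors = FALSE
  ), path)
}

#' Build an observation table from phenotype records and pool climate
#'
#' Merges per-pool climate covariates into the per-individual table and
#' selects the response.
#'
#' @param records phenotype records ([read_phenotype_csv()] layout), or a
#'   fitness table from [fitness_table()] for `response = "fitness"`.
#' @param climate pool-climate table ([pool_climate_table()] layout); a
#'   column `abs_mean_minus_20` is derived if absent.
#' @param response `"ctmax"` or `"fitness"`.
#' @return observation table for [build_model_frame()].
#' @export
build_observations <- function(records, climate, response = c("ctmax", "fitness")) {
  response <- match.arg(response)
  if (!"abs_mean_minus_20" %in% names(climate)) {
    climate$abs_mean_minus_20 <- abs(climate$mean_daily_mean - 20)
  }
  if (response == "ctmax") {
    keep <- !is.na(records$ctmax)
    rec <- records[keep, , drop = FALSE]
    resp <- rec$ctmax
    trial <- rec$trial_id
  } else {
    rec <- records
    resp <- rec$r
    trial <- NA_character_
  }
  m <- match(rec$pool_id, climate$pool_id)
  if (anyNA(m)) {
    stop("pool(s) without climate metrics: ",
         paste(unique(rec$pool_id[is.na(m)]), collapse = ", "))
  }
  data.frame(
    response = resp, clone = rec$clone_id, pool = rec$pool_id,
    year = rec$year, dev_temp = rec$dev_temp, trial = trial,
    hottest_month_mean_daily_max = climate$hottest_month_mean_daily_max[m],
    abs_mean_minus_20 = climate$abs_mean_minus_20[m],
    daily_sd = climate$daily_sd[m],
    predictability_days = climate$predictability_days[m],
    stringsAsFactors = FALSE
  )
}

#' Run the full analysis pipeline
#'
#' Executes the five stages -- climate metrics, fitness, model fitting, model
#' comparison, heritability -- writing each stage's CSV output and a JSON run
#' manifest with input digests, seeds, per-stage timing and warnings.
#'
#' @param config list with elements `temperature_csv`, `phenotype_csv`
#'   (input paths), `out_dir`, `seed`, optional `models` (character vector of
#'   model ids to fit; default `c("M1-0", "M1-1")`), `response` (default
#'   `"ctmax"`), `hottest_month` (default 8), and `settings` (MCMC settings;
#'   default reduced settings for interactive use).
#' @return the run manifest (list), invisibly; written as `manifest.json`.
#' @export
pipeline_run <- function(config) {
  for (f in c("temperature_csv", "phenotype_csv")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      stop("config$", f, " missing or file not found; aborting before any stage")
    }
  }
  out_dir <- config$out_dir %||% stop("config$out_dir required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  response <- config$response %||% "ctmax"
  models <- config$models %||% c("M1-0", "M1-1")
  settings <- config$settings %||%
    list(n_iterations = 2000L, n_burn_in = 1000L, thin = 2L, n_chains = 2L)
  manifest <- list(
    package_version = as.character(utils::packageVersion("thermoclone")),
    seed = seed,
    inputs = list(
      temperature_csv = unname(tools::md5sum(config$temperature_csv)),
      phenotype_csv = unname(tools::md5sum(config$phenotype_csv))
    ),
    config = config[setdiff(names(config), "settings")],
    stages = list(), warnings = character(0)
  )
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- withCallingHandlers(fun(), warning = function(w) {
      manifest$warnings <<- c(manifest$warnings,
                              paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  climate <- run_stage("metrics", function() {
    series <- read_temperature_csv(config$temperature_csv)
    cl <- pool_climate_table(series, hottest_month = config$hottest_month %||% 8)
    write.csv(cl, file.path(out_dir, "climate.csv"), row.names = FALSE)
    cl
  })
  records <- read_phenotype_csv(config$phenotype_csv)
  fitness <- run_stage("fitness", function() {
    ft <- fitness_table(records)
    write.csv(ft, file.path(out_dir, "fitness.csv"), row.names = FALSE)
    ft
  })
  obs <- if (response == "ctmax") {
    build_observations(records, climate, "ctmax")
  } else {
    ftab <- fitness
    names(ftab)[names(ftab) == "clone_id"] <- "clone_id" # schema already matches
    build_observations(ftab, climate, "fitness")
  }
  fits <- run_stage("fit", function() {
    lapply(setNames(models, models), function(m) {
      sample_posterior(model_registry(m, response), obs,
                       settings = settings, seed = seed)
    })
  })
  comparison <- run_stage("compare", function() {
    loos <- lapply(fits, function(f) psis_loo(pointwise_loglik(f)))
    cmp <- compare_models(loos)
    write.csv(cmp, file.path(out_dir, "comparison.csv"), row.names = FALSE)
    cmp
  })
  run_stage("h2", function() {
    with_clone <- names(fits)[vapply(fits, function(f)
      any(grepl("^sigma_clone", colnames(f$draws))), logical(1))]
    if (length(with_clone)) {
      h2 <- heritability_table(fits[[with_clone[length(with_clone)]]])
      write.csv(h2, file.path(out_dir, "h2.csv"), row.names = FALSE)
      h2
    } else NULL
  })
  manifest$outputs <- list.files(out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
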