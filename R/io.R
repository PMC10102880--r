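#' Read a panel CSV
#'
#' Long-format delimited text, one row per unit per wave, columns
#' `unit_id`, `wave`, `s`, then `r` and `y` for sample files, then the
#' covariates; missing outcome cells are empty. A strict schema check
#' precedes invariant validation; a population file containing any outcome
#' value is rejected, while a missing `y` column in a population file is
#' fine. Unit ids are preserved as opaque strings.
#'
#' @param path file path.
#' @param role `"population"` or `"sample"`.
#' @param validate stop on invariant violations.
#' @return a `ppcm_population` or `ppcm_sample` frame.
#' @export
read_panel_csv <- function(path, role = c("population", "sample"),
                           validate = TRUE) {
  role <- match.arg(role)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(unit_id = "character"))
  if (role == "population") population_frame(df, validate = validate)
  else sample_frame(df, validate = validate)
}

#' @rdname read_panel_csv
#' @param x a panel frame.
#' @export
write_panel_csv <- function(x, path) {
  stopifnot(inherits(x, "ppcm_panel"))
  write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a report to disk
#'
#' Writes a rendered CSV and a raw-scale JSON side by side. In the CSV the
#' `bias` and `sd` columns are multiplied by 100 (the conventional
#' presentation scale); `mse` and `cp` are left untouched. The JSON carries
#' everything on the raw scale. Rows are ordered deterministically by
#' estimator then scenario.
#'
#' @param report a `comparison_report`, `simulation_report` or
#'   `ppcm_posterior`.
#' @param path output CSV path; the JSON lands next to it with extension
#'   `.json`.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, path) {
  jpath <- sub("\\.csv$", "", path)
  jpath <- paste0(jpath, ".json")
  if (inherits(report, "comparison_report")) {
    df <- as.data.frame(report)
    df <- df[order(df$estimator, df$scenario), , drop = FALSE]
    out <- df
    out$bias <- 100 * out$bias
    out$sd <- 100 * out$sd
    write.csv(out, path, row.names = FALSE)
    jsonlite::write_json(df, jpath, dataframe = "rows", digits = NA)
  } else if (inherits(report, "simulation_report")) {
    out <- data.frame(bias = 100 * report$bias, sd = 100 * report$sd,
                      mse = report$mse, cp = report$cp,
                      n_reps = report$n_reps)
    write.csv(out, path, row.names = FALSE)
    jsonlite::write_json(unclass(report), jpath, auto_unbox = TRUE,
                         digits = NA)
  } else if (inherits(report, "ppcm_posterior")) {
    df <- data.frame(wave = report$waves, mean = report$mean_wave,
                     lower = report$ci_wave[, 1],
                     upper = report$ci_wave[, 2])
    write.csv(df, path, row.names = FALSE)
    jsonlite::write_json(
      list(mean_wave = report$mean_wave, ci_wave = report$ci_wave,
           mean = report$mean, ci = report$ci, J = report$J,
           backend = report$backend, manifest = report$manifest),
      jpath, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported report type")
  invisible(c(csv = path, json = jpath))
}

#' Read a run configuration
#'
#' Flat declarative configuration (YAML if the `yaml` package is available
#' and the file ends in `.yml`/`.yaml`, otherwise JSON) with blocks:
#' `backend`, `mcmc` (passed to [mcmc_control()]), `sensitivity` (either a
#' preset name — `"MARS"`, `"MNARS+PE"`, `"2x"` — or explicit
#' `gamma`/`delta` bounds), `J`, `seed`.
#'
#' @param path config file.
#' @return list with entries `backend`, `mcmc`, `sens`, `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  mcmc <- do.call(mcmc_control, as.list(cfg$mcmc))
  sens <- if (is.character(cfg$sensitivity)) {
    sensitivity_preset(cfg$sensitivity)
  } else if (is.null(cfg$sensitivity)) {
    sensitivity_config()
  } else {
    pb <- function(b) if (is.list(b) && !is.null(b$poly))
      poly_bound(b$poly[1], b$poly[2], b$poly[3],
                 on = if (is.null(b$on)) "age" else b$on) else b
    sensitivity_config(gamma = pb(cfg$sensitivity$gamma),
                       delta = pb(cfg$sensitivity$delta))
  }
  list(backend = if (is.null(cfg$backend)) "trees" else cfg$backend,
       mcmc = mcmc, sens = sens,
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
}
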