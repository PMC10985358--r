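#' Read and validate a pipeline run configuration
#'
#' A run configuration is a YAML (or R list) with blocks `paths` (input
#' tables and output directory), `model` (arguments of [occu_config()]),
#' `mcmc` (schedule for [fit_occupancy()]), `ppc` (`n_rep`), `simulate`
#' (arguments of [sim_scenario()]) and `seed`. Unknown keys are rejected;
#' a config written back to disk round-trips unchanged.
#'
#' @param config path to a YAML file or a named list.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  allowed <- c("paths", "model", "mcmc", "ppc", "simulate", "seed")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  sub_allowed <- list(
    paths = c("photos", "days", "geo", "stations", "rodents", "intro_dates",
              "out_dir"),
    model = c("psi", "gamma", "epsilon", "competition", "rho_carrion",
              "sigma_upper", "conditioning"),
    mcmc = c("chains", "adapt", "burn_in", "iter", "thin"),
    ppc = c("n_rep"),
    simulate = c("n_years", "n_sites", "n_weeks", "day_dropout",
                 "feeding_start_year"))
  for (blk in names(sub_allowed)) {
    unknown <- setdiff(names(config[[blk]]), sub_allowed[[blk]])
    if (length(unknown) > 0)
      stop("unknown key(s) in '", blk, "': ", paste(unknown, collapse = ", "))
  }
  config$seed <- config$seed %||% 1L
  structure(config, class = c("run_config", "list"))
}

config_occu <- function(config)
  do.call(occu_config, config$model %||% list())

out_path <- function(config, file) {
  dir <- config$paths$out_dir %||% "."
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  file.path(dir, file)
}

#' Pipeline stage: prepare the dataset bundle
#'
#' Runs the data-preparation and covariate stages on the configured input
#' tables and writes the detection-history table, covariate table and a
#' JSON filtering report to the output directory.
#'
#' @param config a [read_run_config()] configuration.
#' @return list with `histories` and `covariates` (invisibly also written
#'   as CSV).
#' @export
pipeline_prepare <- function(config) {
  config <- read_run_config(config)
  p <- config$paths
  days <- if (!is.null(p$days)) {
    readr::read_csv(p$days, show_col_types = FALSE)
  } else {
    photos_to_days(readr::read_csv(p$photos, show_col_types = FALSE))
  }
  intro <- readr::read_csv(p$intro_dates, show_col_types = FALSE)
  histories <- build_histories(days, intro)
  winters <- dplyr::distinct(histories, .data$site_id, .data$year)
  covariates <- build_covariates(
    winters, readr::read_csv(p$geo, show_col_types = FALSE),
    readr::read_csv(p$stations, show_col_types = FALSE),
    readr::read_csv(p$rodents, show_col_types = FALSE))
  readr::write_csv(histories, out_path(config, "histories.csv"))
  readr::write_csv(covariates, out_path(config, "covariates.csv"))
  jsonlite::write_json(filtering_summary(histories),
                       out_path(config, "filtering_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(histories = histories, covariates = covariates))
}

#' Pipeline stage: simulate a synthetic dataset
#'
#' @inheritParams pipeline_prepare
#' @return the [simulate_dataset()] result; histories and covariates are
#'   written as CSV in the configured output directory.
#' @export
pipeline_simulate <- function(config) {
  config <- read_run_config(config)
  args <- config$simulate %||% list()
  args$seed <- config$seed
  sim <- simulate_dataset(do.call(sim_scenario, args))
  readr::write_csv(sim$histories, out_path(config, "sim_histories.csv"))
  readr::write_csv(sim$covariates, out_path(config, "sim_covariates.csv"))
  readr::write_csv(sim$latent, out_path(config, "sim_latent.csv"))
  invisible(sim)
}

#' Pipeline stage: fit the model
#'
#' @inheritParams pipeline_prepare
#' @param histories,covariates optional in-memory tables (otherwise read
#'   from the prepared CSVs in the output directory).
#' @return the fitted `occu_fit`; posterior draws (CSV) and a summary JSON
#'   (medians, intervals, Rhat, manifest with seed and config) are written.
#' @export
pipeline_fit <- function(config, histories = NULL, covariates = NULL) {
  config <- read_run_config(config)
  if (is.null(histories))
    histories <- readr::read_csv(out_path(config, "histories.csv"),
                                 show_col_types = FALSE)
  if (is.null(covariates))
    covariates <- readr::read_csv(out_path(config, "covariates.csv"),
                                  show_col_types = FALSE)
  mc <- config$mcmc %||% list()
  fit <- fit_occupancy(histories, covariates, config_occu(config),
                       chains = mc$chains %||% 4,
                       adapt = mc$adapt %||% 1000,
                       burn_in = mc$burn_in %||% 10000,
                       iter = mc$iter %||% 25000, thin = mc$thin %||% 5,
                       seed = config$seed)
  readr::write_csv(dplyr::as_tibble(draw_matrix(fit)),
                   out_path(config, "posterior_draws.csv"))
  summ <- tidy(fit)
  readr::write_csv(summ, out_path(config, "posterior_summary.csv"))
  manifest <- list(seed = config$seed, schedule = fit$schedule[-6],
                   max_rhat = max(fit$rhat, na.rm = TRUE),
                   rhat_warning = max(fit$rhat, na.rm = TRUE) > 1.05,
                   config = unclass(config))
  jsonlite::write_json(manifest, out_path(config, "fit_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(fit)
}

#' Pipeline stage: derive stationary carrion-use curves
#'
#' @inheritParams pipeline_fit
#' @param fit a fitted `occu_fit`.
#' @param covariate,grid passed to [use_curves()].
#' @return tibble of use curves (also written as CSV).
#' @export
pipeline_derive <- function(config, fit, covariate = "feeding",
                            grid = seq(-2, 2, length.out = 21)) {
  config <- read_run_config(config)
  curves <- use_curves(fit, covariate, grid, n_draws = 1000)
  readr::write_csv(curves, out_path(config,
                                    paste0("use_", covariate, ".csv")))
  invisible(curves)
}

#' Pipeline stage: posterior predictive check
#'
#' @inheritParams pipeline_fit
#' @param fit a fitted `occu_fit`.
#' @return the `occu_ppc` (report also written as JSON).
#' @export
pipeline_ppc <- function(config, fit) {
  config <- read_run_config(config)
  ppc <- posterior_predictive_check(fit,
                                    n_rep = config$ppc$n_rep %||% 1000,
                                    seed = config$seed)
  jsonlite::write_json(list(p_detection = ppc$p_detection,
                            p_transition = ppc$p_transition,
                            n_rep = ppc$n_rep),
                       out_path(config, "ppc_report.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(ppc$discrepancies,
                   out_path(config, "ppc_discrepancies.csv"))
  invisible(ppc)
}
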