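#' Default generating parameters for the synthetic study design
#'
#' Fixed effects at realistic values for the study system: Arctic foxes
#' rarer at carrion than red foxes (lower initial occupancy and
#' colonization), competition expressed mainly through extinction (the
#' probability of leaving an occupied carcass roughly doubles when the
#' competitor is present), rodent abundance raising colonization for both
#' species with a compensating negative competition interaction for Arctic
#' foxes, supplemental feeding helping Arctic foxes only, and detection
#' dropping when the carrion is absent. Year random-effect SDs default to
#' 0.3 on the logit scale.
#'
#' @param n_years number of years.
#' @param sigma year random-effect SD used for all eight blocks.
#' @return named parameter vector (random effects at 0; the simulator draws
#'   them).
#' @export
default_sim_params <- function(n_years = 16, sigma = 0.3) {
  th <- empty_params(n_years, sigma = sigma)
  set <- function(nm, v) th[nm] <<- v
  # Arctic fox
  set("psi_A_int", qlogis(0.13))
  set("psi_A_CLG", 0.3); set("psi_A_TFG", -0.8); set("psi_A_feeding", 0.6)
  set("gam_A_int", qlogis(0.094))
  set("gam_A_CLG", 0.8); set("gam_A_TFG", -0.8)
  set("gam_A_rodent", 0.8); set("gam_A_feeding", 0.8)
  set("gam_A_comp", -0.5); set("gam_A_comp_rodent", -0.8)
  set("eps_A_int", qlogis(0.16))
  set("eps_A_feeding", -0.6)
  set("eps_A_comp", qlogis(0.40) - qlogis(0.16))      # ~ +1.25
  set("eps_A_comp_rodent", -0.6)
  set("rho_A_int", qlogis(0.40))
  set("rho_A_nocarrion", qlogis(0.16) - qlogis(0.40))
  # red fox
  set("psi_R_int", qlogis(0.37)); set("psi_R_CLG", -0.6)
  set("gam_R_int", qlogis(0.39))
  set("gam_R_CLG", -0.4); set("gam_R_rodent", 0.6)
  set("eps_R_int", qlogis(0.23))
  set("eps_R_comp", qlogis(0.46) - qlogis(0.23))      # ~ +1.05
  set("rho_R_int", qlogis(0.35))
  set("rho_R_nocarrion", qlogis(0.18) - qlogis(0.35))
  th
}

#' Simulation scenario for the synthetic study design
#'
#' Describes a camera-trap study to simulate: years, sites, weekly primary
#' periods of 7 days, true parameters, covariate generators (standardized
#' site gradients, a cyclic rodent series, feeding that switches on late in
#' the series at a subset of sites), daily carrion-presence dynamics, and a
#' per-day dropout rate. The defaults mirror the real design: 16 years x
#' 18 cameras x 7 weeks x 7 days with ~20% of days unobserved.
#'
#' @param n_years,n_sites,n_weeks,n_days design dimensions.
#' @param params true parameter vector (random effects are drawn by the
#'   simulator from the `sigma_*` entries).
#' @param day_dropout probability a day is unobserved.
#' @param feeding_start_year first year with active feeding stations.
#' @param carrion_persist,carrion_return daily probabilities that the bait
#'   stays present / reappears (defaults give a mean presence run of ~22
#'   days and ~63% of days with carrion).
#' @param seed integer seed (one global seed drives covariates, random
#'   effects, latent states and observations).
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_years = 16, n_sites = 18, n_weeks = 7,
                         n_days = 7, params = default_sim_params(n_years),
                         day_dropout = 0.2, feeding_start_year = 13,
                         carrion_persist = 0.955, carrion_return = 0.0756,
                         seed = 1) {
  stopifnot(n_weeks <= 7, n_days == 7, n_years >= 1, n_sites >= 1)
  structure(list(n_years = n_years, n_sites = n_sites, n_weeks = n_weeks,
                 n_days = n_days, params = params,
                 day_dropout = day_dropout,
                 feeding_start_year = feeding_start_year,
                 carrion_persist = carrion_persist,
                 carrion_return = carrion_return, seed = seed),
            class = "sim_scenario")
}

std0 <- function(x) {
  s <- sd(x)
  if (s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

#' Simulate a synthetic camera-trap dataset
#'
#' Draws covariates, year random effects, weekly latent joint-state chains
#' and daily observations under the model, applies the day-dropout and the
#' week/winter retention filters, and returns data in the same shape the
#' data-preparation stage emits, plus the true latent states for oracle
#' tests.
#'
#' @param scenario a [sim_scenario()].
#' @return list with `histories` (filtered detection-history tibble),
#'   `covariates` (site x year tibble with standardized columns),
#'   `latent` (true weekly states per winter), `params` (true vector
#'   including the drawn random effects) and `scenario`.
#' @export
simulate_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  s <- scenario
  set.seed(s$seed)
  sites <- sprintf("S%02d", seq_len(s$n_sites))
  years <- seq_len(s$n_years)

  # covariates: site gradients, cyclic rodent series, late-onset feeding
  clg <- rnorm(s$n_sites); tfg <- rnorm(s$n_sites)
  cyc <- c(0.5, 2, 6, 1)
  rodent_raw <- cyc[(years - 1) %% 4 + 1] * exp(rnorm(s$n_years, 0, 0.3))
  near_station <- runif(s$n_sites) < 0.5
  feed_base <- ifelse(near_station, rexp(s$n_sites, rate = 2), 0)
  covariates <- tidyr::expand_grid(site_id = sites, year = years) |>
    dplyr::mutate(
      CLG_raw = clg[match(.data$site_id, sites)],
      TFG_raw = tfg[match(.data$site_id, sites)],
      rodent_raw = rodent_raw[.data$year],
      feeding_raw = feed_base[match(.data$site_id, sites)] *
        (.data$year >= s$feeding_start_year),
      CLG = std0(.data$CLG_raw), TFG = std0(.data$TFG_raw),
      rodent = std0(.data$rodent_raw), feeding = std0(.data$feeding_raw))

  # true parameter vector with drawn year random effects
  th <- s$params
  for (sp in c("A", "R")) for (b in c("psi", "gam", "eps", "rho")) {
    sg <- th[[paste0("sigma_", b, "_", sp)]]
    th[paste0("u_", b, "_", sp, "_", years)] <- rnorm(s$n_years, 0, sg)
  }

  # design: carrion flags and day dropout on the full grid
  design <- tidyr::expand_grid(site_id = sites, year = years,
                               week = seq_len(s$n_weeks), day = 1:7)
  n_win <- s$n_sites * s$n_years
  carr <- matrix(NA_integer_, n_win, s$n_weeks * 7)
  carr[, 1] <- 1L
  for (d in 2:(s$n_weeks * 7)) {
    stay <- runif(n_win) < s$carrion_persist
    back <- runif(n_win) < s$carrion_return
    carr[, d] <- ifelse(carr[, d - 1] == 1L, as.integer(stay),
                        as.integer(back))
  }
  observed <- matrix(runif(n_win * s$n_weeks * 7) >= s$day_dropout,
                     n_win, s$n_weeks * 7)
  design$carrion <- as.integer(t(carr))
  design$observed <- as.logical(t(observed))

  # pack the design and simulate latent states + observations in one pass
  hist0 <- design |>
    dplyr::mutate(obs = factor(ifelse(.data$observed, "none", NA_character_),
                               levels = obs_levels))
  pk <- build_pack(hist0, covariates)
  simres <- cpp_simulate(pk$obs, pk$carrion, pk$year, pk$X, pk$n_years,
                         unname(th), pk$cond)

  n <- nrow(pk$winters)
  oa <- array(simres$obs, dim = c(7, 7, n))
  hist_full <- pk$winters |>
    dplyr::mutate(.w = dplyr::row_number()) |>
    tidyr::expand_grid(week = 1:7, day = 1:7) |>
    dplyr::mutate(obs = factor(obs_levels[ifelse(
      oa[cbind(.data$day, .data$week, .data$.w)] == 0, NA_integer_,
      oa[cbind(.data$day, .data$week, .data$.w)])], levels = obs_levels),
      carrion = array(pk$carrion, dim = c(7, 7, n))[
        cbind(.data$day, .data$week, .data$.w)]) |>
    dplyr::select(-".w")

  filtered <- apply_retention_filters(hist_full)
  if (nrow(filtered) == 0)
    stop("scenario produced zero retained camera-winters")

  latent <- pk$winters |>
    tidyr::expand_grid(week = 1:7) |>
    dplyr::mutate(state = c("U", "A", "R", "AR")[
      simres$z[cbind(rep(seq_len(n), each = 7), .data$week)]])

  list(histories = filtered, covariates = covariates, latent = latent,
       params = th, scenario = s)
}

# week (>= 4 observed days) and winter (>= 4 retained weeks) filters,
# shared with the data-preparation stage semantics
apply_retention_filters <- function(hist_full, min_days_per_week = 4,
                                    min_weeks = 4) {
  wk <- hist_full |>
    dplyr::group_by(.data$site_id, .data$year, .data$week) |>
    dplyr::summarise(n_obs = sum(!is.na(.data$obs)), .groups = "drop") |>
    dplyr::mutate(keep_week = .data$n_obs >= min_days_per_week)
  win <- wk |>
    dplyr::group_by(.data$site_id, .data$year) |>
    dplyr::summarise(n_weeks = sum(.data$keep_week), .groups = "drop") |>
    dplyr::mutate(keep_winter = .data$n_weeks >= min_weeks)
  out <- hist_full |>
    dplyr::left_join(wk[c("site_id", "year", "week", "keep_week")],
                     by = c("site_id", "year", "week")) |>
    dplyr::left_join(win[c("site_id", "year", "keep_winter")],
                     by = c("site_id", "year")) |>
    dplyr::filter(.data$keep_winter)
  out$obs[!out$keep_week] <- NA
  out$carrion[!out$keep_week] <- NA_integer_
  dplyr::select(out, -"keep_week", -"keep_winter")
}

#' Deterministic micro-datasets for worked examples and tests
#'
#' @param name one of `"single_week_single_day"` (one winter, one observed
#'   day with an Arctic fox), `"boundary_filters"` (day records exercising
#'   the 36-photo, 4-day and 4-week thresholds) or `"both_species_cooccur"`
#'   (two winters with joint AR weeks).
#' @return a list with the fixture's tables; shape depends on the fixture.
#' @export
make_fixture <- function(name) {
  registry <- c("single_week_single_day", "boundary_filters",
                "both_species_cooccur")
  if (!name %in% registry)
    stop("unknown fixture '", name, "'; available: ",
         paste(registry, collapse = ", "))
  switch(name,
    single_week_single_day = {
      h <- dplyr::tibble(site_id = "S01", year = 1L, week = 1L, day = 1L,
                         obs = factor("A", levels = obs_levels),
                         carrion = 1L)
      cov <- dplyr::tibble(site_id = "S01", year = 1L, CLG = 0, TFG = 0,
                           rodent = 0, feeding = 0)
      list(histories = h, covariates = cov)
    },
    boundary_filters = {
      intro <- lubridate::as_date("2020-02-01")
      dates <- intro + 0:34                      # 5 weeks
      n_photos <- rep(144L, 35)
      n_photos[8] <- 35L                          # week 2: excluded day
      n_photos[9] <- 36L                          # boundary: retained
      # week 3 gets only 3 observed days -> dropped
      excluded_w3 <- intro + c(14, 15, 16, 17)
      days <- dplyr::tibble(
        site_id = "S01", date = dates, n_photos = n_photos,
        arctic_seen = as.integer(dates == intro + 1),
        red_seen = as.integer(dates %in% (intro + c(2, 15))),
        carrion_present = 1L) |>
        dplyr::mutate(excluded = .data$n_photos < 36 |
                        .data$date %in% excluded_w3)
      list(days = days,
           intro_dates = dplyr::tibble(site_id = "S01", year = 2020L,
                                       carrion_intro_date = intro))
    },
    both_species_cooccur = {
      h <- tidyr::expand_grid(site_id = c("S01", "S02"), year = 1L,
                              week = 1:4, day = 1:7) |>
        dplyr::mutate(obs = factor(
          dplyr::case_when(site_id == "S01" & week %in% 1:2 ~ "AR",
                           site_id == "S01" ~ "A",
                           week %in% 2:3 ~ "R",
                           TRUE ~ "none"), levels = obs_levels),
          carrion = 1L)
      cov <- dplyr::tibble(site_id = c("S01", "S02"), year = 1L, CLG = 0,
                           TFG = 0, rodent = 0, feeding = 0)
      list(histories = h, covariates = cov)
    })
}
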