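#' Logit-linear predictor of one parameter block
#'
#' Computes the probability implied by a block of the parameter vector for
#' given standardized covariate values, year and (for gamma/epsilon)
#' competitor presence.
#'
#' @param params named parameter vector (see [param_names()]).
#' @param block one of `"psi"`, `"gamma"`, `"epsilon"`, `"rho"`.
#' @param species `"A"` (Arctic fox) or `"R"` (red fox).
#' @param covariates named list/vector with `CLG`, `TFG`, `rodent`,
#'   `feeding` (ignored for rho).
#' @param year year index (1-based); its random effect is added. Use
#'   `year = 0` for the population-level (random effect zero) value.
#' @param n_years number of years the vector was built for.
#' @param competitor_present competition terms are added only when TRUE
#'   (gamma/epsilon blocks).
#' @param carrion for the rho block: is the carrion present that day?
#' @return probability on (0, 1).
#' @export
linpred <- function(params, block, species, covariates = NULL, year = 0,
                    n_years, competitor_present = FALSE, carrion = TRUE) {
  block <- match.arg(block, c("psi", "gamma", "epsilon", "rho"))
  stopifnot(species %in% c("A", "R"))
  short <- c(psi = "psi", gamma = "gam", epsilon = "eps", rho = "rho")[block]
  if (year > n_years || year < 0) stop("unknown year index: ", year)
  u <- if (year == 0) 0 else
    params[[paste0("u_", short, "_", species, "_", year)]]
  if (block == "rho") {
    lp <- params[[paste0("rho_", species, "_int")]] + u +
      if (!carrion) params[[paste0("rho_", species, "_nocarrion")]] else 0
    return(plogis(lp))
  }
  pre <- paste0(short, "_", species, "_")
  lp <- params[[paste0(pre, "int")]] + u
  for (v in block_covariates)
    lp <- lp + params[[paste0(pre, v)]] * covariates[[v]]
  if (block != "psi" && isTRUE(competitor_present)) {
    lp <- lp + params[[paste0(pre, "comp")]] +
      params[[paste0(pre, "comp_rodent")]] * covariates[["rodent"]] +
      params[[paste0(pre, "comp_feeding")]] * covariates[["feeding"]]
  }
  plogis(lp)
}

#' Initial joint-state distribution
#'
#' Independent-species product over the four joint states
#' (U, A, R, AR).
#'
#' @param psi_A,psi_R species-specific initial occupancy probabilities.
#' @return named probability 4-vector summing to 1.
#' @export
initial_state_distribution <- function(psi_A, psi_R) {
  stopifnot(psi_A >= 0, psi_A <= 1, psi_R >= 0, psi_R <= 1)
  c(U = (1 - psi_A) * (1 - psi_R), A = psi_A * (1 - psi_R),
    R = (1 - psi_A) * psi_R, AR = psi_A * psi_R)
}

#' Weekly joint-state transition matrix
#'
#' Builds the 4 x 4 row-stochastic kernel over (U, A, R, AR) from the eight
#' colonization/extinction probabilities, with competition conditioned on
#' the competitor's state in the departing week (default) or the arriving
#' week (row-renormalized variant).
#'
#' @param gam_A,gam_R colonization with the competitor absent.
#' @param gam_A_comp,gam_R_comp colonization with the competitor present.
#' @param eps_A,eps_R extinction with the competitor absent.
#' @param eps_A_comp,eps_R_comp extinction with the competitor present.
#' @param conditioning `"departing"` or `"arriving"`.
#' @return 4 x 4 matrix with dimnames (U, A, R, AR).
#' @export
build_transition_matrix <- function(gam_A, gam_A_comp, gam_R, gam_R_comp,
                                    eps_A, eps_A_comp, eps_R, eps_R_comp,
                                    conditioning = "departing") {
  p <- c(gam_A, gam_A_comp, gam_R, gam_R_comp,
         eps_A, eps_A_comp, eps_R, eps_R_comp)
  stopifnot(all(p >= 0), all(p <= 1))
  cond <- match.arg(conditioning, c("departing", "arriving"))
  Tm <- cpp_transition_matrix(p, as.integer(cond == "arriving"))
  dimnames(Tm) <- list(c("U", "A", "R", "AR"), c("U", "A", "R", "AR"))
  Tm
}

#' Daily emission probability
#'
#' Probability of an observed daily state given the latent weekly joint
#' state. Species absent from the latent state are never observed (no false
#' positives); unobserved days have probability 1.
#'
#' @param latent latent state: `"U"`, `"A"`, `"R"` or `"AR"`.
#' @param observed observed state: `"none"`, `"A"`, `"R"`, `"AR"`, or `NA`
#'   (unobserved day).
#' @param rho_A,rho_R daily detection probabilities.
#' @return probability.
#' @export
emission_probability <- function(latent, observed, rho_A, rho_R) {
  latent <- match.arg(latent, c("U", "A", "R", "AR"))
  if (is.na(observed)) return(1)
  observed <- match.arg(as.character(observed), c("none", "A", "R", "AR"))
  zA <- latent %in% c("A", "AR"); zR <- latent %in% c("R", "AR")
  yA <- observed %in% c("A", "AR"); yR <- observed %in% c("R", "AR")
  if ((yA && !zA) || (yR && !zR)) return(0)
  p <- 1
  if (zA) p <- p * (if (yA) rho_A else 1 - rho_A)
  if (zR) p <- p * (if (yR) rho_R else 1 - rho_R)
  p
}

# ---- internal: pack a histories + covariates pair for the C++ core --------

obs_to_code <- function(obs) {
  code <- match(as.character(obs), obs_levels)  # 1..4
  code[is.na(code)] <- 0L
  as.integer(code)
}

build_pack <- function(histories, covariates, config = occu_config()) {
  winters <- dplyr::distinct(histories, .data$site_id, .data$year) |>
    dplyr::arrange(.data$site_id, .data$year)
  years <- sort(unique(winters$year))
  n <- nrow(winters)
  obs <- array(0L, dim = c(7, 7, n))      # day, week, winter
  car <- array(1L, dim = c(7, 7, n))
  h <- dplyr::inner_join(histories,
                         dplyr::mutate(winters, .w = dplyr::row_number()),
                         by = c("site_id", "year"))
  idx <- cbind(h$day, h$week, h$.w)
  obs[idx] <- obs_to_code(h$obs)
  car[idx] <- ifelse(is.na(h$carrion), 1L, as.integer(h$carrion))
  car[obs == 0L] <- 1L
  # dim c(day, week, winter) flattens day-fastest, matching the C++ layout
  cov <-dplyr::left_join(winters, covariates, by = c("site_id", "year"))
  need <- c("CLG", "TFG", "rodent", "feeding")
  if (anyNA(cov[need]))
    stop("covariates missing for some camera-winters")
  X <- as.matrix(cov[need])
  list(obs = as.integer(obs), carrion = as.integer(car),
       year = as.integer(match(winters$year, years)), X = X,
       n_years = length(years), years = years, winters = winters,
       cond = as.integer(config$conditioning == "arriving"))
}

#' Marginalized log-likelihood of detection histories
#'
#' Exact log-likelihood of the weekly 4-state latent Markov chain with daily
#' emissions, computed by the forward algorithm with the latent states
#' marginalized out. Each camera-winter is an independent replicate.
#'
#' @param histories detection-history table (see [build_histories()]).
#' @param covariates covariate table with standardized `CLG`, `TFG`,
#'   `rodent`, `feeding` per site x year.
#' @param params named parameter vector over the same years.
#' @param config model structure, see [occu_config()].
#' @return total log-likelihood, with the per-winter contributions in the
#'   `by_winter` attribute.
#' @export
marginal_likelihood <- function(histories, covariates, params,
                                config = occu_config()) {
  if (nrow(histories) == 0) stop("empty detection history")
  pk <- build_pack(histories, covariates, config)
  ll <- cpp_loglik(pk$obs, pk$carrion, pk$year, pk$X, pk$n_years,
                   unname(params), pk$cond)
  structure(sum(ll), by_winter = dplyr::mutate(pk$winters, loglik = ll))
}

#' Log posterior density
#'
#' Sum of the marginalized likelihood over all camera-winters, Logistic(0,1)
#' log-priors on every intercept and slope, Normal(0, sigma^2) on the year
#' random effects, and Uniform(0, B) on the random-effect SDs.
#'
#' @inheritParams marginal_likelihood
#' @param params named parameter vector.
#' @param n_years required when `histories` is NULL (prior only).
#' @return log density (`-Inf` outside the prior support).
#' @export
log_posterior <- function(params, histories = NULL, covariates = NULL,
                          config = occu_config(), n_years = NULL) {
  if (is.null(histories)) {
    stopifnot(!is.null(n_years))
    return(cpp_logprior(unname(params), n_years, config$sigma_upper))
  }
  pk <- build_pack(histories, covariates, config)
  lp <- cpp_logprior(unname(params), pk$n_years, config$sigma_upper)
  if (!is.finite(lp)) return(-Inf)
  lp + sum(cpp_loglik(pk$obs, pk$carrion, pk$year, pk$X, pk$n_years,
                      unname(params), pk$cond))
}
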