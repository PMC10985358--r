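#' Model structure configuration
#'
#' Declares which design variables enter each parameter block, mirroring the
#' default structure of the analysis: initial occupancy (psi), colonization
#' (gamma) and extinction (epsilon) are logit-linear in the two geographic
#' gradients (CLG, TFG), the annual rodent index and the feeding-station
#' index; gamma and epsilon additionally carry a competitor-presence main
#' effect and its interactions with rodent abundance and feeding; daily
#' detection (rho) depends on whether the carrion is present that day.
#' Every block has an independent year random effect per species.
#'
#' @param psi,gamma,epsilon character vectors of covariates entering each
#'   block; subsets of `c("CLG", "TFG", "rodent", "feeding")`.
#' @param competition competition terms on gamma and epsilon; subset of
#'   `c("main", "rodent", "feeding")` ("rodent"/"feeding" are interactions of
#'   the competitor-presence effect with those covariates).
#' @param rho_carrion logical; does detection depend on daily carrion
#'   presence?
#' @param sigma_upper upper bound of the Uniform(0, B) prior on the year
#'   random-effect standard deviations (logit scale).
#' @param conditioning whether competition terms in the weekly transition are
#'   conditioned on the competitor's state in the departing week (default,
#'   the standard two-species dynamic-occupancy construction) or in the
#'   arriving week (row-renormalized variant).
#' @return an object of class `occu_config`.
#' @export
occu_config <- function(psi = c("CLG", "TFG", "rodent", "feeding"),
                        gamma = c("CLG", "TFG", "rodent", "feeding"),
                        epsilon = c("CLG", "TFG", "rodent", "feeding"),
                        competition = c("main", "rodent", "feeding"),
                        rho_carrion = TRUE,
                        sigma_upper = 5,
                        conditioning = c("departing", "arriving")) {
  covs <- c("CLG", "TFG", "rodent", "feeding")
  stopifnot(all(psi %in% covs), all(gamma %in% covs), all(epsilon %in% covs),
            all(competition %in% c("main", "rodent", "feeding")),
            is.logical(rho_carrion), sigma_upper > 0)
  structure(list(psi = psi, gamma = gamma, epsilon = epsilon,
                 competition = competition, rho_carrion = rho_carrion,
                 sigma_upper = sigma_upper,
                 conditioning = match.arg(conditioning)),
            class = "occu_config")
}

block_covariates <- c("CLG", "TFG", "rodent", "feeding")

#' Parameter names of the full model
#'
#' The parameter vector is laid out as 46 fixed effects (23 per species:
#' psi intercept + 4 slopes; gamma and epsilon intercept + 4 slopes +
#' competition main effect + 2 interactions; rho intercept + carrion-absence
#' effect), 8 random-effect standard deviations (species x block), and
#' 8 x n_years year random effects.
#'
#' @param n_years number of study years.
#' @return character vector naming every element of the parameter vector.
#' @export
param_names <- function(n_years) {
  fixed <- unlist(lapply(c("A", "R"), function(s) {
    c(paste0("psi_", s, "_", c("int", block_covariates)),
      paste0("gam_", s, "_", c("int", block_covariates,
                               "comp", "comp_rodent", "comp_feeding")),
      paste0("eps_", s, "_", c("int", block_covariates,
                               "comp", "comp_rodent", "comp_feeding")),
      paste0("rho_", s, "_", c("int", "nocarrion")))
  }))
  sig <- as.vector(outer(c("psi", "gam", "eps", "rho"), c("A", "R"),
                         function(b, s) paste0("sigma_", b, "_", s)))
  re <- unlist(lapply(c("A", "R"), function(s)
    unlist(lapply(c("psi", "gam", "eps", "rho"), function(b)
      paste0("u_", b, "_", s, "_", seq_len(n_years))))))
  c(fixed, sig, re)
}

#' Build a zero-initialized named parameter vector
#' @inheritParams param_names
#' @param sigma value for the random-effect SDs (default 0.5).
#' @return named numeric vector.
#' @export
empty_params <- function(n_years, sigma = 0.5) {
  nm <- param_names(n_years)
  th <- setNames(numeric(length(nm)), nm)
  th[grepl("^sigma_", nm)] <- sigma
  th
}

# Indices (1-based) of parameters sampled under a given configuration.
# Intercepts, enabled slopes, enabled competition terms, all sigmas and all
# year REs are free; disabled slopes are pinned at zero.
free_param_indices <- function(config, n_years) {
  nm <- param_names(n_years)
  keep <- rep(TRUE, length(nm))
  for (s in c("A", "R")) {
    for (cv in block_covariates) {
      if (!(cv %in% config$psi)) keep[nm == paste0("psi_", s, "_", cv)] <- FALSE
      if (!(cv %in% config$gamma)) keep[nm == paste0("gam_", s, "_", cv)] <- FALSE
      if (!(cv %in% config$epsilon)) keep[nm == paste0("eps_", s, "_", cv)] <- FALSE
    }
    comp_terms <- c(main = "comp", rodent = "comp_rodent",
                    feeding = "comp_feeding")
    for (k in names(comp_terms)) {
      if (!(k %in% config$competition)) {
        keep[nm == paste0("gam_", s, "_", comp_terms[[k]])] <- FALSE
        keep[nm == paste0("eps_", s, "_", comp_terms[[k]])] <- FALSE
      }
    }
    if (!config$rho_carrion) keep[nm == paste0("rho_", s, "_nocarrion")] <- FALSE
  }
  which(keep)
}
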