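#' Stationary distribution of a weekly transition matrix
#'
#' Unique probability vector pi with pi T = pi, obtained from the linear
#' system (I - T' + 1) pi = 1. Requires an irreducible aperiodic chain
#' (interior transition probabilities); boundary kernels (rows of 0/1) make
#' the system singular and raise an error.
#'
#' @param Tm 4 x 4 row-stochastic matrix.
#' @return named probability 4-vector.
#' @export
stationary_distribution <- function(Tm) {
  stopifnot(is.matrix(Tm), nrow(Tm) == ncol(Tm))
  if (any(abs(rowSums(Tm) - 1) > 1e-12))
    stop("transition matrix rows must sum to 1")
  n <- nrow(Tm)
  A <- diag(n) - t(Tm) + matrix(1, n, n)
  pi <- tryCatch(solve(A, rep(1, n)),
                 error = function(e)
                   stop("chain is reducible or periodic; no unique ",
                        "stationary distribution", call. = FALSE))
  if (any(pi < -1e-10))
    stop("chain is reducible; no unique stationary distribution")
  pi <- pmax(pi, 0); pi <- pi / sum(pi)
  names(pi) <- rownames(Tm) %||% c("U", "A", "R", "AR")[seq_len(n)]
  pi
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-species stationary carrion use
#'
#' @param pi stationary 4-vector over (U, A, R, AR).
#' @return named vector `use_A`, `use_R` (probability the species uses the
#'   carrion in the long run, alone or together with its competitor).
#' @export
carrion_use <- function(pi) {
  c(use_A = unname(pi[2] + pi[4]), use_R = unname(pi[3] + pi[4]))
}

# eight transition probabilities for one draw at given covariates, RE = 0
draw_probs <- function(theta, nm, covariates, n_years) {
  p <- setNames(theta, nm)
  g <- function(block, s, comp) linpred(p, block, s, covariates, year = 0,
                                        n_years = n_years,
                                        competitor_present = comp)
  c(gam_A = g("gamma", "A", FALSE), gam_A_comp = g("gamma", "A", TRUE),
    gam_R = g("gamma", "R", FALSE), gam_R_comp = g("gamma", "R", TRUE),
    eps_A = g("epsilon", "A", FALSE), eps_A_comp = g("epsilon", "A", TRUE),
    eps_R = g("epsilon", "R", FALSE), eps_R_comp = g("epsilon", "R", TRUE))
}

#' Stationary carrion-use curves over a covariate grid
#'
#' For each posterior draw and grid value, builds the weekly transition
#' matrix with the focal covariate set to the grid value (other covariates
#' at their mean, i.e. 0 after standardization; year random effects at 0),
#' takes its stationary distribution and reports the per-species use with
#' posterior median and 50%/90% intervals.
#'
#' @param fit an [occu_fit][fit_occupancy()].
#' @param covariate one of `"CLG"`, `"TFG"`, `"rodent"`, `"feeding"`.
#' @param grid numeric grid (standardized scale).
#' @param range_obs observed range of the standardized covariate; grid
#'   values outside it trigger an extrapolation warning.
#' @param n_draws number of posterior draws used (thinned evenly;
#'   default all).
#' @return tibble: `covariate`, `value`, `species`, `median`, `lwr50`,
#'   `upr50`, `lwr90`, `upr90`.
#' @export
use_curves <- function(fit, covariate = "feeding",
                       grid = seq(-2, 2, length.out = 21),
                       range_obs = NULL, n_draws = NULL) {
  stopifnot(covariate %in% block_covariates)
  if (is.null(range_obs) && !is.null(fit$pack))
    range_obs <- range(fit$pack$X[, match(covariate, block_covariates)])
  if (!is.null(range_obs) && (min(grid) < range_obs[1] ||
                              max(grid) > range_obs[2]))
    warning("grid extends beyond the observed covariate range ",
            "(extrapolation)")
  m <- draw_matrix(fit)
  if (!is.null(n_draws) && n_draws < nrow(m))
    m <- m[round(seq(1, nrow(m), length.out = n_draws)), , drop = FALSE]
  nm <- fit$param_names
  cond <- fit$config$conditioning
  out <- lapply(grid, function(v) {
    covs <- setNames(as.list(rep(0, 4)), block_covariates)
    covs[[covariate]] <- v
    use <- t(apply(m, 1, function(th) {
      pr <- draw_probs(th, nm, covs, fit$pack$n_years)
      Tm <- build_transition_matrix(pr[1], pr[2], pr[3], pr[4],
                                    pr[5], pr[6], pr[7], pr[8],
                                    conditioning = cond)
      carrion_use(stationary_distribution(Tm))
    }))
    summarize_use(use, covariate, v)
  })
  dplyr::bind_rows(out)
}

summarize_use <- function(use, covariate, value) {
  qs <- apply(use, 2, quantile, probs = c(0.05, 0.25, 0.5, 0.75, 0.95))
  dplyr::tibble(covariate = covariate, value = value,
                species = c("A", "R"),
                median = as.numeric(qs["50%", ]),
                lwr50 = as.numeric(qs["25%", ]),
                upr50 = as.numeric(qs["75%", ]),
                lwr90 = as.numeric(qs["5%", ]),
                upr90 = as.numeric(qs["95%", ]))
}

#' Average stationary carrion use (intercepts only)
#'
#' Stationary use at the average covariate values (0 after
#' standardization), i.e. computed from the estimated intercepts only.
#'
#' @inheritParams use_curves
#' @return tibble as in [use_curves()] with a single grid point.
#' @export
average_use <- function(fit, n_draws = NULL) {
  use_curves(fit, covariate = "rodent", grid = 0, n_draws = n_draws)
}

#' Plot stationary carrion-use curves
#' @param object output of [use_curves()].
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_use_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$median,
                                       colour = .data$species,
                                       fill = .data$species)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lwr50,
                                      ymax = .data$upr50),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lwr90), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$upr90), linetype = 2) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = unique(object$covariate)[1],
                  y = "stationary carrion use") +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
}

#' Bayesian p-value from discrepancy pairs
#'
#' Proportion of posterior-predictive replicates whose discrepancy exceeds
#' the observed one. Values near 0 or 1 indicate misfit; fit is
#' conventionally adequate for p in (.1, .9).
#'
#' @param d_obs,d_sim observed and simulated discrepancies (equal length).
#' @return proportion in `[0, 1]`.
#' @export
bayes_p <- function(d_obs, d_sim) {
  stopifnot(length(d_obs) == length(d_sim))
  mean(d_sim > d_obs)
}

#' Posterior predictive check
#'
#' Simulates replicate datasets on the observed design (same winters,
#' missingness and carrion flags) from posterior draws and compares
#' chi-squared discrepancies between observed and replicate data for
#' (a) the detection model: per winter x species x week counts of detection
#' days against their expectation under the conditional weekly state
#' marginals (forward-backward), and (b) the transition model: counts of
#' observed joint-state week pairs against their model expectation.
#'
#' @param fit an [occu_fit][fit_occupancy()].
#' @param n_rep number of replicate datasets (the full analysis uses
#'   10,000; fewer than 100 triggers a warning).
#' @param seed integer seed.
#' @return object of class `occu_ppc`: `p_detection`, `p_transition` and a
#'   tibble of per-replicate discrepancy pairs.
#' @export
posterior_predictive_check <- function(fit, n_rep = 1000, seed = 1) {
  if (n_rep < 100) warning("n_rep < 100 gives unstable Bayesian p-values")
  pk <- fit$pack
  m <- draw_matrix(fit)
  set.seed(seed)
  take <- sample.int(nrow(m), n_rep, replace = n_rep > nrow(m))
  res <- matrix(NA_real_, n_rep, 4,
                dimnames = list(NULL, c("det_obs", "det_sim",
                                        "trans_obs", "trans_sim")))
  ref_ws <- weekly_observed_states(pk, pk$obs)  # design: which weeks count
  for (r in seq_len(n_rep)) {
    th <- unname(m[take[r], ])
    sim <- cpp_simulate(pk$obs, pk$carrion, pk$year, pk$X, pk$n_years, th,
                        pk$cond)
    et <- transition_expected_counts(pk, th, ref_ws)
    res[r, "det_obs"] <- detection_discrepancy(pk, pk$obs, th)
    res[r, "det_sim"] <- detection_discrepancy(pk, sim$obs, th)
    res[r, "trans_obs"] <- transition_discrepancy(pk, pk$obs, et, ref_ws)
    res[r, "trans_sim"] <- transition_discrepancy(pk, sim$obs, et, ref_ws)
  }
  structure(list(p_detection = bayes_p(res[, "det_obs"], res[, "det_sim"]),
                 p_transition = bayes_p(res[, "trans_obs"],
                                        res[, "trans_sim"]),
                 discrepancies = dplyr::as_tibble(res) |>
                   dplyr::mutate(rep = dplyr::row_number(), .before = 1),
                 n_rep = n_rep, seed = seed),
            class = "occu_ppc")
}

# ---- discrepancy internals ------------------------------------------------

# per-winter detection probabilities (2 carrion levels x 2 species), RE on
rho_by_winter <- function(pk, th) {
  n_years <- pk$n_years
  nm <- param_names(n_years)
  p <- setNames(th, nm)
  t <- pk$year
  out <- list()
  for (s in c("A", "R")) {
    u <- p[paste0("u_rho_", s, "_", t)]
    lp <- p[[paste0("rho_", s, "_int")]] + u
    out[[paste0(s, "1")]] <- plogis(lp)
    out[[paste0(s, "0")]] <- plogis(lp + p[[paste0("rho_", s, "_nocarrion")]])
  }
  out
}

# chi-squared between observed and expected daily detection counts per
# winter x species x week, expectation from forward-backward marginals
detection_discrepancy <- function(pk, obs, th) {
  n <- nrow(pk$winters)
  marg <- cpp_state_marginals(obs, pk$carrion, pk$year, pk$X, pk$n_years,
                              th, pk$cond)
  oa <- array(obs, dim = c(7, 7, n))         # day, week, winter
  ca <- array(pk$carrion, dim = c(7, 7, n))
  rho <- rho_by_winter(pk, th)
  chi <- 0
  for (w in 1:7) {
    ow <- oa[, w, , drop = TRUE]             # 7 days x n winters
    cw <- ca[, w, , drop = TRUE]
    observed <- ow != 0
    n_obs <- colSums(observed)
    keep <- n_obs > 0
    if (!any(keep)) next
    pA <- marg[, (w - 1) * 4 + 2] + marg[, (w - 1) * 4 + 4]
    pR <- marg[, (w - 1) * 4 + 3] + marg[, (w - 1) * 4 + 4]
    nc1 <- colSums(observed & cw == 1)
    nc0 <- n_obs - nc1
    O_A <- colSums(ow == 2 | ow == 4)
    O_R <- colSums(ow == 3 | ow == 4)
    E_A <- pA * (nc1 * rho$A1 + nc0 * rho$A0)
    E_R <- pR * (nc1 * rho$R1 + nc0 * rho$R0)
    for (v in list(cbind(O_A, E_A)[keep, , drop = FALSE],
                   cbind(O_R, E_R)[keep, , drop = FALSE])) {
      e <- v[, 2]; o <- v[, 1]
      ok <- e > 1e-12
      chi <- chi + sum((o[ok] - e[ok])^2 / e[ok])
    }
  }
  chi
}

# observed weekly joint states (0 = week not retained) as n x 7 matrix
weekly_observed_states <- function(pk, obs) {
  n <- nrow(pk$winters)
  oa <- array(obs, dim = c(7, 7, n))
  sapply(1:7, function(w) {
    ow <- oa[, w, , drop = TRUE]
    retained <- colSums(ow != 0) > 0
    sA <- colSums(ow == 2 | ow == 4) > 0
    sR <- colSums(ow == 3 | ow == 4) > 0
    ifelse(retained, 1L + sA + 2L * sR, 0L)
  })
}

# expected counts of observed joint-state week pairs (16 cells) plus the
# per-winter week-detectability terms needed to score a dataset
transition_expected_counts <- function(pk, th, ref_ws = NULL) {
  n <- nrow(pk$winters)
  nm <- param_names(pk$n_years)
  p <- setNames(th, nm)
  oa <- array(pk$obs, dim = c(7, 7, n))
  ca <- array(pk$carrion, dim = c(7, 7, n))
  rho <- rho_by_winter(pk, th)
  t <- pk$year
  # per-winter psi and transition kernels (covariates + REs)
  lp_block <- function(short, s, comp = FALSE) {
    off <- paste0(short, "_", s, "_")
    lp <- p[[paste0(off, "int")]] + p[paste0("u_", short, "_", s, "_", t)] +
      as.numeric(pk$X %*% unlist(p[paste0(off, block_covariates)]))
    if (comp)
      lp <- lp + p[[paste0(off, "comp")]] +
        p[[paste0(off, "comp_rodent")]] * pk$X[, 3] +
        p[[paste0(off, "comp_feeding")]] * pk$X[, 4]
    plogis(lp)
  }
  psiA <- lp_block("psi", "A"); psiR <- lp_block("psi", "R")
  gA <- lp_block("gam", "A"); gAc <- lp_block("gam", "A", TRUE)
  gR <- lp_block("gam", "R"); gRc <- lp_block("gam", "R", TRUE)
  eA <- lp_block("eps", "A"); eAc <- lp_block("eps", "A", TRUE)
  eR <- lp_block("eps", "R"); eRc <- lp_block("eps", "R", TRUE)
  Tm <- array(NA_real_, c(n, 4, 4))
  for (i in seq_len(n))
    Tm[i, , ] <- build_transition_matrix(gA[i], gAc[i], gR[i], gRc[i],
                                         eA[i], eAc[i], eR[i], eRc[i],
                                         if (pk$cond == 1) "arriving"
                                         else "departing")
  # weekly per-species "detected at least once" probabilities given presence
  pdetA <- pdetR <- matrix(NA_real_, n, 7)
  for (w in 1:7) {
    ow <- oa[, w, , drop = TRUE]; cw <- ca[, w, , drop = TRUE]
    observed <- ow != 0
    nc1 <- colSums(observed & cw == 1); nc0 <- colSums(observed) - nc1
    pdetA[, w] <- 1 - (1 - rho$A1)^nc1 * (1 - rho$A0)^nc0
    pdetR[, w] <- 1 - (1 - rho$R1)^nc1 * (1 - rho$R0)^nc0
  }
  # Q[[w]][[z]][[a]] = P(observed weekly state a | latent z) for week w,
  # precomputed once per week (z, a indexed over U, A, R, AR)
  week_q <- function(w) {
    lapply(1:4, function(z) {
      zA <- z %in% c(2, 4); zR <- z %in% c(3, 4)
      lapply(1:4, function(a) {
        aA <- a %in% c(2, 4); aR <- a %in% c(3, 4)
        pa <- if (zA) (if (aA) pdetA[, w] else 1 - pdetA[, w]) else
          rep(as.numeric(!aA), n)
        pr <- if (zR) (if (aR) pdetR[, w] else 1 - pdetR[, w]) else
          rep(as.numeric(!aR), n)
        pa * pr
      })
    })
  }
  if (is.null(ref_ws)) ref_ws <- weekly_observed_states(pk, pk$obs)
  retained <- ref_ws != 0
  mu <- cbind((1 - psiA) * (1 - psiR), psiA * (1 - psiR),
              (1 - psiA) * psiR, psiA * psiR)
  E <- matrix(0, 4, 4)
  Qw <- week_q(1)
  for (w in 1:6) {
    Qn <- week_q(w + 1)
    keep <- retained[, w] & retained[, w + 1]
    if (any(keep)) {
      # inner[[z1]][[b]] = sum_z2 T[z1, z2] q_{w+1}(b | z2)
      inner <- lapply(1:4, function(z1) lapply(1:4, function(b) {
        v <- 0
        for (z2 in 1:4) v <- v + Tm[, z1, z2] * Qn[[z2]][[b]]
        v
      }))
      for (a in 1:4) for (b in 1:4) {
        val <- 0
        for (z1 in 1:4)
          val <- val + mu[, z1] * Qw[[z1]][[a]] * inner[[z1]][[b]]
        E[a, b] <- E[a, b] + sum(val[keep])
      }
    }
    mu_new <- matrix(0, n, 4)
    for (z2 in 1:4) {
      v <- 0
      for (z1 in 1:4) v <- v + mu[, z1] * Tm[, z1, z2]
      mu_new[, z2] <- v
    }
    mu <- mu_new
    Qw <- Qn
  }
  E
}

# chi-squared of observed week-pair counts against expected counts
transition_discrepancy <- function(pk, obs, expected, ref_ws = NULL) {
  ws <- weekly_observed_states(pk, obs)
  ref <- if (is.null(ref_ws)) weekly_observed_states(pk, pk$obs) else ref_ws
  O <- matrix(0, 4, 4)
  for (w in 1:6) {
    keep <- ref[, w] != 0 & ref[, w + 1] != 0
    if (!any(keep)) next
    a <- ws[keep, w]; b <- ws[keep, w + 1]
    for (k in seq_along(a)) O[a[k], b[k]] <- O[a[k], b[k]] + 1
  }
  ok <- expected > 1e-12
  sum((O[ok] - expected[ok])^2 / expected[ok])
}

#' @export
print.occu_ppc <- function(x, ...) {
  cat("Posterior predictive check (", x$n_rep, " replicates)\n", sep = "")
  cat(sprintf("  Bayesian p, detection model:  %.3f\n", x$p_detection))
  cat(sprintf("  Bayesian p, transition model: %.3f\n", x$p_transition))
  cat("  (adequate fit conventionally p in (.1, .9))\n")
  invisible(x)
}

#' @export
glance.occu_ppc <- function(x, ...) {
  dplyr::tibble(p_detection = x$p_detection,
                p_transition = x$p_transition, n_rep = x$n_rep)
}

#' @export
autoplot.occu_ppc <- function(object, ...) {
  d <- object$discrepancies |>
    tidyr::pivot_longer(-"rep", names_to = c("part", "which"),
                        names_sep = "_") |>
    tidyr::pivot_wider(names_from = "which")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$obs, y = .data$sim)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::facet_wrap(~.data$part, scales = "free") +
    ggplot2::labs(x = "observed discrepancy", y = "replicate discrepancy") +
    ggplot2::theme_minimal()
}
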