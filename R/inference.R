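#' Fit the two-species dynamic occupancy model by MCMC
#'
#' Samples the marginalized posterior with an adaptive
#' Metropolis-within-Gibbs sampler (component-wise random-walk proposals
#' with Roberts-Rosenthal scale adaptation toward a 0.44 acceptance rate).
#' Priors: Logistic(0, 1) on every logit-scale intercept and slope,
#' Normal(0, sigma^2) on the year random effects and Uniform(0, B) on their
#' SDs. The default schedule mirrors the full analysis (4 chains, 1000
#' adaptation + 10,000 burn-in, 25,000 draws thinned 1-in-5); pass smaller
#' values for exploratory runs.
#'
#' @inheritParams marginal_likelihood
#' @param chains,adapt,burn_in,iter,thin MCMC schedule; `iter` draws per
#'   chain are taken after `adapt + burn_in`, keeping every `thin`-th.
#' @param seed integer seed; runs are bit-reproducible.
#' @param use_likelihood set FALSE to sample the prior only (prior
#'   predictive identity checks).
#' @param init optional named vector of initial values (jittered per chain).
#' @return an object of class `occu_fit`: posterior draws, per-parameter
#'   Gelman-Rubin statistics and summaries. Methods: [tidy()], [glance()],
#'   [autoplot()].
#' @export
fit_occupancy <- function(histories, covariates, config = occu_config(),
                          chains = 4, adapt = 1000, burn_in = 10000,
                          iter = 25000, thin = 5, seed = 1,
                          use_likelihood = TRUE, init = NULL) {
  pk <- build_pack(histories, covariates, config)
  nm <- param_names(pk$n_years)
  free <- free_param_indices(config, pk$n_years)
  set.seed(seed)
  kept <- iter %/% thin
  draws <- array(NA_real_, dim = c(kept, chains, length(nm)),
                 dimnames = list(NULL, NULL, nm))
  accepts <- matrix(NA_real_, chains, length(free))
  t0 <- Sys.time()
  for (ch in seq_len(chains)) {
    th0 <- draw_init(nm, init, pk$n_years)
    for (tries in 1:20) {
      lp <- cpp_logprior(unname(th0), pk$n_years, config$sigma_upper)
      ll <- if (use_likelihood)
        sum(cpp_loglik(pk$obs, pk$carrion, pk$year, pk$X, pk$n_years,
                       unname(th0), pk$cond)) else 0
      if (is.finite(lp + ll)) break
      th0 <- draw_init(nm, init, pk$n_years)
      if (tries == 20) stop("could not find finite initial values")
    }
    res <- cpp_sampler(pk$obs, pk$carrion, pk$year, pk$X, pk$n_years,
                       unname(th0), as.integer(free - 1L),
                       config$sigma_upper, as.integer(adapt + burn_in),
                       as.integer(iter), as.integer(thin), pk$cond,
                       use_likelihood)
    draws[, ch, ] <- res$draws
    accepts[ch, ] <- res$accept
  }
  rhat <- gelman_rubin(draws[, , free, drop = FALSE])
  structure(list(draws = draws, free = free, param_names = nm,
                 rhat = setNames(rep(NA_real_, length(nm)), nm) |>
                   replace(free, rhat),
                 accept = colMeans(accepts),
                 pack = pk, config = config,
                 schedule = list(chains = chains, adapt = adapt,
                                 burn_in = burn_in, iter = iter, thin = thin,
                                 seed = seed),
                 runtime = as.numeric(difftime(Sys.time(), t0,
                                               units = "secs"))),
            class = "occu_fit")
}

draw_init <- function(nm, init, n_years) {
  th <- empty_params(n_years)
  # intercepts from the prior, slopes at zero, sigma at 0.5; jittered
  ints <- grepl("_int$", nm)
  th[ints] <- rlogis(sum(ints))
  th[grepl("^sigma_", nm)] <- abs(0.5 + rnorm(8, 0, 0.1))
  th[grepl("^u_", nm)] <- rnorm(sum(grepl("^u_", nm)), 0, 0.1)
  if (!is.null(init)) th[names(init)] <- init + rnorm(length(init), 0, 0.05)
  th
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain PSRF per parameter. Values above 1.05 are
#' conventionally taken to indicate non-convergence.
#'
#' @param draws array `iterations x chains x parameters` (or
#'   `iterations x chains` for one parameter).
#' @return named numeric vector of Rhat values.
#' @export
gelman_rubin <- function(draws) {
  if (inherits(draws, "occu_fit"))
    draws <- draws$draws[, , draws$free, drop = FALSE]
  if (length(dim(draws)) == 2) dim(draws) <- c(dim(draws), 1)
  n <- dim(draws)[1]; m <- dim(draws)[2]
  if (m < 2) stop("gelman_rubin needs at least 2 chains")
  apply(draws, 3, function(x) {
    means <- colMeans(x)
    W <- mean(apply(x, 2, var))
    B <- n * var(means)
    if (W == 0) {
      if (B == 0) { warning("constant chains; Rhat set to 1"); return(1) }
      return(Inf)
    }
    sqrt(((n - 1) / n * W + B / n) / W)
  })
}

#' Flat matrix of posterior draws
#'
#' Stacks the kept draws of all chains into one matrix with named
#' parameter columns.
#'
#' @param fit an `occu_fit`.
#' @param params optional character vector of parameter names to keep.
#' @return numeric matrix, one column per parameter.
#' @export
draw_matrix <- function(fit, params = NULL) {
  d <- fit$draws
  m <- matrix(aperm(d, c(1, 2, 3)), nrow = dim(d)[1] * dim(d)[2],
              dimnames = list(NULL, fit$param_names))
  if (!is.null(params)) m <- m[, params, drop = FALSE]
  m
}

#' @export
tidy.occu_fit <- function(x, ...) {
  m <- draw_matrix(x)
  free_nm <- x$param_names[x$free]
  qs <- t(apply(m[, free_nm, drop = FALSE], 2, quantile,
                probs = c(0.05, 0.15, 0.25, 0.5, 0.75, 0.85, 0.95)))
  dplyr::tibble(term = free_nm,
                estimate = qs[, "50%"],
                conf.low.90 = qs[, "5%"], conf.high.90 = qs[, "95%"],
                conf.low.70 = qs[, "15%"], conf.high.70 = qs[, "85%"],
                conf.low.50 = qs[, "25%"], conf.high.50 = qs[, "75%"],
                rhat = unname(x$rhat[free_nm]))
}

#' @export
glance.occu_fit <- function(x, ...) {
  dplyr::tibble(n_winters = nrow(x$pack$winters),
                n_years = x$pack$n_years,
                n_parameters = length(x$free),
                n_draws = dim(x$draws)[1] * dim(x$draws)[2],
                chains = x$schedule$chains,
                max_rhat = max(x$rhat, na.rm = TRUE),
                runtime_s = x$runtime)
}

#' @export
print.occu_fit <- function(x, ...) {
  cat("Two-species dynamic occupancy fit\n")
  cat(sprintf("  %d camera-winters, %d years, %d free parameters\n",
              nrow(x$pack$winters), x$pack$n_years, length(x$free)))
  cat(sprintf("  %d draws (%d chains), max Rhat %.3f\n",
              dim(x$draws)[1] * dim(x$draws)[2], x$schedule$chains,
              max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Posterior interval plot
#'
#' @param object an `occu_fit`.
#' @param pars optional regular expression selecting parameters (default:
#'   fixed effects).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.occu_fit <- function(object, pars = "^(psi|gam|eps|rho)_", ...) {
  td <- tidy(object)
  td <- td[grepl(pars, td$term), , drop = FALSE]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term,
                                                      .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low.90,
                                         xmax = .data$conf.high.90),
                            height = 0, linewidth = 0.3) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low.50,
                                         xmax = .data$conf.high.50),
                            height = 0, linewidth = 1) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "posterior (logit scale)", y = NULL) +
    ggplot2::theme_minimal()
}
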