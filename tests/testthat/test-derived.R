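test_that("stationary distribution solves pi T = pi", {
  # no competition: per-species use is the closed form gamma/(gamma+eps)
  Tm <- build_transition_matrix(0.25, 0.25, 0.4, 0.4, 0.75, 0.75, 0.3, 0.3)
  pi <- stationary_distribution(Tm)
  use <- carrion_use(pi)
  expect_equal(unname(use["use_A"]), 0.25 / (0.25 + 0.75),
               tolerance = 1e-10)
  expect_equal(unname(use["use_R"]), 0.4 / (0.4 + 0.3), tolerance = 1e-10)

  expect_equal(unname(stationary_distribution(matrix(0.25, 4, 4))),
               rep(0.25, 4))

  set.seed(71)
  for (i in 1:50) {
    p <- random_trans_p()
    Tm <- build_transition_matrix(p$gam_A, p$gam_A_comp, p$gam_R,
                                  p$gam_R_comp, p$eps_A, p$eps_A_comp,
                                  p$eps_R, p$eps_R_comp)
    pi <- stationary_distribution(Tm)
    expect_equal(sum(pi), 1, tolerance = 1e-12)
    expect_true(all(pi >= 0))
    expect_equal(unname(pi), oracle_stationary_power(Tm), tolerance = 1e-9)
    expect_equal(as.numeric(pi %*% Tm), unname(pi), tolerance = 1e-12)
  }
})

test_that("reducible kernels are rejected", {
  expect_error(stationary_distribution(diag(4)), "reducible")
  expect_error(stationary_distribution(matrix(0.2, 4, 4)), "sum to 1")
})

test_that("use curves are deterministic for a single-draw posterior", {
  th <- empty_params(1, sigma = 0.5)
  fit <- make_fake_fit(matrix(th, 1, dimnames = list(NULL, names(th))))
  # all-zero coefficients: gamma = eps = 0.5 -> use = 0.5 for both species
  suppressWarnings(av <- average_use(fit))
  expect_equal(av$median, c(0.5, 0.5))
  expect_equal(av$lwr90, av$upr90)

  # curves over a grid are smooth deterministic functions of the covariate
  th2 <- th
  th2["gam_A_int"] <- qlogis(0.2); th2["eps_A_int"] <- qlogis(0.3)
  th2["gam_A_feeding"] <- 1
  fit2 <- make_fake_fit(matrix(th2, 1, dimnames = list(NULL, names(th2))))
  suppressWarnings(cv <- use_curves(fit2, "feeding", grid = c(-1, 0, 1)))
  a <- cv[cv$species == "A", ]
  expect_equal(a$median[2], 0.2 / (0.2 + 0.3), tolerance = 1e-12)
  expect_true(all(diff(a$median) > 0))
  # red fox untouched by the Arctic fox's feeding slope (no competition)
  expect_equal(cv$median[cv$species == "R"], rep(0.5, 3))
})

test_that("without competition, Arctic use ignores red-fox parameters", {
  set.seed(81)
  th <- empty_params(1, sigma = 0.5)
  nm <- names(th)
  th[grepl("^(psi|gam|eps|rho)_A", nm)] <- rnorm(23, 0, 0.7)
  th[grepl("comp", nm)] <- 0
  th2 <- th
  r_terms <- setdiff(grep("^(psi|gam|eps)_R", nm, value = TRUE),
                     grep("comp", nm, value = TRUE))
  th2[r_terms] <- rnorm(length(r_terms))
  f1 <- make_fake_fit(matrix(th, 1, dimnames = list(NULL, nm)))
  f2 <- make_fake_fit(matrix(th2, 1, dimnames = list(NULL, nm)))
  suppressWarnings({
    c1 <- use_curves(f1, "rodent", grid = c(-1, 1))
    c2 <- use_curves(f2, "rodent", grid = c(-1, 1))
  })
  expect_equal(c1$median[c1$species == "A"], c2$median[c2$species == "A"],
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(c1$median[c1$species == "R"],
                                c2$median[c2$species == "R"])))
})

test_that("grid values beyond the observed range warn about extrapolation", {
  th <- empty_params(1)
  fit <- make_fake_fit(matrix(th, 1, dimnames = list(NULL, names(th))))
  expect_warning(use_curves(fit, "feeding", grid = c(0, 3)),
                 "extrapolation")
})

test_that("Bayesian p-values are proportions with the right limits", {
  d_sim <- c(1, 2, 3, 4)
  expect_equal(bayes_p(rep(-Inf, 4), d_sim), 1)
  expect_equal(bayes_p(rep(Inf, 4), d_sim), 0)
  expect_equal(bayes_p(c(0, 0, 10, 10), d_sim), 0.5)
})

test_that("posterior predictive checks run end to end on a small fit", {
  sc <- sim_scenario(n_years = 3, n_sites = 5, seed = 5,
                     params = default_sim_params(3, sigma = 0.2))
  sim <- simulate_dataset(sc)
  fit <- fit_occupancy(sim$histories, sim$covariates, chains = 2,
                       adapt = 200, burn_in = 200, iter = 400, thin = 2,
                       seed = 9)
  ppc <- posterior_predictive_check(fit, n_rep = 120, seed = 3)
  expect_s3_class(ppc, "occu_ppc")
  expect_true(ppc$p_detection >= 0 && ppc$p_detection <= 1)
  expect_true(ppc$p_transition >= 0 && ppc$p_transition <= 1)
  expect_equal(nrow(ppc$discrepancies), 120)
  expect_true(all(is.finite(as.matrix(ppc$discrepancies[, -1]))))
  expect_warning(posterior_predictive_check(fit, n_rep = 50, seed = 3),
                 "unstable")
})

test_that("plot builders return ggplot objects", {
  th <- empty_params(1, sigma = 0.5)
  fit <- make_fake_fit(matrix(th, 1, dimnames = list(NULL, names(th))))
  expect_s3_class(autoplot(fit), "ggplot")
  suppressWarnings(cv <- use_curves(fit, "rodent", grid = c(-1, 0, 1)))
  expect_s3_class(plot_use_curves(cv), "ggplot")
})
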