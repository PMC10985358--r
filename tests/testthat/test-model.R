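test_that("logit-linear predictors reduce to their intercepts", {
  th <- empty_params(3, sigma = 0.5)
  covs <- list(CLG = 0, TFG = 0, rodent = 0, feeding = 0)
  expect_equal(linpred(th, "gamma", "A", covs, year = 0, n_years = 3), 0.5)
  th["gam_A_int"] <- qlogis(0.094)
  expect_equal(linpred(th, "gamma", "A", covs, year = 0, n_years = 3), 0.094)
  # competition terms are inert when the competitor is absent
  th["gam_A_comp"] <- 1
  expect_equal(linpred(th, "gamma", "A", covs, year = 0, n_years = 3,
                       competitor_present = FALSE), 0.094)
  expect_gt(linpred(th, "gamma", "A", covs, year = 0, n_years = 3,
                    competitor_present = TRUE), 0.094)
  # year random effect enters additively; unknown years error
  th["u_gam_A_2"] <- 0.7
  expect_equal(linpred(th, "gamma", "A", covs, year = 2, n_years = 3),
               plogis(qlogis(0.094) + 0.7))
  expect_error(linpred(th, "gamma", "A", covs, year = 9, n_years = 3),
               "unknown year")
  # detection depends on the daily carrion flag
  th["rho_A_int"] <- qlogis(0.40)
  th["rho_A_nocarrion"] <- qlogis(0.16) - qlogis(0.40)
  expect_equal(linpred(th, "rho", "A", year = 0, n_years = 3,
                       carrion = TRUE), 0.40)
  expect_equal(linpred(th, "rho", "A", year = 0, n_years = 3,
                       carrion = FALSE), 0.16)
})

test_that("initial state distribution is the independent-species product", {
  expect_equal(unname(initial_state_distribution(0, 0)), c(1, 0, 0, 0))
  expect_equal(unname(initial_state_distribution(1, 0)), c(0, 1, 0, 0))
  expect_equal(unname(initial_state_distribution(0.5, 0.5)), rep(0.25, 4))
  set.seed(4)
  for (i in 1:20) {
    p <- initial_state_distribution(runif(1), runif(1))
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
  }
})

test_that("transition matrix matches the keep/leave enumeration oracle", {
  # degenerate: no colonization, no extinction -> identity
  expect_equal(unname(build_transition_matrix(0, 0, 0, 0, 0, 0, 0, 0)),
               diag(4))
  # hand-checked row from departing state U
  Tm <- build_transition_matrix(0.2, 0.9, 0.4, 0.9, 0.5, 0.5, 0.5, 0.5)
  expect_equal(unname(Tm["U", ]), c(0.48, 0.12, 0.32, 0.08))
  set.seed(11)
  for (i in 1:200) {
    p <- random_trans_p()
    Tm <- build_transition_matrix(p$gam_A, p$gam_A_comp, p$gam_R,
                                  p$gam_R_comp, p$eps_A, p$eps_A_comp,
                                  p$eps_R, p$eps_R_comp)
    expect_equal(unname(rowSums(Tm)), rep(1, 4), tolerance = 1e-12)
    expect_equal(unname(Tm), oracle_transition_matrix(p), tolerance = 1e-12)
  }
})

test_that("arriving-state conditioning stays row-stochastic and differs", {
  set.seed(12)
  p <- random_trans_p()
  Ta <- build_transition_matrix(p$gam_A, p$gam_A_comp, p$gam_R,
                                p$gam_R_comp, p$eps_A, p$eps_A_comp,
                                p$eps_R, p$eps_R_comp,
                                conditioning = "arriving")
  expect_equal(unname(rowSums(Ta)), rep(1, 4), tolerance = 1e-12)
  Td <- build_transition_matrix(p$gam_A, p$gam_A_comp, p$gam_R,
                                p$gam_R_comp, p$eps_A, p$eps_A_comp,
                                p$eps_R, p$eps_R_comp)
  expect_gt(max(abs(Ta - Td)), 1e-3)
  # without competition the two conditionings coincide
  Tn <- build_transition_matrix(p$gam_A, p$gam_A, p$gam_R, p$gam_R,
                                p$eps_A, p$eps_A, p$eps_R, p$eps_R,
                                conditioning = "arriving")
  Tn2 <- build_transition_matrix(p$gam_A, p$gam_A, p$gam_R, p$gam_R,
                                 p$eps_A, p$eps_A, p$eps_R, p$eps_R)
  expect_equal(unname(Tn), unname(Tn2), tolerance = 1e-12)
})

test_that("emission probabilities forbid false positives", {
  expect_equal(emission_probability("AR", "AR", 0.4, 0.35), 0.4 * 0.35)
  expect_equal(emission_probability("A", "R", 0.4, 0.35), 0)
  expect_equal(emission_probability("U", "A", 0.4, 0.35), 0)
  expect_equal(emission_probability("U", "none", 0.4, 0.35), 1)
  expect_equal(emission_probability("A", NA, 0.4, 0.35), 1)
  expect_equal(emission_probability("AR", "A", 0.4, 0.35), 0.4 * 0.65)
})

test_that("one-week one-day likelihood equals the four-state sum", {
  fx <- make_fixture("single_week_single_day")
  th <- empty_params(1)
  th["psi_A_int"] <- qlogis(0.3); th["psi_R_int"] <- qlogis(0.6)
  th["rho_A_int"] <- qlogis(0.4); th["rho_R_int"] <- qlogis(0.35)
  ll <- marginal_likelihood(fx$histories, fx$covariates, th)
  expected <- log(0.3 * (1 - 0.6) * 0.4 + 0.3 * 0.6 * 0.4 * (1 - 0.35))
  expect_equal(as.numeric(ll), expected)
})

test_that("a fully unobserved history has likelihood one", {
  fx <- make_fixture("single_week_single_day")
  h <- fx$histories
  h$obs[] <- NA
  expect_equal(as.numeric(marginal_likelihood(h, fx$covariates,
                                              empty_params(1))), 0)
})

test_that("forward algorithm equals latent-sequence enumeration", {
  set.seed(21)
  for (i in 1:50) {
    cs <- random_likelihood_case()
    ll_pkg <- case_package_loglik(cs)
    ll_oracle <- oracle_likelihood(cs$obs, cs$carrion, cs$psi_A, cs$psi_R,
                                   cs$trans_p, cs$rho_A1, cs$rho_A0,
                                   cs$rho_R1, cs$rho_R0)
    expect_equal(ll_pkg, ll_oracle, tolerance = 1e-8)
  }
})

test_that("without competition the two species' likelihoods factorize", {
  set.seed(31)
  # a dataset in which red foxes are never detected, scored with rho_R ~ 0:
  # species A's likelihood must not depend on red-fox occupancy parameters
  cs <- random_likelihood_case(W = 5)
  cs$obs[cs$obs == 3] <- 1
  cs$obs[cs$obs == 4] <- 2
  th <- cs$th
  th[grepl("comp", names(th))] <- 0
  th["rho_R_int"] <- -30
  th[grepl("^u_rho_R", names(th))] <- 0
  tabs <- case_to_tables(cs)
  base <- marginal_likelihood(tabs$histories, tabs$covariates,
                              reindex_single_year(th, cs$year))
  th2 <- th
  th2[c("psi_R_int", "gam_R_int", "eps_R_int", "gam_R_rodent",
        "eps_R_CLG")] <- rnorm(5)
  alt <- marginal_likelihood(tabs$histories, tabs$covariates,
                             reindex_single_year(th2, cs$year))
  expect_equal(as.numeric(base), as.numeric(alt), tolerance = 1e-9)
})

test_that("the likelihood is symmetric under species relabelling", {
  set.seed(41)
  cs <- random_likelihood_case(W = 4)
  tabs <- case_to_tables(cs)
  th <- reindex_single_year(cs$th, cs$year)
  ll <- marginal_likelihood(tabs$histories, tabs$covariates, th)
  # swap data labels (A <-> R) and parameter blocks
  h2 <- tabs$histories
  h2$obs <- factor(c("none", "R", "A", "AR")[match(as.character(h2$obs),
                                                   obs_levels())],
                   levels = obs_levels())
  ll2 <- marginal_likelihood(h2, tabs$covariates, swap_species(th))
  expect_equal(as.numeric(ll), as.numeric(ll2), tolerance = 1e-10)
})
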