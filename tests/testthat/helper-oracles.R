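# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: transition rows come from enumerating the
# two species' keep/leave outcomes, likelihoods from summing over all 4^W
# latent sequences, stationary distributions from power iteration.

state_has <- function(z, sp) {
  # z in 1..4 = U, A, R, AR
  if (sp == "A") z %in% c(2, 4) else z %in% c(3, 4)
}

# enumeration oracle for one row of the weekly transition kernel
# (departing-state conditioning)
oracle_transition_row <- function(from, p) {
  # p: named list gam_A, gam_A_comp, gam_R, gam_R_comp, eps_A, eps_A_comp,
  #    eps_R, eps_R_comp
  a0 <- state_has(from, "A"); r0 <- state_has(from, "R")
  pA_occupied <- if (a0) 1 - (if (r0) p$eps_A_comp else p$eps_A)
                 else (if (r0) p$gam_A_comp else p$gam_A)
  pR_occupied <- if (r0) 1 - (if (a0) p$eps_R_comp else p$eps_R)
                 else (if (a0) p$gam_R_comp else p$gam_R)
  row <- numeric(4)
  for (a1 in 0:1) for (r1 in 0:1) {
    pr <- (if (a1) pA_occupied else 1 - pA_occupied) *
      (if (r1) pR_occupied else 1 - pR_occupied)
    row[1 + a1 + 2 * r1] <- row[1 + a1 + 2 * r1] + pr
  }
  row
}

oracle_transition_matrix <- function(p) {
  t(sapply(1:4, function(z) oracle_transition_row(z, p)))
}

# daily emission computed from first principles
oracle_emission <- function(z, y, rA, rR) {
  if (is.na(y) || y == 0) return(1)
  zA <- state_has(z, "A"); zR <- state_has(z, "R")
  yA <- y %in% c(2, 4); yR <- y %in% c(3, 4)
  if ((yA && !zA) || (yR && !zR)) return(0)
  (if (zA) (if (yA) rA else 1 - rA) else 1) *
    (if (zR) (if (yR) rR else 1 - rR) else 1)
}

# brute-force likelihood: sum over all 4^W latent sequences
# obs, carrion: W x 7 matrices (obs codes 0..4)
oracle_likelihood <- function(obs, carrion, psi_A, psi_R, trans_p,
                              rho_A1, rho_A0, rho_R1, rho_R0) {
  W <- nrow(obs)
  Tm <- oracle_transition_matrix(trans_p)
  init <- c((1 - psi_A) * (1 - psi_R), psi_A * (1 - psi_R),
            (1 - psi_A) * psi_R, psi_A * psi_R)
  week_emit <- function(z, w) {
    p <- 1
    for (d in 1:7) {
      y <- obs[w, d]
      if (y == 0) next
      rA <- if (carrion[w, d] == 1) rho_A1 else rho_A0
      rR <- if (carrion[w, d] == 1) rho_R1 else rho_R0
      p <- p * oracle_emission(z, y, rA, rR)
    }
    p
  }
  total <- 0
  seqs <- as.matrix(expand.grid(rep(list(1:4), W)))
  for (k in seq_len(nrow(seqs))) {
    zs <- seqs[k, ]
    pr <- init[zs[1]] * week_emit(zs[1], 1)
    if (W > 1) for (w in 2:W)
      pr <- pr * Tm[zs[w - 1], zs[w]] * week_emit(zs[w], w)
    total <- total + pr
  }
  log(total)
}

oracle_stationary_power <- function(Tm, iters = 1000) {
  v <- rep(1 / nrow(Tm), nrow(Tm))
  for (i in seq_len(iters)) v <- as.numeric(v %*% Tm)
  v / sum(v)
}

# random probability away from the boundary
rprob <- function(n = 1, lo = 0.05, hi = 0.95) runif(n, lo, hi)

random_trans_p <- function() {
  p <- as.list(rprob(8))
  names(p) <- c("gam_A", "gam_A_comp", "gam_R", "gam_R_comp",
                "eps_A", "eps_A_comp", "eps_R", "eps_R_comp")
  p
}

# random single-winter dataset + parameter vector for likelihood checks;
# returns everything both the package path and the oracle need
random_likelihood_case <- function(W = sample(1:6, 1), n_years = 3) {
  th <- empty_params(n_years)
  nm <- names(th)
  fixed <- !grepl("^(sigma_|u_)", nm)
  th[fixed] <- rnorm(sum(fixed), 0, 0.8)
  th[grepl("^u_", nm)] <- rnorm(sum(grepl("^u_", nm)), 0, 0.3)
  yr <- sample(seq_len(n_years), 1)
  covs <- list(CLG = rnorm(1), TFG = rnorm(1), rodent = rnorm(1),
               feeding = rnorm(1))
  obs <- matrix(0L, W, 7)
  carrion <- matrix(rbinom(W * 7, 1, 0.6), W, 7)
  for (w in 1:W) {
    n_obs <- sample(0:7, 1, prob = c(1, rep(2, 7)))  # some weeks empty
    if (n_obs > 0)
      obs[w, sample(7, n_obs)] <- sample(1:4, n_obs, replace = TRUE,
                                         prob = c(6, 2, 2, 1))
  }
  # probabilities implied by th at these covariates (hand inverse-logit)
  lp <- function(block, sp, comp = FALSE) {
    pre <- paste0(block, "_", sp, "_")
    v <- th[[paste0(pre, "int")]] + th[[paste0("u_", block, "_", sp, "_", yr)]]
    if (block != "rho")
      v <- v + sum(unlist(th[paste0(pre, c("CLG", "TFG", "rodent",
                                           "feeding"))]) * unlist(covs))
    if (comp)
      v <- v + th[[paste0(pre, "comp")]] +
        th[[paste0(pre, "comp_rodent")]] * covs$rodent +
        th[[paste0(pre, "comp_feeding")]] * covs$feeding
    plogis(v)
  }
  trans_p <- list(gam_A = lp("gam", "A"), gam_A_comp = lp("gam", "A", TRUE),
                  gam_R = lp("gam", "R"), gam_R_comp = lp("gam", "R", TRUE),
                  eps_A = lp("eps", "A"), eps_A_comp = lp("eps", "A", TRUE),
                  eps_R = lp("eps", "R"), eps_R_comp = lp("eps", "R", TRUE))
  rho <- function(sp, car) plogis(th[[paste0("rho_", sp, "_int")]] +
                                    th[[paste0("u_rho_", sp, "_", yr)]] +
                                    (1 - car) *
                                    th[[paste0("rho_", sp, "_nocarrion")]])
  list(th = th, W = W, year = yr, n_years = n_years, covs = covs, obs = obs,
       carrion = carrion,
       psi_A = lp("psi", "A"), psi_R = lp("psi", "R"), trans_p = trans_p,
       rho_A1 = rho("A", 1), rho_A0 = rho("A", 0),
       rho_R1 = rho("R", 1), rho_R0 = rho("R", 0))
}

# histories/covariates tibbles for a random_likelihood_case
case_to_tables <- function(cs) {
  h <- tidyr::expand_grid(site_id = "S01", year = cs$year,
                          week = seq_len(cs$W), day = 1:7) |>
    dplyr::mutate(
      obs = factor(c("none", "A", "R", "AR")[ifelse(
        cs$obs[cbind(week, day)] == 0, NA_integer_,
        cs$obs[cbind(week, day)])], levels = c("none", "A", "R", "AR")),
      carrion = cs$carrion[cbind(week, day)])
  cov <- dplyr::tibble(site_id = "S01", year = cs$year,
                       CLG = cs$covs$CLG, TFG = cs$covs$TFG,
                       rodent = cs$covs$rodent, feeding = cs$covs$feeding)
  list(histories = h, covariates = cov)
}

# package likelihood for a case, with the parameter vector re-indexed to the
# single observed year (the pack maps years to 1..n distinct years)
case_package_loglik <- function(cs, conditioning = "departing") {
  tabs <- case_to_tables(cs)
  th1 <- empty_params(1)
  nm3 <- names(cs$th)
  for (nm in names(th1)) {
    src <- if (grepl("^u_", nm))
      sub("_1$", paste0("_", cs$year), nm) else nm
    th1[[nm]] <- cs$th[[src]]
  }
  as.numeric(marginal_likelihood(tabs$histories, tabs$covariates, th1,
                                 occu_config(conditioning = conditioning)))
}

# minimal occu_fit-shaped object holding fixed draws, for derived-stage tests
make_fake_fit <- function(draws_matrix, n_years = 1,
                          config = occu_config()) {
  nm <- param_names(n_years)
  stopifnot(ncol(draws_matrix) == length(nm))
  arr <- array(NA_real_, dim = c(nrow(draws_matrix), 2, length(nm)),
               dimnames = list(NULL, NULL, nm))
  arr[, 1, ] <- draws_matrix
  arr[, 2, ] <- draws_matrix
  structure(list(draws = arr, free = seq_along(nm), param_names = nm,
                 rhat = setNames(rep(1, length(nm)), nm),
                 pack = list(X = matrix(0, 1, 4,
                                        dimnames = list(NULL,
                                                        c("CLG", "TFG",
                                                          "rodent",
                                                          "feeding"))),
                             n_years = n_years,
                             winters = dplyr::tibble(site_id = "S01",
                                                     year = 1)),
                 config = config,
                 schedule = list(chains = 2)),
            class = "occu_fit")
}

obs_levels <- function() c("none", "A", "R", "AR")

# re-index a parameter vector over n years to the single-year layout the
# pack uses when only year `yr` appears in the data
reindex_single_year <- function(th, yr) {
  th1 <- empty_params(1)
  for (nm in names(th1)) {
    src <- if (grepl("^u_", nm)) sub("_1$", paste0("_", yr), nm) else nm
    th1[[nm]] <- th[[src]]
  }
  th1
}

# swap the two species' parameter blocks (A <-> R)
swap_species <- function(th) {
  nm <- names(th)
  out <- th
  a_nm <- grepl("_A_|_A$", nm)
  r_nm <- grepl("_R_|_R$", nm)
  out[nm[a_nm]] <- th[sub("_A", "_R", nm[a_nm])]
  out[nm[r_nm]] <- th[sub("_R", "_A", nm[r_nm])]
  out
}
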