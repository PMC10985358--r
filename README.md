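# carrionuse

Two-species dynamic occupancy modelling of winter carrion use from
camera-trap data.

## What it is for

In the low-Arctic tundra, Arctic foxes (*Vulpes lagopus*) and red foxes
(*Vulpes vulpes*) scavenge the same reindeer carcasses in winter, and
ecologists want to know whether — and under which resource conditions —
one species keeps the other away from this food source. Baited camera
traps record daily visits, but a species that uses a carcass is not
photographed every day, so naive detection rates confound use with
detectability. `carrionuse` is for ecologists analysing such paired
camera-trap series: it estimates weekly *use* of carrion sites by two
interacting species while modelling the daily detection process
explicitly.

## The model

Each camera x winter is an independent hidden-Markov time series over at
most 7 weekly primary periods. The weekly latent state is the joint
occupancy (U, A, R, AR). Week 1 is drawn from species-specific initial
occupancy probabilities ψ; between weeks the state moves through a 4x4
kernel built from colonization (γ) and extinction (ε) probabilities that
may depend on the competitor's presence in the departing week; each
observed day contributes detection probabilities ρ for the species
present (no false positives). All probabilities are logit-linear in
standardized covariates — two geographic PCA gradients (coast-to-land,
tundra-to-forest), an annual rodent index, a feeding-station kernel
index — with competition main effects and competition x resource
interactions on γ and ε, a daily carrion-presence effect on ρ, and year
random effects everywhere. The likelihood marginalizes the latent chain
exactly (forward algorithm, in C++), and a component-wise adaptive
Metropolis sampler draws from the posterior under Logistic(0, 1) priors
on coefficients and Uniform(0, 5) priors on random-effect SDs.
Long-run "carrion use" is the steady state of the estimated weekly
kernel; chi-squared posterior predictive checks give Bayesian p-values
for the detection and transition parts of the model.

The full path from raw data is covered: photo tables → filtered daily
records (≥ 36 of 144 expected pictures) → week-segmented detection
histories (> 3 observed days per week, > 3 weeks per winter, ≤ 7 weeks)
→ covariate assembly → fit → derived curves and checks. A synthetic-data
generator emulating the real design (16 years x 18 cameras x 7 weeks x
7 days, ~20% missing days, 288 retained camera-winters) makes the whole
chain testable without any data download.

## Worked example

Simulate a small study, fit with a short exploratory schedule, and look
at the competition and detection estimates:

```r
library(carrionuse)

sim <- simulate_dataset(sim_scenario(n_years = 8, n_sites = 10, seed = 42))
fit <- fit_occupancy(sim$histories, sim$covariates,
                     chains = 2, adapt = 500, burn_in = 500,
                     iter = 1000, thin = 2, seed = 42)
fit
#> Two-species dynamic occupancy fit
#>   80 camera-winters, 8 years, 118 free parameters
#>   1000 draws (2 chains), max Rhat 1.173

dplyr::filter(tidy(fit),
              grepl("^(eps|rho)_[AR]_(int|comp|nocarrion)$", term))[, 1:5]
#> # A tibble: 8 × 5
#>   term            estimate conf.low.90 conf.high.90 conf.low.70
#>   <chr>              <dbl>       <dbl>        <dbl>       <dbl>
#> 1 eps_A_int         -1.72       -2.99       -0.532       -2.49
#> 2 eps_A_comp         0.541      -0.745       1.74        -0.268
#> 3 rho_A_int         -0.611      -1.19       -0.0695      -0.987
#> 4 rho_A_nocarrion   -0.898      -1.30       -0.490       -1.13
#> 5 eps_R_int         -1.20       -1.75       -0.709       -1.52
#> 6 eps_R_comp         1.18        0.261       2.19         0.589
#> 7 rho_R_int         -0.492      -0.878      -0.174       -0.722
#> 8 rho_R_nocarrion   -0.760      -0.987      -0.538       -0.912
```

Terms are on the logit scale: `eps_R_comp` = 1.18 means red foxes leave
an occupied carcass much more readily when an Arctic fox is present
(the generating design builds in symmetric competition on extinction),
and the negative `*_nocarrion` terms mean both species are detected less
once the bait is gone. Long-run carrion use at average covariates, and a
goodness-of-fit check:

```r
average_use(fit, n_draws = 500)
#> # A tibble: 2 × 8
#>   covariate value species median lwr50 upr50 lwr90 upr90
#> 1 rodent        0 A        0.298 0.227 0.386 0.142 0.529
#> 2 rodent        0 R        0.613 0.571 0.648 0.502 0.706

posterior_predictive_check(fit, n_rep = 200, seed = 1)
#> Posterior predictive check (200 replicates)
#>   Bayesian p, detection model:  0.290
#>   Bayesian p, transition model: 0.630
#>   (adequate fit conventionally p in (.1, .9))
```

So in this synthetic study red foxes use carrion at roughly twice the
rate of Arctic foxes in the long run, and both parts of the model pass
the predictive check — as they should on data the model itself
generated.

`use_curves(fit, "feeding")` sweeps one covariate for the stationary-use
plot, `autoplot(fit)` draws posterior intervals, and the
`pipeline_*()` functions (plus `inst/scripts/carrionuse-cli.R`) chain
prepare → fit → derive → ppc from a YAML run config.

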