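---
title: "Modelling two-species carrion use from camera traps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling two-species carrion use from camera traps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carrionuse)
```

## The problem

Arctic foxes (*Vulpes lagopus*) and red foxes (*Vulpes vulpes*) both
scavenge reindeer carrion on the low-Arctic tundra in winter, and the
endangered Arctic fox is widely thought to be excluded from resources by
its larger competitor. Camera traps baited with carrion record which
species visit a carcass day by day, but cameras miss animals that are
present, so raw detections confound *use* with *detectability*. This
package implements a two-species dynamic occupancy model that separates
the two: a weekly latent Markov chain describes which species use a
carrion site, and a daily observation model describes how often a using
species actually shows up on the pictures.

## Model

Each camera x winter combination is an independent time series of at most
7 weekly primary periods of 7 days. The joint latent state each week is
one of

* `U` — neither species uses the site,
* `A` — Arctic fox only,
* `R` — red fox only,
* `AR` — both.

Week 1 starts the day the carrion is introduced and the state is drawn
from independent species-specific initial occupancy probabilities
$\psi_A, \psi_R$. Between weeks the state moves through a $4 \times 4$
transition kernel built from per-species colonization probabilities
$\gamma_x$ (an unused site becomes used) and extinction probabilities
$\epsilon_x$ (a used site is abandoned). Competition enters by letting
$\gamma$ and $\epsilon$ depend on whether the competitor is present: the
kernel row for departing state `A`, for example, uses the Arctic fox's
competitor-free extinction and the red fox's conditional colonization
$\gamma_{R|A}$. Within a week the state is assumed constant (closure);
each observed day contributes a detection probability $\rho_x$ per
species present, with no false positives. Days with fewer than 36 of the
144 expected pictures are treated as unobserved, weeks with fewer than 4
observed days are dropped (the chain still advances a calendar week), and
camera-winters with fewer than 4 retained weeks are discarded.

All probabilities are logit-linear:

$$\mathrm{logit}(\theta_{x,it}) = \alpha_\theta^x + \beta^x_\theta
  \cdot \mathbf{z}_{it} + \left[\delta^x_\theta + \delta^x_{\theta
  \times \mathrm{rod}}\, \mathrm{rod}_t + \delta^x_{\theta \times
  \mathrm{feed}}\, \mathrm{feed}_{it}\right] C_{it} + u^x_{\theta,t}$$

where $\mathbf{z}$ holds the standardized covariates (coast-to-land
gradient CLG, tundra-to-forest gradient TFG, annual rodent index,
feeding-station kernel index), $C$ indicates competitor presence (only
for $\gamma$ and $\epsilon$), and $u_t \sim N(0, \sigma^2_\theta)$ is a
year random effect. Detection depends only on whether the carrion is
still present that day plus its year effect. The likelihood marginalizes
the latent chain exactly with the forward algorithm, so no discrete
states are sampled — posterior geometry improves and the result is
mathematically identical.

## Covariates

* **CLG / TFG** are the first two axes of a PCA on five standardized
  site-geography variables (elevation, distances to coast, road and
  forest, proportion of productive habitat). PCA signs are arbitrary, so
  the package fixes a convention: CLG loads positively on distance to
  coast (larger = inland) and TFG negatively on distance to forest
  (larger = closer to forest).
* **Rodent index**: fall captures per 100 trap-nights summed over the
  three focal rodent species within a trapping site, averaged over
  sites; a winter in calendar year $t$ uses the fall of $t-1$. Summing
  before averaging is one of several defensible combination rules; it is
  the default and can be changed upstream of the model, which only sees
  the standardized index.
* **Feeding index**: a time-dependent Gaussian kernel density of
  supplemental feeding stations (SD = 15 km, matching Arctic fox
  home-range scale) evaluated on a 2-km grid at the camera's cell, with
  only stations already active before the focal winter contributing. The
  kernel shape is a package choice (the bandwidth and resolution are the
  design's); any non-negative, additive, distance-decaying kernel would
  serve, and the function is small enough to swap.
* All continuous covariates are centered and scaled with the sample-SD
  (n - 1) convention before entering the logit scale.

## Priors and sampling

Intercepts and slopes get Logistic(0, 1) priors — on the probability
scale an intercept is then exactly Uniform(0, 1), which the test suite
verifies by running the sampler with the likelihood disabled. Year
random-effect standard deviations get Uniform(0, 5) priors; the upper
bound is generous on the logit scale and configurable. We parameterize
the prior on the SD rather than the variance for sampler stability; with
a flat prior either way this is a bounded reparameterization, not a
change of model.

Sampling uses component-wise random-walk Metropolis with
Roberts-Rosenthal batch adaptation of each proposal scale toward a 0.44
acceptance rate during a dedicated adaptation phase. Updates of a year
effect only rescore the camera-winters of that year, which makes a full
sweep cheap. The default schedule (4 chains, 1000 adaptation + 10,000
burn-in, 25,000 draws thinned 1-in-5, i.e. 20,000 kept) mirrors the full
analysis; tests and the acceptance script use a smoke profile (4 chains,
1000 + 1000, 2000 draws thinned 1-in-2) that finishes a study-scale fit
in about two minutes while still recovering generating parameters.
Chains are initialized with intercepts drawn from the prior, slopes at
zero, SDs near 0.5, jittered per chain; a seed makes runs
bit-reproducible.

## Derived quantities

*Stationary carrion use* treats the estimated weekly kernel as a Markov
chain and reports its steady state $\pi$ ($\pi T = \pi$, solved as a
linear system): `use_A` $= \pi_A + \pi_{AR}$ is the long-run probability
that Arctic foxes use the site. `use_curves()` sweeps one covariate with
the others at their mean (0 after standardization) and year effects at
zero, per posterior draw, giving median and 50%/90% bands; "average use"
is the same quantity computed from the intercepts alone. Boundary
kernels (probabilities exactly 0 or 1) make the chain reducible and are
rejected rather than silently resolved.

## Posterior predictive checks

There is no single canonical discrepancy statistic for this model
class, so the package documents its own choice (and the check accepts
any user-computed discrepancy pair through `bayes_p()`):

* **Detection**: per camera-winter x species x week, a Pearson
  chi-squared between the observed number of detection days and its
  expectation under the conditional (forward-backward) weekly state
  marginals.
* **Transition**: a chi-squared over the 16 cells of consecutive-week
  pairs of *observed* joint states (a species counts as present in a
  week if detected on any day) against their model expectation given the
  design, missingness and carrion flags.

Replicate datasets are simulated on the observed design from posterior
draws; the Bayesian p-value is the share of replicates whose discrepancy
exceeds the observed one, with fit conventionally adequate for p in
(.1, .9). On data generated from the model itself both p-values land in
that band in ≥ 90% of repetitions (tested at 500 replicates, 20
repetitions) — a calibration property of the chosen
statistics, not a statement about any particular alternative.

## The synthetic design

`sim_scenario()` defaults mirror the real study: 16 years x 18 cameras x
7 weeks x 7 days with ~20% of days unobserved, which after filtering
yields 288 camera-winters. Site gradients are
standard-normal site effects; the rodent index follows a noisy 4-year
cycle (the vole/lemming cycle); feeding switches on in year 13 of 16 at
about half the sites (the conservation program started feeding late in
the real series); the bait is present under a two-state daily Markov
chain tuned to a mean presence run of ~22 days and ~63% of days with
bait. Generating fixed effects use field-realistic intercept-scale
magnitudes and effect signs (e.g. competition roughly
doubles both species' weekly probability of leaving an occupied
carcass); year random effects are drawn with SD 0.3. One global seed
drives covariates, random effects, latent states and observations.

What the generator does *not* emulate: spatial autocorrelation between
cameras, within-week movement (closure violations), photo-level noise,
non-random missingness, and other scavengers. Passing recovery and
calibration tests on this design therefore demonstrates the estimator is
correct under the model's own assumptions — it does not certify the
model fits real data, which is exactly what the posterior predictive
check is for (with mobile, imperfectly detected species the detection
part commonly shows misfit in practice).

## Numerical and design choices

* **Competitor conditioning.** The construction conditions $\gamma$ and
  $\epsilon$ on the competitor's state in the *departing* week, the
  standard two-species dynamic-occupancy convention. An alternative
  reading — conditioning on the arriving week — is available
  (`occu_config(conditioning = "arriving")`); its cell products are
  renormalized per row since they no longer form a probability measure.
  The two coincide when competition effects are zero.
* **Dropped weeks** inside a winter advance the latent chain with
  emission 1 (missing at random) rather than compressing time, keeping
  the weekly time base.
* **Forward recursion** rescales by the weekly total and accumulates
  logs, so likelihoods of long histories cannot underflow; a zero total
  (impossible data under the parameters) returns `-Inf` rather than
  `NaN`.
* **Boundary inputs**: constant covariates are an error for
  `standardize()` but are centered with a warning when assembling a
  covariate table (a feeding index can be legitimately all-zero in
  subsets); filters use the strict "more than 3" reading (>= 4 days,
  >= 4 weeks), pinned by boundary tests.
* **Problem sizes** in tests were chosen to exercise each property at
  the scale the analysis targets: enumeration checks use single winters
  with up to 6 weeks (4^6 sequences), recovery uses the full 288
  camera-winter design with the smoke schedule, calibration uses 20
  repetitions of a 6-year x 8-site design at 500 replicates.

## Limitations

* Exactly two species; no spatial dependence between cameras; no
  within-week dynamics.
* The PPC discrepancies are one defensible choice; p-values computed
  with other statistics need not match.
* The smoke schedule's Rhat is typically ~1.1 on study-scale data; for
  inference-grade runs use the full schedule and check `glance()$max_rhat`
  <= 1.05.
* The rodent-index combination rule and whether the feeding index is
  itself standardized before entering the logit are configurable
  upstream choices; defaults are documented above.
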